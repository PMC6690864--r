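# Shared fixtures: tiny in-code career tables and desk-scale sampler configs.

# quick sampler settings for unit tests; acceptance tests choose their own
quick_config <- function(seed = 1L, n_samples = 300L, n_chains = 2L,
                         n_adapt = 200L, n_burnin = 200L) {
  mcmc_config(n_adapt = n_adapt, n_burnin = n_burnin, n_samples = n_samples,
              thin = 1L, n_chains = n_chains, seed = seed)
}

# one player's seasons as a raw data frame in the input CSV schema
player_rows <- function(id, ages, perf, mp = 30, pos = "PG",
                        first_season = 2000L) {
  data.frame(player_id = id, season = first_season + seq_along(ages) - 1L,
             age = ages, performance = perf,
             mp_per_game = rep_len(mp, length(ages)),
             position = rep_len(pos, length(ages)), stringsAsFactors = FALSE)
}

toy_careers <- function(...) career_table(rbind(...), metric = "performance")

write_fixture_csv <- function(df, metric = "ws") {
  names(df)[names(df) == "performance"] <- metric
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
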