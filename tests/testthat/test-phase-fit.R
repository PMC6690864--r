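test_that("a hierarchical exponential phase fit recovers the generating slope", {
  sim <- simulate_careers(sim_config(n_players = 200, noise_sd = 0.01,
                                     slope_sds = c(0.02, 0.2), seed = 21))
  pre <- split_phases(sim$careers, 27)$prepeak
  fit <- fit_phase(pre, "exponential", phase = "prepeak",
                   config = quick_config(seed = 3))
  expect_true(fit$available)
  slope <- fit$summary[fit$summary$parameter == "slope", ]
  expect_lt(abs(slope$mean - 0.06), 0.005)
  # per-player slopes exist exactly for players with >= 2 pre-peak seasons
  n_pre <- table(pre$player_id)
  expect_setequal(fit$beta_by_player$player_id,
                  names(n_pre)[n_pre >= 2])
  expect_equal(fit$dic$dic, 2 * fit$dic$dbar - fit$dic$dhat,
               tolerance = 1e-12)
})

test_that("a pooled fit (random slopes off) matches OLS on the transformed scale", {
  sim <- simulate_careers(sim_config(n_players = 60, slope_sds = c(0, 0.2),
                                     slope_obs_sd = c(0, 0.12), seed = 22))
  pre <- split_phases(sim$careers, 27)$prepeak
  fit <- fit_phase(pre, "exponential", phase = "prepeak",
                   random_slopes = FALSE, offset = 0,
                   config = quick_config(seed = 4, n_samples = 600))
  expect_null(fit$beta_by_player)
  td <- linearize("exponential", pre, offset = 0)
  ols <- stats::coef(stats::lm(td$y ~ td$x))
  sl <- fit$summary[fit$summary$parameter == "slope", ]
  ic <- fit$summary[fit$summary$parameter == "intercept", ]
  d <- fit$samples$diagnostics
  mcse_sl <- stats::sd(as_draws_matrix(fit$samples, "mu_b")) /
    sqrt(d$ess[d$parameter == "mu_b"])
  expect_lt(abs(sl$mean - ols[2]), 4 * mcse_sl + 1e-6)
  expect_lt(abs(ic$mean - ols[1]), 0.02)
})

test_that("random slopes shrink a sparse player toward the population mean", {
  set.seed(30)
  # 30 well-observed players plus one noisy sparse player whose raw
  # least-squares slope sits a few population sds out
  base <- lapply(1:30, function(i) {
    ages <- 19:26
    player_rows(sprintf("p%02d", i), ages,
                exp(0.2 + stats::rnorm(1, 0.05, 0.01) * ages +
                      stats::rnorm(length(ages), 0, 0.05)))
  })
  out <- player_rows("out", 19:21,
                     exp(0.2 + 0.12 * (19:21) + c(0.05, -0.08, 0.1)))
  ct <- career_table(do.call(rbind, c(base, list(out))))
  fit <- fit_phase(ct, "exponential", phase = "prepeak", offset = 0,
                   config = quick_config(seed = 5))
  td <- linearize("exponential", ct, offset = 0)
  keep <- td$player_id == "out"
  raw_ols <- stats::coef(stats::lm(td$y[keep] ~ td$x[keep]))[2]
  mu_b <- fit$summary$mean[fit$summary$parameter == "slope"]
  bayes <- fit$beta_by_player$mean[fit$beta_by_player$player_id == "out"]
  expect_lt(abs(bayes - mu_b), abs(raw_ols - mu_b))
})

test_that("compare_functions is deterministic and keeps failed fits visible", {
  sim <- simulate_careers(sim_config(n_players = 25, seed = 23))
  cfg <- quick_config(seed = 7, n_samples = 200)
  c1 <- compare_functions(sim$careers, families = c("exponential", "linear"),
                          config = cfg)
  c2 <- compare_functions(sim$careers, families = c("exponential", "linear"),
                          config = cfg)
  expect_equal(as.data.frame(c1), as.data.frame(c2))
  expect_equal(nrow(c1), 4L)
  expect_equal(sum(c1$best), 2L)
  expect_error(compare_functions(sim$careers, families = "linear"), "two")
})

test_that("an empty phase is reported as unavailable, not dropped", {
  short <- simulate_careers(sim_config(n_players = 10,
                                       age_entry_range = c(19, 20),
                                       career_length_range = c(3, 5),
                                       seed = 24))
  cmp <- compare_functions(short$careers,
                           families = c("exponential", "linear"),
                           config = quick_config(seed = 8, n_samples = 150))
  post <- cmp[cmp$phase == "postpeak", ]
  expect_equal(nrow(post), 2L)
  expect_true(all(!post$available))
  expect_true(all(is.na(post$dic)))
})

test_that("DIC ranking is invariant to player relabeling", {
  sim <- simulate_careers(sim_config(n_players = 30, seed = 25))
  cfg <- quick_config(seed = 9, n_samples = 250)
  fams <- c("exponential", "linear")
  c1 <- compare_functions(sim$careers, families = fams, config = cfg)
  relabeled <- as.data.frame(sim$careers)
  ids <- unique(relabeled$player_id)
  new_ids <- stats::setNames(sprintf("z%03d", rev(seq_along(ids))), ids)
  relabeled$player_id <- unname(new_ids[relabeled$player_id])
  c2 <- compare_functions(career_table(relabeled), families = fams,
                          config = cfg)
  for (ph in c("prepeak", "postpeak")) {
    expect_equal(c1$family[c1$phase == ph & c1$best],
                 c2$family[c2$phase == ph & c2$best])
  }
})
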