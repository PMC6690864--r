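test_that("model 1 output structure honours the latent-variable contracts", {
  sim <- simulate_careers(sim_config(n_players = 50, seed = 41))
  cov <- aggregate_covariates(sim$careers)
  fit <- fit_bianus_model1(sim$careers, covariates = cov,
                           config = quick_config(seed = 13))
  # loadings of the slope indicators are constants, not sampled
  expect_identical(fit$latent$lambda, c(lambda1 = 1, lambda2 = 1))
  # rho is a correlation in every draw
  rho_draws <- as.numeric(fit$samples$draws[["rho"]])
  expect_true(all(rho_draws >= -1 & rho_draws <= 1))
  # latent scores cover exactly the players in the data
  expect_setequal(fit$latent$phi1_by_player$player_id,
                  unique(sim$careers$player_id))
  expect_equal(nrow(fit$latent$gamma), 4L)
  # both phase DICs obey the identity
  for (ph in c("prepeak", "postpeak")) {
    dic <- fit[[ph]]$dic
    expect_equal(dic$dic, 2 * dic$dbar - dic$dhat, tolerance = 1e-12)
  }
  # sign conventions: posterior factor scores track the true rates
  tr <- sim$truth[match(fit$latent$phi1_by_player$player_id,
                        sim$truth$player_id), ]
  expect_gt(stats::cor(fit$latent$phi1_by_player$mean, tr$beta1), 0.5)
  expect_gt(stats::cor(fit$latent$phi2_by_player$mean, tr$beta2), 0.5)
})

test_that("model 1 requires covariates for every player", {
  sim <- simulate_careers(sim_config(n_players = 12, seed = 42))
  cov <- aggregate_covariates(sim$careers)
  cov_missing <- cov[-3, ]
  expect_error(fit_bianus_model1(sim$careers, covariates = cov_missing),
               cov$player_id[3])
  expect_error(fit_bianus_model1(sim$careers,
                                 covariates = cov[, c("player_id", "X1")]),
               "X2")
})

test_that("a null factor correlation is covered by the rho interval", {
  sim <- simulate_careers(sim_config(n_players = 80, rho = 0, seed = 43))
  cov <- aggregate_covariates(sim$careers)
  fit <- fit_bianus_model1(sim$careers, covariates = cov,
                           config = quick_config(seed = 14, n_samples = 500))
  expect_lt(fit$latent$rho$ci_low, 0)
  expect_gt(fit$latent$rho$ci_high, 0)
})

test_that("extract_interaction returns the rho summary and slope pairs", {
  sim <- simulate_careers(sim_config(n_players = 60, rho = 0.7, seed = 44))
  cov <- aggregate_covariates(sim$careers)
  fit <- fit_bianus_model1(sim$careers, covariates = cov,
                           config = quick_config(seed = 15, n_samples = 400))
  it <- extract_interaction(fit, force = TRUE)
  expect_equal(nrow(it$pairs), length(fit$players))
  expect_equal(nrow(it$pairs), nrow(fit$latent$phi1_by_player))
  expect_gt(it$empirical_correlation, 0)
  # a flagged fit refuses extraction unless forced
  if (!fit$converged) expect_error(extract_interaction(fit), "flags")
})

test_that("model 2 estimates the inflection and surfaces diagnostics", {
  sim <- simulate_careers(sim_config(n_players = 40, tau = 28,
                                     slope_means = c(0.35, -0.25),
                                     slope_sds = c(0.08, 0.08),
                                     intercepts = c(4, NA),
                                     noise_sd = 0.05,
                                     career_length_range = c(8, 18),
                                     seed = 45))
  cov <- aggregate_covariates(sim$careers, cutoff_age = 28)
  fit <- fit_bianus_model2(sim$careers, covariates = cov,
                           config = quick_config(seed = 16, n_samples = 500))
  tau_mean <- fit$summary$mean[fit$summary$parameter == "tau_mean"]
  expect_lt(abs(tau_mean - 28), 1)
  # convergence diagnostics are mandatory in the output
  expect_true(is.character(fit$flags))
  expect_true(is.logical(fit$converged))
  expect_true(all(c("rhat", "ess") %in% names(fit$samples$diagnostics)))
  expect_s3_class(fit$tau_by_player, "data.frame")
})

test_that("recovery_report is exact for an oracle fit and rejects foreign ids", {
  sim <- simulate_careers(sim_config(n_players = 20, seed = 46))
  tr <- sim$truth
  degenerate <- function(v) data.frame(player_id = tr$player_id, mean = v,
                                       ci_low = v, ci_high = v,
                                       stringsAsFactors = FALSE)
  oracle <- structure(list(
    latent = list(beta1_by_player = degenerate(tr$beta1),
                  beta2_by_player = degenerate(tr$beta2),
                  phi1_by_player = degenerate(tr$phi1),
                  phi2_by_player = degenerate(tr$phi2),
                  rho = data.frame(parameter = "rho",
                                   mean = attr(tr, "config")$rho,
                                   ci_low = attr(tr, "config")$rho,
                                   ci_high = attr(tr, "config")$rho)),
    players = tr$player_id), class = "bianus_fit")
  rep <- recovery_report(tr, oracle)
  expect_true(all(rep$bias == 0))
  expect_true(all(rep$rmse == 0))
  expect_true(all(rep$coverage == 1))

  foreign <- oracle
  foreign$latent$beta1_by_player$player_id <- paste0("zz",
    foreign$latent$beta1_by_player$player_id)
  expect_error(recovery_report(tr, foreign), "not in truth")
})
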