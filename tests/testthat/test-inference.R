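# The conjugate normal-mean model is the workhorse fixture: y_i ~ N(mu,
# sigma0) with known sigma0 and mu ~ N(m0, s0) has a closed-form posterior,
# so the sampler can be checked against exact numbers.
conjugate_model <- function(y, sigma0 = 1, m0 = 0, s0 = 10) {
  code <- "model {
    for (i in 1:N) { y[i] ~ dnorm(mu, t0) }
    mu ~ dnorm(m0, pm)
  }"
  bianus_model(code, list(y = y, N = length(y), t0 = 1 / sigma0^2,
                          m0 = m0, pm = 1 / s0^2), params = "mu",
               inits = function(chain) list(mu = c(-5, 5, -2, 2)[chain]))
}

conjugate_posterior <- function(y, sigma0 = 1, m0 = 0, s0 = 10) {
  prec <- 1 / s0^2 + length(y) / sigma0^2
  list(mean = (m0 / s0^2 + sum(y) / sigma0^2) / prec, sd = sqrt(1 / prec))
}

test_that("sample_posterior recovers a conjugate normal-mean posterior", {
  set.seed(1)
  y <- stats::rnorm(25, 3, 1)
  post <- conjugate_posterior(y)
  s <- sample_posterior(conjugate_model(y), quick_config(seed = 2,
                                                         n_samples = 500))
  est <- mean(as_draws_matrix(s, "mu"))
  ess <- s$diagnostics$ess[s$diagnostics$parameter == "mu"]
  expect_lt(abs(est - post$mean), 3 * post$sd / sqrt(ess))
  expect_equal(stats::sd(as_draws_matrix(s, "mu")), post$sd, tolerance = 0.15)
  # chains start far apart but agree on a well-identified model
  expect_lt(s$diagnostics$rhat[s$diagnostics$parameter == "mu"], 1.01)
  expect_true(s$converged)
})

test_that("sampling is reproducible given seed and config", {
  y <- c(1.2, 0.7, 2.4, 1.9)
  cfg <- quick_config(seed = 9, n_samples = 200)
  s1 <- sample_posterior(conjugate_model(y), cfg)
  s2 <- sample_posterior(conjugate_model(y), cfg)
  expect_identical(s1$draws, s2$draws)
  s3 <- sample_posterior(conjugate_model(y), quick_config(seed = 10,
                                                          n_samples = 200))
  expect_false(identical(s1$draws, s3$draws))
})

test_that("an unsamplable model is an initialization error", {
  bad <- bianus_model("model { y ~ dnorm(mu, -1) \n mu ~ dnorm(0, 1) }",
                      list(y = 1), "mu")
  expect_error(sample_posterior(bad, quick_config()), "initialization")
})

fake_samples <- function(draws_list, n_chains = 2L) {
  structure(list(draws = draws_list,
                 diagnostics = data.frame(parameter = names(draws_list),
                                          rhat = 1, ess = 1000),
                 flags = character(0), converged = TRUE,
                 config = mcmc_config(n_chains = n_chains, seed = 1)),
            class = "posterior_samples")
}

test_that("summarize_draws applies the type-7 quantile rule and pools chains", {
  s <- fake_samples(list(theta = matrix(1:100, nrow = 2, byrow = TRUE)))
  out <- summarize_draws(s, "theta")
  expect_equal(out$mean, 50.5)
  expect_equal(out$ci_low, 3.475)   # quantile(1:100, 0.025, type = 7)
  expect_equal(out$ci_high, 97.525)

  const <- fake_samples(list(c0 = matrix(4.2, 2, 50)))
  expect_equal(unlist(summarize_draws(const, "c0")[, c("mean", "ci_low",
                                                       "ci_high")]),
               c(mean = 4.2, ci_low = 4.2, ci_high = 4.2))

  # invariance to the order in which chains are concatenated
  m <- matrix(stats::rnorm(200), nrow = 2)
  expect_equal(summarize_draws(fake_samples(list(x = m)), "x")[, -1],
               summarize_draws(fake_samples(list(x = m[2:1, ])), "x")[, -1])

  expect_error(summarize_draws(s, "nope"), "unknown parameter")
})

test_that("split_rhat flags separated chains and passes mixed ones", {
  set.seed(3)
  apart <- rbind(stats::rnorm(400, 0, 0.1), stats::rnorm(400, 5, 0.1))
  expect_gt(split_rhat(apart), 2)
  mixed <- matrix(stats::rnorm(800), nrow = 2)
  expect_lt(split_rhat(mixed), 1.02)
  expect_equal(split_rhat(matrix(7, 2, 100)), 1)
})

test_that("compute_dic obeys its identity and degenerates correctly", {
  dev_fn <- function(draw) unname(draw["theta"])^2 + 10
  degen <- fake_samples(list(theta = matrix(2, 2, 100)))
  dic <- compute_dic(degen, dev_fn)
  expect_equal(dic$pd, 0)
  expect_equal(dic$dic, dic$dhat)

  spread <- fake_samples(list(theta = matrix(stats::rnorm(400), 2)))
  dic2 <- compute_dic(spread, dev_fn)
  expect_equal(dic2$dic, 2 * dic2$dbar - dic2$dhat, tolerance = 1e-12)
  expect_gt(dic2$pd, 0)

  bad <- fake_samples(list(theta = matrix(c(1, NA, 1, 1), 2)))
  expect_error(compute_dic(bad, dev_fn), "non-finite deviance")
})

test_that("pD is about one free parameter on the conjugate fixture", {
  set.seed(5)
  y <- stats::rnorm(40, 1, 1)
  s <- sample_posterior(conjugate_model(y), quick_config(seed = 6,
                                                         n_samples = 800))
  dev_fn <- function(draw) {
    -2 * sum(stats::dnorm(y, unname(draw["mu"]), 1, log = TRUE))
  }
  dic <- compute_dic(s, dev_fn)
  expect_equal(dic$pd, 1, tolerance = 0.25)
})

test_that("extract_vector reassembles indexed parameters in order", {
  draw <- c("b[2]" = 20, "b[10]" = 100, "b[1]" = 10, sigma = 0.5)
  expect_equal(extract_vector(draw, "b"), c(10, 20, 100))
  expect_equal(extract_vector(draw, "sigma"), 0.5)
  expect_error(extract_vector(draw, "zz"), "no elements")
})
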