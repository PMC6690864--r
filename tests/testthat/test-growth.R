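test_that("the four families evaluate to their closed forms", {
  expect_equal(predict(age_function("linear", 2, 0.5), 4), 4.0,
               tolerance = 1e-12)
  expect_equal(predict(age_function("power", 3.7, -1.3), 1), 3.7,
               tolerance = 1e-12)
  expect_equal(predict(age_function("exponential", 2.5, 0), c(19, 30, 41)),
               rep(2.5, 3), tolerance = 1e-12)
  expect_equal(predict(age_function("logistic", 1, 0, delta = 10), 33), 5.0,
               tolerance = 1e-12)
  # spot values against explicit arithmetic
  expect_equal(predict(age_function("power", 2, 0.5), 9), 2 * 3,
               tolerance = 1e-12)
  expect_equal(predict(age_function("exponential", 1.2, 0.05), 20),
               1.2 * exp(1), tolerance = 1e-12)
})

test_that("age_function enforces its parameter invariants", {
  expect_error(age_function("logistic", 1, 1), "delta")
  expect_error(age_function("logistic", 1, 1, delta = -2), "delta")
  expect_error(age_function("power", 1, 1, delta = 3), "logistic")
  expect_error(predict(age_function("power", 1, 1), c(2, 0)), "age > 0")
})

test_that("evaluate is monotone in age when beta has fixed sign", {
  ages <- seq(18, 40, by = 0.5)
  for (fam in c("linear", "exponential", "power")) {
    up <- predict(age_function(fam, 1.5, 0.2), ages)
    dn <- predict(age_function(fam, 1.5, -0.2), ages)
    expect_true(all(diff(up) > 0), info = fam)
    expect_true(all(diff(dn) < 0), info = fam)
  }
})

test_that("linearize maps known values and reports inadequate offsets", {
  # a plain data frame exercises the pure transform (ages need not be
  # career-plausible here)
  ct <- data.frame(player_id = "a", age = c(1, exp(1)),
                   performance = c(exp(1), exp(2)))
  td <- linearize("power", ct, offset = 0)
  expect_equal(td$y, c(1, 2), tolerance = 1e-12)
  expect_equal(td$x, c(0, 1), tolerance = 1e-12)
  expect_identical(td$transform_kind, "log_log")

  td2 <- linearize("exponential", ct, offset = 0)
  expect_equal(td2$x, ct$age)
  expect_identical(td2$transform_kind, "log_linear")

  ct_neg <- toy_careers(player_rows("a", 20:22, c(2, -1.2, 3)))
  expect_error(linearize("power", ct_neg, offset = 0), "1\\.3")
})

test_that("back_transform inverts linearize on random tables", {
  set.seed(42)
  for (rep in 1:100) {
    fam <- sample(c("power", "exponential"), 1)
    perf <- stats::runif(12, -2, 10)
    ct <- toy_careers(player_rows("a", 19:30, perf))
    td <- linearize(fam, ct)
    expect_equal(back_transform(td), perf, tolerance = 1e-10)
  }
})

test_that("the power family is exactly affine after the log-log transform", {
  f <- age_function("power", 2.3, -0.7)
  ct <- toy_careers(player_rows("a", 19:35, predict(f, 19:35)))
  td <- linearize("power", ct, offset = 0)
  ols <- stats::lm(td$y ~ td$x)
  expect_equal(unname(stats::coef(ols)[2]), -0.7, tolerance = 1e-12)
  expect_equal(unname(stats::coef(ols)[1]), log(2.3), tolerance = 1e-12)
})

test_that("log_likelihood matches closed forms and a brute-force oracle", {
  f <- age_function("exponential", exp(0.5), 0.04)
  ct <- toy_careers(player_rows("a", 20:24, exp(0.5 + 0.04 * (20:24))))
  td <- linearize("exponential", ct, offset = 0)
  # zero residuals: n times the log-density at zero
  expect_equal(log_likelihood(f, 0.3, td, c(a = 0.04)),
               5 * stats::dnorm(0, sd = 0.3, log = TRUE), tolerance = 1e-12)
  # single observation at its mean
  ct1 <- toy_careers(player_rows("a", 20, exp(0.5 + 0.04 * 20)))
  td1 <- linearize("exponential", ct1, offset = 0)
  expect_equal(log_likelihood(f, 0.7, td1, c(a = 0.04)),
               -0.5 * log(2 * pi * 0.7^2), tolerance = 1e-12)

  # random instance vs naive per-point summation with per-player slopes
  set.seed(7)
  df <- rbind(player_rows("a", 20:23, stats::runif(4, 1, 5)),
              player_rows("b", 25:29, stats::runif(5, 1, 5)))
  ct2 <- career_table(df)
  td2 <- linearize("power", ct2, offset = 0)
  slopes <- c(a = 0.3, b = -0.2)
  naive <- 0
  for (i in seq_along(td2$y)) {
    mu_i <- log(2.3) + slopes[td2$player_id[i]] * td2$x[i]
    naive <- naive + stats::dnorm(td2$y[i], mu_i, 0.5, log = TRUE)
  }
  expect_equal(log_likelihood(age_function("power", 2.3, 0), 0.5, td2, slopes),
               unname(naive), tolerance = 1e-12)

  fp <- age_function("power", 2.3, 0)
  expect_error(log_likelihood(fp, 0.3, td2, c(a = 0.3)), "player")
  expect_error(log_likelihood(f, 0.3, td2, slopes), "does not match")
  expect_error(log_likelihood(f, -1, td1, c(a = 1)), "sigma")
})

test_that("log_likelihood is maximized at the OLS solution on the transformed scale", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(8:20, 1)
    ages <- sample(19:40, n)
    perf <- exp(stats::rnorm(n, 1 + 0.05 * ages, 0.3))
    ct <- toy_careers(player_rows("a", seq_len(n) + 18, perf))
    ct$age <- ages  # decouple age from the row index
    td <- linearize("exponential", ct, offset = 0)
    ols <- stats::coef(stats::lm(td$y ~ td$x))
    at_ols <- log_likelihood(age_function("exponential", exp(ols[1]), 0),
                             0.4, td, unname(ols[2]))
    for (eps in c(-0.01, 0.01)) {
      expect_lt(log_likelihood(age_function("exponential", exp(ols[1] + eps), 0),
                               0.4, td, unname(ols[2])), at_ols)
      expect_lt(log_likelihood(age_function("exponential", exp(ols[1]), 0),
                               0.4, td, unname(ols[2]) + eps), at_ols)
    }
  }
})

test_that("default_offset shifts the minimum to the floor", {
  expect_equal(default_offset(c(-1.2, 3)), 1.3)
  expect_equal(default_offset(c(0.5, 3)), 0)
  expect_equal(default_offset(c(0.02, 3)), 0.08)
})
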