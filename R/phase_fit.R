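# Hierarchical per-phase fits of the age-change families, and DIC-based
# comparison across families. Linearizable families (power, exponential,
# linear) are fit as Gaussian regressions on the transformed scale; the
# logistic family has no linearization and is fit on the raw scale.

.slope_index <- function(player_id, min_seasons, random_slopes) {
  players <- sort(unique(player_id))
  n_seasons <- table(player_id)[players]
  if (!random_slopes) {
    return(list(players_random = character(0), pooled = players,
                idx = rep(1L, length(player_id)), P = 0L))
  }
  random_p <- players[n_seasons >= min_seasons]
  idx_map <- stats::setNames(seq_along(random_p), random_p)
  P <- length(random_p)
  idx <- ifelse(player_id %in% random_p, idx_map[player_id], P + 1L)
  list(players_random = random_p, pooled = setdiff(players, random_p),
       idx = as.integer(idx), P = P)
}

# The sampler works in a centered parameterization -- level at the mean of x
# plus zero-centered per-player slope deviations -- which is the same joint
# model as intercept + per-player slopes but without the near-flat ridge
# between the intercept and the mean slope when x (age or log age) sits far
# from 0. The raw-scale intercept is recovered as a derived node.
.phase_code_linearized <- function(random_slopes, random_intercepts) {
  slope_block <- if (random_slopes) "
  for (p in 1:P) {
    d[p] ~ dnorm(0, tb)
    du[p] <- d[p]
    b[p] <- mu_b + d[p]
  }
  du[P+1] <- 0
  sb ~ dnorm(0, 1) T(0,)
  tb <- pow(sb, -2)" else "
  b1 <- mu_b"
  mu_line <- if (random_slopes) "lvl[i] + mu_b * (x[i] - xbar) + du[pb[i]] * x[i]"
             else "lvl[i] + b1 * (x[i] - xbar)"
  int_block <- if (random_intercepts) "
  for (q in 1:Q) {
    adev[q] ~ dnorm(0, ta)
    a[q] <- alpha + adev[q]
  }
  sa ~ dnorm(0, 1) T(0,)
  ta <- pow(sa, -2)" else ""
  lvl_line <- if (random_intercepts) "cc + adev[pa[i]]" else "cc"
  paste0("model {
  for (i in 1:N) {
    lvl[i] <- ", lvl_line, "
    y[i] ~ dnorm(", mu_line, ", ty)
  }", slope_block, int_block, "
  cc ~ dnorm(0, 0.01)
  alpha <- cc - mu_b * xbar
  mu_b ~ dnorm(0, 0.01)
  sigma ~ dnorm(0, 1) T(0,)
  ty <- pow(sigma, -2)
}")
}

.phase_code_logistic <- function(random_slopes) {
  slope_block <- if (random_slopes) "
  for (p in 1:P) { b[p] ~ dnorm(mu_b, tb) }
  b[P+1] <- mu_b
  sb ~ dnorm(0, 1) T(0,)
  tb <- pow(sb, -2)" else "
  b1 <- mu_b"
  b_line <- if (random_slopes) "b[pb[i]]" else "b1"
  paste0("model {
  for (i in 1:N) {
    mu[i] <- delta / (1 + exp(la + ", b_line, " * x[i]))
    y[i] ~ dnorm(mu[i], ty)
  }", slope_block, "
  delta ~ dnorm(0, 1.0E-4) T(0,)
  la ~ dnorm(0, 0.01)
  mu_b ~ dnorm(0, 0.04)
  sigma ~ dnorm(0, 1) T(0,)
  ty <- pow(sigma, -2)
}")
}

# OLS starting values. A pooled least-squares line (on centered x) seeds the
# level and mean slope, per-player least-squares slopes seed the slope
# deviations; chains get a small deterministic jitter on the mean slope so
# split-R-hat retains power against real non-convergence. Starting the chains
# in the high-posterior region matters because the level/mean-slope exchange
# is the slowest direction of this posterior.
.player_ols_dev <- function(td, players, mu0) {
  vapply(players, function(p) {
    rows <- td$player_id == p
    x <- td$x[rows]; y <- td$y[rows]
    if (length(x) < 2L || stats::var(x) == 0) return(0)
    b <- stats::cov(x, y) / stats::var(x)
    if (!is.finite(b)) 0 else b - mu0
  }, numeric(1))
}

.ols_inits <- function(td, si, random_slopes) {
  xc <- td$x - mean(td$x)
  co <- stats::lm.fit(cbind(1, xc), td$y)$coefficients
  cc0 <- unname(co[1]); mu0 <- unname(co[2])
  sigma0 <- max(stats::sd(td$y - cc0 - mu0 * xc), 1e-3)
  d0 <- if (random_slopes && si$P > 0L) {
    unname(.player_ols_dev(td, si$players_random, mu0))
  }
  function(chain) {
    jit <- c(-1, 1, -0.5, 0.5, 0.25, -0.25)[(chain - 1L) %% 6L + 1L]
    ini <- list(cc = cc0, mu_b = mu0 * (1 + 0.05 * jit) + 0.002 * jit,
                sigma = sigma0)
    if (!is.null(d0)) ini$d <- d0
    ini
  }
}

# Deviance of the observed raw performance given one posterior draw. For
# log-scale fits the log-normal Jacobian (-sum(y)) puts the deviance on the
# raw-data scale, so DIC values are comparable across families fit on
# different scales.
.make_phase_deviance <- function(family, td, raw_perf, idx, random_slopes,
                                 a_idx = NULL) {
  force(family); force(td); force(raw_perf); force(idx)
  force(random_slopes); force(a_idx)
  jac <- if (td$transform_kind == "identity") 0 else 2 * sum(td$y)
  function(draw) {
    sigma <- unname(draw["sigma"])
    b_i <- if (random_slopes) {
      c(extract_vector(draw, "b"), unname(draw["mu_b"]))[idx]
    } else rep(unname(draw["b1"]), length(td$x))
    if (family == "logistic") {
      mu <- unname(draw["delta"]) / (1 + exp(unname(draw["la"]) + b_i * td$x))
      return(-2 * sum(stats::dnorm(raw_perf, mu, sigma, log = TRUE)))
    }
    a_i <- if (is.null(a_idx)) unname(draw["alpha"])
           else extract_vector(draw, "a")[a_idx]
    mu <- a_i + b_i * td$x
    -2 * sum(stats::dnorm(td$y, mu, sigma, log = TRUE)) + jac
  }
}

#' Fit one career phase with a hierarchical age-change model
#'
#' Fits a single function family to one phase (pre-peak or post-peak) of a
#' career table. Linearizable families (power, exponential, linear) are fit
#' as Gaussian regressions on the transformed scale — a global intercept, a
#' population mean slope, and (by default) per-player slope deviations drawn
#' from a superordinate normal. The logistic family is fit on the raw scale
#' (it has no linearization) and is allowed to fail gracefully: a
#' non-estimable fit is returned with `available = FALSE` and a diagnostic
#' message rather than a number.
#'
#' Players with fewer than `min_seasons` seasons in the phase do not receive
#' an individual slope (a random slope is not identifiable from one point
#' without full pooling); their rows are pooled to the population slope.
#'
#' @param data A `career_table` holding the rows of one phase (e.g. one
#'   element of [split_phases()]).
#' @param family One of `"power"`, `"exponential"`, `"logistic"`, `"linear"`.
#' @param phase Label, `"prepeak"` or `"postpeak"`.
#' @param random_slopes Adjust the slope per player (default TRUE).
#' @param random_intercepts Adjust the intercept per player (default FALSE;
#'   slope adjustment alone is usually sufficient).
#' @param offset Log-offset for the performance metric; default
#'   [default_offset()].
#' @param min_seasons Minimum seasons in the phase for an individual slope.
#' @param config An [mcmc_config()].
#' @return A `phase_fit`: `summary` rows for `intercept`, `slope` (population
#'   mean), `sigma`; `beta_by_player` (posterior mean and 95% CI per
#'   individually adjusted player); `dic` (a `dic_result`); `samples`;
#'   `transform` metadata; `available`; `flags`.
#' @export
fit_phase <- function(data, family, phase = c("prepeak", "postpeak"),
                      random_slopes = TRUE, random_intercepts = FALSE,
                      offset = NULL, min_seasons = 2L,
                      config = mcmc_config()) {
  phase <- match.arg(phase)
  stopifnot(inherits(data, "career_table"))
  if (nrow(data) == 0L) stop("phase '", phase, "' has no rows")
  family <- match.arg(family, c("power", "exponential", "logistic", "linear"))

  si <- .slope_index(data$player_id, min_seasons, random_slopes)
  if (random_slopes && si$P == 0L) {
    random_slopes <- FALSE
    si <- .slope_index(data$player_id, min_seasons, FALSE)
  }
  fail <- function(msg) {
    structure(list(phase = phase, family = family, available = FALSE,
                   message = msg, summary = NULL, beta_by_player = NULL,
                   dic = NULL, samples = NULL, flags = "fit unavailable"),
              class = "phase_fit")
  }

  if (family == "logistic") {
    if (is.null(offset)) offset <- default_offset(data$performance)
    td <- structure(list(y = data$performance + offset, x = as.numeric(data$age),
                         player_id = data$player_id, age = as.numeric(data$age),
                         offset = offset, transform_kind = "identity",
                         family = family), class = "transformed_data")
    code <- .phase_code_logistic(random_slopes)
    jd <- list(N = length(td$y), y = td$y, x = td$x)
    inits <- function(chain) list(delta = max(td$y) * 1.5, la = 2, mu_b = 0)
  } else {
    td <- linearize(family, data, offset = offset)
    code <- .phase_code_linearized(random_slopes, random_intercepts)
    jd <- list(N = length(td$y), y = td$y, x = td$x, xbar = mean(td$x))
    inits <- .ols_inits(td, si, random_slopes)
  }
  if (random_slopes) {
    jd$P <- si$P
    jd$pb <- si$idx
  }
  if (random_intercepts && family != "logistic") {
    players_all <- sort(unique(data$player_id))
    jd$Q <- length(players_all)
    jd$pa <- match(data$player_id, players_all)
  }
  params <- c("alpha", "mu_b", "sigma",
              if (random_slopes) c("b", "sb") else "b1",
              if (random_intercepts && family != "logistic") c("a", "sa"),
              if (family == "logistic") c("delta", "la"))
  if (family == "logistic") params <- setdiff(params, "alpha")

  samples <- tryCatch(
    sample_posterior(bianus_model(code, jd, params, inits), config),
    error = function(e) conditionMessage(e))
  if (is.character(samples)) return(fail(samples))

  a_idx <- if (random_intercepts && family != "logistic") jd$pa else NULL
  dev_fn <- .make_phase_deviance(family, td, data$performance, si$idx,
                                 random_slopes, a_idx = a_idx)
  dic <- tryCatch(compute_dic(samples, dev_fn), error = function(e) NULL)
  if (is.null(dic)) return(fail("deviance not finite over posterior draws"))

  sm <- summarize_draws(samples)
  pick <- function(nm, label) {
    row <- sm[sm$parameter == nm, , drop = FALSE]
    if (nrow(row)) row$parameter <- label
    row
  }
  summary_tab <- rbind(
    if (family != "logistic") pick("alpha", "intercept"),
    pick("mu_b", "slope"), pick("sigma", "sigma"),
    if (family == "logistic") pick("delta", "delta"),
    if (family == "logistic") pick("la", "log_alpha"))

  beta_by_player <- NULL
  if (random_slopes && si$P > 0L) {
    bnames <- paste0("b[", seq_len(si$P), "]")
    bsum <- summarize_draws(samples, bnames)
    beta_by_player <- data.frame(player_id = si$players_random,
                                 mean = bsum$mean, ci_low = bsum$ci_low,
                                 ci_high = bsum$ci_high,
                                 stringsAsFactors = FALSE)
  }

  structure(list(phase = phase, family = family, available = TRUE,
                 message = NULL, summary = summary_tab,
                 beta_by_player = beta_by_player,
                 pooled_players = si$pooled, dic = dic, samples = samples,
                 transform = td[c("offset", "transform_kind", "family")],
                 flags = samples$flags, config = config),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  if (!x$available) {
    cat(sprintf("<phase_fit> %s / %s: NA (estimate not available): %s\n",
                x$phase, x$family, x$message))
    return(invisible(x))
  }
  cat(sprintf("<phase_fit> %s / %s, DIC %.2f\n", x$phase, x$family, x$dic$dic))
  print(x$summary, row.names = FALSE)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = " | "), "\n")
  invisible(x)
}

#' Compare age-change function families by DIC
#'
#' Splits the careers at the cutoff age, fits every requested family to each
#' phase, and tabulates the DIC. All deviances are computed on the observed
#' raw-performance scale (with the log-normal Jacobian for log-scale fits) so
#' the values are comparable across families. The lowest-DIC family per
#' phase is flagged `best`; fits that could not be estimated appear with
#' `available = FALSE` and `NA` DIC rather than being dropped.
#'
#' @param data A `career_table`.
#' @param cutoff Cutoff age (default 27).
#' @param families At least two of the four family names.
#' @param config An [mcmc_config()].
#' @param offset Shared log-offset; default [default_offset()] of the data.
#' @param ... Passed to [fit_phase()] (e.g. `random_slopes`, `min_seasons`).
#' @return A `function_comparison` data frame: `phase`, `family`, `dic`,
#'   `pd`, `available`, `best`, with the fits in `attr(, "fits")`.
#' @export
compare_functions <- function(data, cutoff = 27L,
                              families = c("power", "exponential",
                                           "logistic", "linear"),
                              config = mcmc_config(), offset = NULL, ...) {
  stopifnot(inherits(data, "career_table"))
  families <- match.arg(families, c("power", "exponential", "logistic",
                                    "linear"), several.ok = TRUE)
  if (length(families) < 2L) stop("need at least two families to compare")
  if (is.null(offset)) offset <- default_offset(data$performance)
  ph <- split_phases(data, cutoff)
  rows <- list(); fits <- list()
  for (phase in c("prepeak", "postpeak")) {
    pd <- ph[[phase]]
    for (fam in families) {
      fit <- if (nrow(pd) == 0L) {
        structure(list(phase = phase, family = fam, available = FALSE,
                       message = "phase empty", dic = NULL),
                  class = "phase_fit")
      } else {
        tryCatch(fit_phase(pd, fam, phase = phase, offset = offset,
                           config = config, ...),
                 error = function(e) {
                   structure(list(phase = phase, family = fam,
                                  available = FALSE,
                                  message = conditionMessage(e), dic = NULL),
                             class = "phase_fit")
                 })
      }
      fits[[paste(phase, fam, sep = ".")]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        phase = phase, family = fam,
        dic = if (fit$available) fit$dic$dic else NA_real_,
        pd = if (fit$available) fit$dic$pd else NA_real_,
        available = fit$available, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  for (phase in c("prepeak", "postpeak")) {
    in_ph <- out$phase == phase & !is.na(out$dic)
    if (any(in_ph)) {
      out$best[which(in_ph)[which.min(out$dic[in_ph])]] <- TRUE
    }
  }
  structure(out, fits = fits, cutoff = cutoff, offset = offset,
            class = c("function_comparison", "data.frame"))
}
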