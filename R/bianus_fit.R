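# The two-phase latent-variable model. Per-player rates of pre-peak growth
# (beta_1p) and post-peak decline (beta_2p) are indicators (loading fixed at
# 1) of latent development and aging factors (phi_1p, phi_2p), which are
# bivariate normal with correlation rho. Phase-aggregated covariates (minutes
# per game) and position load onto the factors through weight (gamma)
# parameters. Model 1 splits the career at a fixed cutoff age and has one
# likelihood per phase; Model 2 has a single likelihood with a per-player
# Heaviside changepoint.

# Sampled in centered form: phi1c/phi2c are factor deviations around the
# population slope means and d1/d2 the matching slope deviations, so the
# factor-mean / global-intercept ridge of the raw parameterization is never
# visited. phi/b on the natural scale are derived nodes.
.latent_block <- "
  for (p in 1:P) {
    phi1c[p] ~ dnorm(0, tphi1)
    phi2c[p] ~ dnorm(rho * (sphi2 / sphi1) * phi1c[p], tcond)
    d1[p] ~ dnorm(phi1c[p], tm1)
    d2[p] ~ dnorm(phi2c[p], tm2)
    X1[p] ~ dnorm(kx1 + gx1 * phi1c[p], txx1)
    X2[p] ~ dnorm(kx2 + gx2 * phi2c[p], txx2)
    Z[p] ~ dnorm(kz + gz1 * phi1c[p] + gz2 * phi2c[p], tzz)
    phi1[p] <- mu1 + phi1c[p]
    phi2[p] <- mu2 + phi2c[p]
    b1[p] <- mu1 + d1[p]
    b2[p] <- mu2 + d2[p]
    du1[p] <- d1[p]
    du2[p] <- d2[p]
  }
  du1[P+1] <- 0
  du2[P+1] <- 0
  mu1 ~ dnorm(0, 0.01)
  mu2 ~ dnorm(0, 0.01)
  rho ~ dunif(-1, 1)
  sphi1 ~ dnorm(0, 1) T(0,)
  sphi2 ~ dnorm(0, 1) T(0,)
  sm1 ~ dnorm(0, 1) T(0,)
  sm2 ~ dnorm(0, 1) T(0,)
  kx1 ~ dnorm(0, 1); kx2 ~ dnorm(0, 1); kz ~ dnorm(0, 1)
  gx1 ~ dnorm(0, 0.01); gx2 ~ dnorm(0, 0.01)
  gz1 ~ dnorm(0, 0.01); gz2 ~ dnorm(0, 0.01)
  sx1 ~ dnorm(0, 1) T(0.1,); sx2 ~ dnorm(0, 1) T(0.1,)
  sz ~ dnorm(0, 1) T(0.1,)
  tphi1 <- pow(sphi1, -2)
  tcond <- pow(sphi2, -2) / (1 - rho * rho)
  tm1 <- pow(sm1, -2); tm2 <- pow(sm2, -2)
  txx1 <- pow(sx1, -2); txx2 <- pow(sx2, -2)
  tzz <- pow(sz, -2)
"

.model1_code <- paste0("model {
  for (i in 1:N1) {
    y1[i] ~ dnorm(c1 + mu1 * (x1[i] - xbar1) + du1[pb1[i]] * x1[i], ty1)
  }
  for (i in 1:N2) {
    y2[i] ~ dnorm(c2 + mu2 * (x2[i] - xbar2) + du2[pb2[i]] * x2[i], ty2)
  }
", .latent_block, "
  c1 ~ dnorm(0, 0.01)
  c2 ~ dnorm(0, 0.01)
  a1 <- c1 - mu1 * xbar1
  a2 <- c2 - mu2 * xbar2
  sy1 ~ dnorm(0, 1) T(0,)
  sy2 ~ dnorm(0, 1) T(0,)
  ty1 <- pow(sy1, -2); ty2 <- pow(sy2, -2)
}")

.model2_code <- paste0("model {
  for (i in 1:N) {
    mu[i] <- a + (mu1 + du1[pq[i]]) * min(age[i] - tu[pq[i]], 0)
               + (mu2 + du2[pq[i]]) * max(age[i] - tu[pq[i]], 0)
    y[i] ~ dnorm(mu[i], ty)
  }
  for (q in 1:P) {
    tau[q] ~ dnorm(mtau, ttau) T(lo, hi)
    tu[q] <- tau[q]
  }
  tu[P+1] <- mtau
", .latent_block, "
  a ~ dnorm(0, 0.01)
  mtau ~ dunif(lo, hi)
  stau ~ dnorm(0, 0.25) T(0,)
  sy ~ dnorm(0, 1) T(0,)
  ttau <- pow(stau, -2); ty <- pow(sy, -2)
}")

.standardize <- function(v) {
  mu <- mean(v, na.rm = TRUE)
  sd <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(sd) || sd == 0) sd <- 1
  list(z = (v - mu) / sd, center = mu, scale = sd)
}

.check_covariates <- function(covariates, players) {
  stopifnot(is.data.frame(covariates))
  need <- c("player_id", "X1", "X2", "position_code")
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols)) {
    stop("covariates must have column(s): ", paste(missing_cols, collapse = ", "))
  }
  unmatched <- setdiff(players, covariates$player_id)
  if (length(unmatched)) {
    stop("no covariate row for player(s): ",
         paste(utils::head(unmatched, 10L), collapse = ", "),
         if (length(unmatched) > 10L) ", ...")
  }
  covariates[match(players, covariates$player_id), , drop = FALSE]
}

.latent_params <- c("mu1", "mu2", "rho", "sphi1", "sphi2", "sm1", "sm2",
                    "gx1", "gx2", "gz1", "gz2", "sx1", "sx2", "sz",
                    "b1", "b2", "phi1", "phi2")

.gamma_table <- function(samples, covariate_name) {
  g <- summarize_draws(samples, c("gx1", "gx2", "gz1", "gz2"))
  data.frame(covariate = c(covariate_name, covariate_name,
                           "position", "position"),
             factor = c("development", "aging", "development", "aging"),
             mean = g$mean, ci_low = g$ci_low, ci_high = g$ci_high,
             stringsAsFactors = FALSE)
}

.latent_structure <- function(samples, players, covariate_name) {
  P <- length(players)
  per <- function(base) {
    s <- summarize_draws(samples, paste0(base, "[", seq_len(P), "]"))
    data.frame(player_id = players, mean = s$mean, ci_low = s$ci_low,
               ci_high = s$ci_high, stringsAsFactors = FALSE)
  }
  rho_s <- summarize_draws(samples, "rho")
  flags <- character(0)
  rho_draws <- as.numeric(samples$draws[["rho"]])
  if (mean(abs(rho_draws) > 0.98) > 0.10) {
    flags <- c(flags, "rho posterior mass piles at +-1: correlation weakly identified")
  }
  list(rho = rho_s,
       gamma = .gamma_table(samples, covariate_name),
       phi1_by_player = per("phi1"), phi2_by_player = per("phi2"),
       beta1_by_player = per("b1"), beta2_by_player = per("b2"),
       measurement_sds = summarize_draws(samples, c("sm1", "sm2", "sx1",
                                                    "sx2", "sz")),
       lambda = c(lambda1 = 1, lambda2 = 1),
       flags = flags)
}

#' Fit the two-phase latent-variable model with a fixed cutoff (Model 1)
#'
#' Splits careers at `cutoff`, linearizes each phase under its function
#' family, and fits both phase likelihoods jointly with the latent
#' measurement model: per-player slopes `beta_1p`, `beta_2p` are indicators
#' (loadings fixed at 1) of latent development and aging factors whose
#' correlation is `rho`; the phase-aggregated covariate (minutes per game)
#' and the numeric position code load onto the factors through the gamma
#' weights. Covariate indicators are standardized internally; gammas are
#' reported per unit of latent factor on the standardized indicator scale.
#'
#' Players with fewer than `min_seasons` seasons in a phase contribute to
#' that phase through the population mean slope; missing covariate values
#' (e.g. no post-peak seasons) drop out of the measurement equations for that
#' player. Age enters in raw years on the transformed x-scale of each family
#' unless `center_age` is given, in which case the transform of that age is
#' subtracted from x (useful when a common peak age is assumed).
#'
#' @param data A `career_table`.
#' @param cutoff Cutoff age (default 27).
#' @param families Length-2 character vector `(pre, post)`; default
#'   exponential growth before the peak and power-law decline after it.
#'   `"linear"` is also accepted; the logistic family has no linearization
#'   and cannot be used here.
#' @param covariates A `covariate_summary` (from [aggregate_covariates()])
#'   aggregated at the same cutoff.
#' @param offset Log-offset; default [default_offset()] over the whole table.
#' @param min_seasons Minimum seasons per phase for an individual slope.
#' @param center_age Optional age whose transform is subtracted from x.
#' @param config An [mcmc_config()].
#' @return A `bianus_fit` with elements `prepeak`, `postpeak` (intercept /
#'   population slope / sigma summaries, per-player slopes, `dic`), `latent`
#'   (`rho`, `gamma`, factor scores, measurement sds), `samples`,
#'   `covariate_spec`, `flags`, `converged`.
#' @export
fit_bianus_model1 <- function(data, cutoff = 27L,
                              families = c(pre = "exponential", post = "power"),
                              covariates, offset = NULL, min_seasons = 2L,
                              center_age = NULL, config = mcmc_config()) {
  stopifnot(inherits(data, "career_table"), length(families) == 2L)
  fams <- match.arg(families, c("power", "exponential", "linear"),
                    several.ok = TRUE)
  if (length(fams) != 2L) fams <- rep(fams, 2L)
  players <- sort(unique(data$player_id))
  P <- length(players)
  cov <- .check_covariates(covariates, players)
  if (is.null(offset)) offset <- default_offset(data$performance)

  ph <- split_phases(data, cutoff)
  prep <- list()
  for (k in 1:2) {
    phase <- c("prepeak", "postpeak")[k]
    pd <- ph[[phase]]
    if (nrow(pd) == 0L) stop("phase '", phase, "' has no rows at cutoff ", cutoff)
    td <- linearize(fams[k], pd, offset = offset)
    if (!is.null(center_age)) {
      ctr <- switch(fams[k], power = log(center_age), center_age)
      td$x <- td$x - ctr
    }
    n_seasons <- table(pd$player_id)
    qual <- players %in% names(n_seasons)[n_seasons >= min_seasons]
    idx <- ifelse(qual[match(pd$player_id, players)],
                  match(pd$player_id, players), P + 1L)
    prep[[phase]] <- list(td = td, idx = as.integer(idx), qualified = qual,
                          raw = pd)
  }

  zx1 <- .standardize(cov$X1); zx2 <- .standardize(cov$X2)
  zz <- .standardize(cov$position_code)
  jd <- list(N1 = length(prep$prepeak$td$y), y1 = prep$prepeak$td$y,
             x1 = prep$prepeak$td$x, pb1 = prep$prepeak$idx,
             xbar1 = mean(prep$prepeak$td$x),
             N2 = length(prep$postpeak$td$y), y2 = prep$postpeak$td$y,
             x2 = prep$postpeak$td$x, pb2 = prep$postpeak$idx,
             xbar2 = mean(prep$postpeak$td$x),
             P = P, X1 = zx1$z, X2 = zx2$z, Z = zz$z)
  params <- c("a1", "a2", "sy1", "sy2", .latent_params)

  # OLS-seeded starting values: pooled lines give the levels and mean slopes,
  # per-player least-squares slopes seed the slope/factor deviations, so the
  # chains start inside the high-posterior region instead of crawling along
  # the level/mean-slope ridge during burn-in.
  ols_phase <- function(pp) {
    xc <- pp$td$x - mean(pp$td$x)
    co <- stats::lm.fit(cbind(1, xc), pp$td$y)$coefficients
    mu0 <- unname(co[2])
    d0 <- .player_ols_dev(pp$td, players, mu0)
    d0[!pp$qualified] <- 0
    d0 <- pmax(pmin(d0, 5), -5)
    list(c0 = unname(co[1]), mu0 = mu0, d0 = unname(d0))
  }
  o1 <- ols_phase(prep$prepeak); o2 <- ols_phase(prep$postpeak)
  rho0 <- stats::cor(o1$d0, o2$d0)
  if (!is.finite(rho0)) rho0 <- 0
  inits <- function(chain) {
    jit <- c(-1, 1, -0.5, 0.5, 0.25, -0.25)[(chain - 1L) %% 6L + 1L]
    list(c1 = o1$c0, c2 = o2$c0,
         mu1 = o1$mu0 * (1 + 0.05 * jit), mu2 = o2$mu0 * (1 + 0.05 * jit),
         d1 = o1$d0, d2 = o2$d0,
         phi1c = o1$d0, phi2c = o2$d0,
         rho = max(min(rho0, 0.9), -0.9))
  }
  samples <- sample_posterior(
    bianus_model(.model1_code, jd, params, inits), config)

  phase_out <- list()
  for (k in 1:2) {
    phase <- c("prepeak", "postpeak")[k]
    pp <- prep[[phase]]
    anm <- c("a1", "a2")[k]; snm <- c("sy1", "sy2")[k]
    bnm <- c("b1", "b2")[k]; mnm <- c("mu1", "mu2")[k]
    sm <- summarize_draws(samples, c(anm, mnm, snm))
    sm$parameter <- c("intercept", "slope", "sigma")
    qual_idx <- which(pp$qualified)
    bsum <- summarize_draws(samples, paste0(bnm, "[", qual_idx, "]"))
    dev_fn <- local({
      td <- pp$td; idx <- pp$idx
      jac <- if (td$transform_kind == "identity") 0 else 2 * sum(td$y)
      force(anm); force(snm); force(bnm); force(mnm)
      function(draw) {
        b_all <- c(extract_vector(draw, bnm), unname(draw[mnm]))
        mu <- unname(draw[anm]) + b_all[idx] * td$x
        -2 * sum(stats::dnorm(td$y, mu, unname(draw[snm]), log = TRUE)) + jac
      }
    })
    dic <- compute_dic(samples, dev_fn,
                       params = c(anm, snm, mnm,
                                  paste0(bnm, "[", seq_len(P), "]")))
    phase_out[[phase]] <- list(
      phase = phase, family = fams[k], summary = sm,
      beta_by_player = data.frame(player_id = players[qual_idx],
                                  mean = bsum$mean, ci_low = bsum$ci_low,
                                  ci_high = bsum$ci_high,
                                  stringsAsFactors = FALSE),
      dic = dic,
      transform = pp$td[c("offset", "transform_kind", "family")])
  }

  latent <- .latent_structure(samples, players,
                              attr(covariates, "covariate") %||% "covariate")
  flags <- c(samples$flags, latent$flags)
  structure(list(model = "model1", prepeak = phase_out$prepeak,
                 postpeak = phase_out$postpeak, latent = latent,
                 samples = samples, players = players,
                 covariate_spec = list(
                   covariate = attr(covariates, "covariate") %||% "covariate",
                   method = attr(covariates, "method") %||% "mean",
                   cutoff = cutoff,
                   standardization = list(X1 = zx1[c("center", "scale")],
                                          X2 = zx2[c("center", "scale")],
                                          position = zz[c("center", "scale")])),
                 families = stats::setNames(fams, c("pre", "post")),
                 cutoff = cutoff, offset = offset, center_age = center_age,
                 flags = flags, converged = length(flags) == 0L,
                 config = config),
            class = "bianus_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the latent-variable model with estimated inflections (Model 2)
#'
#' Single-likelihood variant: instead of splitting at a fixed cutoff, every
#' player's inflection age `tau_p` is estimated via a Heaviside switch inside
#' one likelihood, while the latent structure (factors, gammas, rho) is
#' identical to [fit_bianus_model1()]. The joint estimation of changepoints,
#' slopes and factors makes this model markedly harder to sample; convergence
#' diagnostics are mandatory in the output and threshold violations are
#' surfaced as flags on the returned fit — never silently dropped.
#'
#' @param data A `career_table`.
#' @param tau_bounds Inflection support, inside `[20, 36]`; default
#'   `c(24, 33)`.
#' @param covariates A `covariate_summary`; its cutoff is used only for the
#'   covariate aggregation, the changepoint itself is estimated.
#' @param family `"linear"` (raw performance, default) or `"exponential"`
#'   (log scale).
#' @param offset Log-offset when `family = "exponential"`.
#' @param min_seasons Minimum career length for individual parameters
#'   (default 4).
#' @param config An [mcmc_config()].
#' @return A `bianus_fit` with the Model 1 latent fields plus `tau_by_player`
#'   and a `tau_mean` summary; `converged` reflects the diagnostics.
#' @export
fit_bianus_model2 <- function(data, tau_bounds = c(24, 33), covariates,
                              family = c("linear", "exponential"),
                              offset = NULL, min_seasons = 4L,
                              config = mcmc_config()) {
  stopifnot(inherits(data, "career_table"), length(tau_bounds) == 2L)
  family <- match.arg(family)
  lo <- tau_bounds[1L]; hi <- tau_bounds[2L]
  if (lo >= hi || lo < 20 || hi > 36) stop("tau_bounds must increase inside [20, 36]")
  if (lo > max(data$age) || hi < min(data$age)) {
    stop("tau_bounds lie outside the observed age range")
  }
  players <- sort(unique(data$player_id))
  P <- length(players)
  cov <- .check_covariates(covariates, players)

  if (family == "exponential") {
    td <- linearize("exponential", data, offset = offset)
    y <- td$y; used_offset <- td$offset
  } else {
    y <- data$performance; used_offset <- 0
  }
  n_seasons <- table(data$player_id)
  qual <- players %in% names(n_seasons)[n_seasons >= min_seasons]
  idx <- ifelse(qual[match(data$player_id, players)],
                match(data$player_id, players), P + 1L)

  zx1 <- .standardize(cov$X1); zx2 <- .standardize(cov$X2)
  zz <- .standardize(cov$position_code)
  jd <- list(N = nrow(data), y = y, age = as.numeric(data$age),
             pq = as.integer(idx), P = P, lo = lo, hi = hi,
             X1 = zx1$z, X2 = zx2$z, Z = zz$z)
  mid <- (lo + hi) / 2

  # Hinge-OLS starting values (changepoint provisionally at the bounds
  # midpoint): global intercept/slopes from a pooled two-segment fit,
  # per-player slope deviations per segment. Without them the chains can
  # park the slope means inside the factor deviations, which drags the
  # factor correlation toward an artefactual -1.
  xpre <- pmin(jd$age - mid, 0); xpost <- pmax(jd$age - mid, 0)
  co <- stats::lm.fit(cbind(1, xpre, xpost), y)$coefficients
  a0 <- unname(co[1]); m10 <- unname(co[2]); m20 <- unname(co[3])
  side_dev <- function(pre_side, m0) {
    d <- vapply(players, function(p) {
      rows <- data$player_id == p &
        (if (pre_side) data$age <= mid else data$age > mid)
      x <- jd$age[rows] - mid; yy <- y[rows]
      if (sum(rows) < 2L || stats::var(x) == 0) return(0)
      b <- stats::cov(x, yy) / stats::var(x)
      if (!is.finite(b)) 0 else b - m0
    }, numeric(1))
    pmax(pmin(unname(d), 5), -5)
  }
  d10 <- side_dev(TRUE, m10); d20 <- side_dev(FALSE, m20)
  rho0 <- stats::cor(d10, d20)
  if (!is.finite(rho0)) rho0 <- 0
  sy0 <- max(stats::sd(y - a0 - m10 * xpre - m20 * xpost), 1e-3)
  inits <- function(chain) {
    jit <- c(-1, 1, -0.5, 0.5, 0.25, -0.25)[(chain - 1L) %% 6L + 1L]
    list(mtau = mid, tau = rep(mid, P), a = a0, sy = sy0,
         mu1 = m10 * (1 + 0.05 * jit), mu2 = m20 * (1 + 0.05 * jit),
         d1 = d10, d2 = d20, phi1c = d10, phi2c = d20,
         rho = max(min(rho0, 0.9), -0.9))
  }
  params <- c("a", "sy", "mtau", "stau", "tau", .latent_params)
  samples <- sample_posterior(bianus_model(.model2_code, jd, params, inits),
                              config)

  sm <- summarize_draws(samples, c("a", "mu1", "mu2", "mtau", "stau", "sy"))
  sm$parameter <- c("intercept", "slope_pre", "slope_post", "tau_mean",
                    "sigma_tau", "sigma")
  qual_idx <- which(qual)
  tsum <- summarize_draws(samples, paste0("tau[", qual_idx, "]"))
  tau_tab <- data.frame(player_id = players[qual_idx], mean = tsum$mean,
                        ci_low = tsum$ci_low, ci_high = tsum$ci_high,
                        stringsAsFactors = FALSE)

  latent <- .latent_structure(samples, players,
                              attr(covariates, "covariate") %||% "covariate")
  flags <- c(samples$flags, latent$flags)
  structure(list(model = "model2", summary = sm, tau_by_player = tau_tab,
                 latent = latent, samples = samples, players = players,
                 covariate_spec = list(
                   covariate = attr(covariates, "covariate") %||% "covariate",
                   method = attr(covariates, "method") %||% "mean"),
                 family = family, tau_bounds = c(lo, hi),
                 offset = used_offset, flags = flags,
                 converged = length(flags) == 0L, config = config),
            class = "bianus_fit")
}

#' @export
print.bianus_fit <- function(x, ...) {
  rho <- x$latent$rho
  cat(sprintf("<bianus_fit> %s, %d players\n", x$model, length(x$players)))
  cat(sprintf("  rho (development-aging correlation): %.3f (95%% CI %.3f to %.3f)\n",
              rho$mean, rho$ci_low, rho$ci_high))
  cat("  covariate weights (gamma):\n")
  g <- x$latent$gamma
  for (i in seq_len(nrow(g))) {
    cat(sprintf("    %s -> %s: %.3f (%.3f to %.3f)\n", g$covariate[i],
                g$factor[i], g$mean[i], g$ci_low[i], g$ci_high[i]))
  }
  if (x$model == "model2") {
    tm <- x$summary[x$summary$parameter == "tau_mean", ]
    cat(sprintf("  population inflection age: %.2f (%.2f to %.2f)\n",
                tm$mean, tm$ci_low, tm$ci_high))
  }
  if (length(x$flags)) {
    cat("  convergence/identification flags:\n")
    for (f in x$flags) cat("   - ", f, "\n", sep = "")
  } else cat("  no flags\n")
  invisible(x)
}

#' Summaries of the development-aging interaction
#'
#' Extracts the posterior summary of the inter-factor correlation `rho`
#' together with the per-player posterior-mean slope pairs
#' `(E[beta_1p], E[beta_2p])` — the table behind the classic pre/post slope
#' scatter. A positive empirical correlation of the pairs means players with
#' stronger development decline more slowly.
#'
#' @param fit A `bianus_fit`.
#' @param force Set TRUE to extract from a fit with convergence flags.
#' @return A `bianus_interaction` list: `rho` (summary row), `pairs` (data
#'   frame `player_id`, `beta_pre`, `beta_post`), `empirical_correlation`.
#' @export
extract_interaction <- function(fit, force = FALSE) {
  stopifnot(inherits(fit, "bianus_fit"))
  if (!fit$converged && !force) {
    stop("fit carries convergence/identification flags; pass force = TRUE to ",
         "extract anyway:\n  ", paste(fit$flags, collapse = "\n  "))
  }
  pairs <- data.frame(player_id = fit$players,
                      beta_pre = fit$latent$beta1_by_player$mean,
                      beta_post = fit$latent$beta2_by_player$mean,
                      stringsAsFactors = FALSE)
  structure(list(rho = fit$latent$rho, pairs = pairs,
                 empirical_correlation = stats::cor(pairs$beta_pre,
                                                    pairs$beta_post)),
            class = "bianus_interaction")
}

#' @export
print.bianus_interaction <- function(x, ...) {
  cat(sprintf("<bianus_interaction> rho %.3f (95%% CI %.3f to %.3f); %d players\n",
              x$rho$mean, x$rho$ci_low, x$rho$ci_high, nrow(x$pairs)))
  cat(sprintf("  empirical corr of posterior-mean slope pairs: %.3f\n",
              x$empirical_correlation))
  invisible(x)
}
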