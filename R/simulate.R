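# Generative simulator of careers with known ground truth. The default
# ("phase") trajectory mode is the generative inversion of the two-phase
# latent-variable model: latent factors (phi_1p, phi_2p) are bivariate normal
# with correlation rho; per-player slopes are the factors plus measurement
# noise; covariates are gamma-weighted factor indicators; each season's
# performance follows the phase family around a global phase intercept, with
# Gaussian noise on the transformed (log) scale, Heaviside-switched at the
# cutoff. The "hinge" mode instead generates continuous piecewise-linear
# careers that bend at a per-player inflection age tau_p, the process the
# broken-stick model estimates.

#' Configuration for the career simulator
#'
#' Defaults describe an elite-basketball-like study: 400 players entering at
#' ages 19-23 with careers of 5-18 consecutive seasons, exponential growth
#' before a cutoff age of 27 and power-law decline after it, correlated
#' latent development/aging factors (`rho = 0.5`), minutes per game loading
#' positively on both factors, position carrying no signal, and observation
#' noise sd 0.1 on the log scale.
#'
#' @param n_players Number of players.
#' @param age_entry_range Inclusive integer range of entry ages.
#' @param career_length_range Inclusive integer range of career lengths
#'   (seasons).
#' @param cutoff Cutoff age for `trajectory = "phase"`.
#' @param tau Inflection specification for `trajectory = "hinge"`: a single
#'   age (common inflection) or a length-2 range for per-player uniform draws.
#' @param trajectory `"phase"` (two-likelihood structure, default) or
#'   `"hinge"` (continuous piecewise-linear with per-player tau).
#' @param families Length-2 vector (pre, post); ignored (linear) for hinge.
#' @param intercepts Global phase intercepts on the transformed scale for
#'   `"phase"` mode; for `"hinge"` mode the single peak-performance intercept
#'   is `intercepts[1]`.
#' @param slope_means,slope_sds Means and sds of the latent factors
#'   (phi_1, phi_2).
#' @param rho Latent factor correlation, in `[-1, 1]`.
#' @param slope_obs_sd Sd of the slope measurement noise around the factors
#'   (beta_ip = phi_ip + e), length 2.
#' @param gamma_minutes Loadings of the minutes-per-game covariate on the
#'   two factors (raw minutes per unit of factor).
#' @param gamma_position Loadings of position on the factors (default 0:
#'   position carries no signal).
#' @param minutes_means Mean minutes per game in each phase.
#' @param covariate_noise_sd Sd of covariate measurement noise (minutes).
#' @param noise_sd Observation noise sd on the transformed scale.
#' @param raw_scale_noise If TRUE, add the observation noise on the raw
#'   performance scale instead (a deliberate misspecification option for
#'   robustness studies).
#' @param dropout_rate Per-season probability scale of early retirement after
#'   the cutoff, tied to the aging factor (0 = off, the default; careers are
#'   otherwise contiguous with no gap seasons).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_players = 400L,
                       age_entry_range = c(19L, 23L),
                       career_length_range = c(5L, 18L),
                       cutoff = 27L, tau = NULL,
                       trajectory = c("phase", "hinge"),
                       families = c(pre = "exponential", post = "power"),
                       intercepts = c(0, 5.56),
                       slope_means = c(0.06, -1.2),
                       slope_sds = c(0.04, 0.5),
                       rho = 0.5,
                       slope_obs_sd = c(0.01, 0.12),
                       gamma_minutes = c(60, 5),
                       gamma_position = c(0, 0),
                       minutes_means = c(25, 24),
                       covariate_noise_sd = 4,
                       noise_sd = 0.1,
                       raw_scale_noise = FALSE,
                       dropout_rate = 0,
                       seed = 1L) {
  trajectory <- match.arg(trajectory)
  if (!is.null(tau)) trajectory <- "hinge"
  if (trajectory == "hinge") {
    if (is.null(tau)) tau <- c(26, 30)
    families <- c(pre = "linear", post = "linear")
  }
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  if (any(c(slope_sds, slope_obs_sd, noise_sd, covariate_noise_sd) < 0)) {
    stop("sds must be >= 0")
  }
  if (diff(age_entry_range) < 0 || diff(career_length_range) < 0) {
    stop("ranges must be non-degenerate (lo <= hi)")
  }
  structure(list(n_players = as.integer(n_players),
                 age_entry_range = as.integer(age_entry_range),
                 career_length_range = as.integer(career_length_range),
                 cutoff = as.integer(cutoff), tau = tau,
                 trajectory = trajectory, families = families,
                 intercepts = intercepts, slope_means = slope_means,
                 slope_sds = slope_sds, rho = rho,
                 slope_obs_sd = slope_obs_sd,
                 gamma_minutes = gamma_minutes,
                 gamma_position = gamma_position,
                 minutes_means = minutes_means,
                 covariate_noise_sd = covariate_noise_sd,
                 noise_sd = noise_sd, raw_scale_noise = raw_scale_noise,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "sim_config")
}

.x_transform <- function(family, age) {
  switch(family, power = log(age), linear = age, exponential = age)
}

#' Simulate careers with known ground truth
#'
#' @param config A [sim_config()].
#' @return A `bianus_sim` list: `careers` (a `career_table` in the same CSV
#'   schema [read_careers()] consumes, metric column `performance`) and
#'   `truth` (per-player `phi1`, `phi2`, `beta1`, `beta2`, `tau`, `X1`, `X2`,
#'   `position`, plus the config). Regenerable from the seed: the same config
#'   always yields the same data.
#' @export
simulate_careers <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  P <- cf$n_players
  ids <- sprintf("P%04d", seq_len(P))

  z1 <- stats::rnorm(P)
  z2 <- cf$rho * z1 + sqrt(1 - cf$rho^2) * stats::rnorm(P)
  phi1 <- cf$slope_means[1] + cf$slope_sds[1] * z1
  phi2 <- cf$slope_means[2] + cf$slope_sds[2] * z2
  beta1 <- phi1 + stats::rnorm(P, 0, cf$slope_obs_sd[1])
  beta2 <- phi2 + stats::rnorm(P, 0, cf$slope_obs_sd[2])

  pos_signal <- cf$gamma_position[1] * (phi1 - cf$slope_means[1]) +
    cf$gamma_position[2] * (phi2 - cf$slope_means[2])
  if (all(cf$gamma_position == 0)) {
    position <- sample(names(position_codes), P, replace = TRUE)
  } else {
    u <- pos_signal + stats::rnorm(P, 0, max(stats::sd(pos_signal), 1e-8))
    position <- names(position_codes)[cut(rank(u), 5L, labels = FALSE)]
  }

  X1 <- cf$minutes_means[1] + cf$gamma_minutes[1] * (phi1 - cf$slope_means[1]) +
    stats::rnorm(P, 0, cf$covariate_noise_sd)
  X2 <- cf$minutes_means[2] + cf$gamma_minutes[2] * (phi2 - cf$slope_means[2]) +
    stats::rnorm(P, 0, cf$covariate_noise_sd)
  X1 <- pmax(X1, 0); X2 <- pmax(X2, 0)

  if (cf$trajectory == "hinge") {
    tau_p <- if (length(cf$tau) == 1L) rep(cf$tau, P)
             else stats::runif(P, cf$tau[1], cf$tau[2])
  } else {
    tau_p <- rep(as.numeric(cf$cutoff), P)
  }

  rows <- vector("list", P)
  first_season <- sample(1970:2010, P, replace = TRUE)
  for (p in seq_len(P)) {
    entry <- sample(seq(cf$age_entry_range[1], cf$age_entry_range[2]), 1L)
    len <- sample(seq(cf$career_length_range[1], cf$career_length_range[2]), 1L)
    ages <- seq(entry, entry + len - 1L)
    if (cf$dropout_rate > 0) {
      post <- ages > tau_p[p]
      if (any(post)) {
        hazard <- cf$dropout_rate *
          stats::plogis(-(phi2[p] - cf$slope_means[2]) /
                          max(cf$slope_sds[2], 1e-8))
        gone <- which(post & stats::runif(length(ages)) < hazard)
        if (length(gone)) ages <- ages[seq_len(min(gone) - 1L)]
      }
    }
    if (cf$trajectory == "hinge") {
      mu <- cf$intercepts[1] + beta1[p] * pmin(ages - tau_p[p], 0) +
        beta2[p] * pmax(ages - tau_p[p], 0)
    } else {
      pre <- ages <= cf$cutoff
      mu <- numeric(length(ages))
      mu[pre] <- cf$intercepts[1] +
        beta1[p] * .x_transform(cf$families[[1]], ages[pre])
      mu[!pre] <- cf$intercepts[2] +
        beta2[p] * .x_transform(cf$families[[2]], ages[!pre])
    }
    noise <- stats::rnorm(length(ages), 0, cf$noise_sd)
    log_scale <- cf$trajectory == "phase" &&
      any(cf$families %in% c("power", "exponential"))
    if (cf$trajectory == "hinge" || !log_scale) {
      perf <- mu + noise
    } else if (cf$raw_scale_noise) {
      perf <- exp(mu) + noise
    } else {
      perf <- exp(mu + noise)
    }
    cov_switch <- if (cf$trajectory == "hinge") tau_p[p] else cf$cutoff
    rows[[p]] <- data.frame(
      player_id = ids[p], season = first_season[p] + seq_along(ages) - 1L,
      age = ages, performance = perf,
      mp_per_game = ifelse(ages <= cov_switch, X1[p], X2[p]),
      position = position[p], stringsAsFactors = FALSE)
  }
  careers <- career_table(do.call(rbind, rows), metric = "performance")
  truth <- structure(
    data.frame(player_id = ids, phi1 = phi1, phi2 = phi2, beta1 = beta1,
               beta2 = beta2, tau = tau_p, X1 = X1, X2 = X2,
               position = position, stringsAsFactors = FALSE),
    config = cf, class = c("sim_truth", "data.frame"))
  structure(list(careers = careers, truth = truth), class = "bianus_sim")
}

#' Write simulated careers and their truth sidecar
#'
#' @param sim A `bianus_sim` from [simulate_careers()].
#' @param path Output CSV path for the careers.
#' @param truth_path Output JSON path for the ground truth; default
#'   `<path>` with a `.truth.json` extension.
#' @return `path`, invisibly.
#' @export
write_sim <- function(sim, path, truth_path = sub("\\.csv$", "", path)) {
  stopifnot(inherits(sim, "bianus_sim"))
  truth_path <- paste0(truth_path, ".truth.json")
  write_careers(sim$careers, path)
  cf <- attr(sim$truth, "config")
  jsonlite::write_json(list(config = unclass(cf),
                            truth = as.data.frame(sim$truth)),
                       truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Parameter-recovery report against simulation truth
#'
#' Compares a fitted `bianus_fit` (or broken-stick fit) with the `sim_truth`
#' it was generated from: per parameter class, the bias and RMSE of posterior
#' means and the fraction of 95% credible intervals covering the truth.
#'
#' @param truth A `sim_truth` (from [simulate_careers()]).
#' @param fit A `bianus_fit` or `broken_stick_fit` on the same players.
#' @return A `recovery_report` data frame: `class`, `n`, `bias`, `rmse`,
#'   `coverage`.
#' @export
recovery_report <- function(truth, fit) {
  stopifnot(inherits(truth, "sim_truth"))
  cf <- attr(truth, "config")
  rows <- list()
  add <- function(class, est, tru) {
    covered <- mean(est$ci_low <= tru & tru <= est$ci_high)
    rows[[length(rows) + 1L]] <<- data.frame(
      class = class, n = length(tru), bias = mean(est$mean - tru),
      rmse = sqrt(mean((est$mean - tru)^2)), coverage = covered,
      stringsAsFactors = FALSE)
  }
  match_truth <- function(est, col) {
    i <- match(est$player_id, truth$player_id)
    if (any(is.na(i))) {
      stop("player id(s) in fit but not in truth: ",
           paste(utils::head(est$player_id[is.na(i)], 10L), collapse = ", "))
    }
    truth[[col]][i]
  }
  if (inherits(fit, "bianus_fit")) {
    add("beta1", fit$latent$beta1_by_player,
        match_truth(fit$latent$beta1_by_player, "beta1"))
    add("beta2", fit$latent$beta2_by_player,
        match_truth(fit$latent$beta2_by_player, "beta2"))
    add("phi1", fit$latent$phi1_by_player,
        match_truth(fit$latent$phi1_by_player, "phi1"))
    add("phi2", fit$latent$phi2_by_player,
        match_truth(fit$latent$phi2_by_player, "phi2"))
    add("rho", fit$latent$rho, cf$rho)
    if (!is.null(fit$tau_by_player)) {
      add("tau", fit$tau_by_player, match_truth(fit$tau_by_player, "tau"))
    }
  } else if (inherits(fit, "broken_stick_fit")) {
    add("beta1", fit$slope_pre_by_player,
        match_truth(fit$slope_pre_by_player, "beta1"))
    add("beta2", fit$slope_post_by_player,
        match_truth(fit$slope_post_by_player, "beta2"))
    add("tau", fit$tau_by_player, match_truth(fit$tau_by_player, "tau"))
  } else {
    stop("fit must be a bianus_fit or broken_stick_fit")
  }
  structure(do.call(rbind, rows), class = c("recovery_report", "data.frame"))
}
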