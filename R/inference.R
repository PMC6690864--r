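#' MCMC sampler configuration
#'
#' Defaults are desk-scale: 1000 adaptation steps, 1000 burn-in, 1000
#' retained samples per chain, no thinning, 4 chains. Production-scale runs
#' (tens of thousands of adaptation/burn-in steps with thinning) are reached
#' by raising these fields; thinning is applied purely as a stride.
#'
#' @param n_adapt Adaptation steps.
#' @param n_burnin Burn-in steps discarded after adaptation.
#' @param n_samples Retained samples per chain (after thinning).
#' @param thin Thinning stride (>= 1).
#' @param n_chains Number of chains (>= 2, so split-R-hat is defined).
#' @param seed Integer seed; all chain RNGs derive from it.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_adapt = 1000L, n_burnin = 1000L, n_samples = 1000L,
                        thin = 1L, n_chains = 4L, seed = 1L) {
  cfg <- list(n_adapt = as.integer(n_adapt), n_burnin = as.integer(n_burnin),
              n_samples = as.integer(n_samples), thin = as.integer(thin),
              n_chains = as.integer(n_chains), seed = as.integer(seed))
  if (any(vapply(cfg, function(v) v < 1L, logical(1))[1:5])) {
    stop("all mcmc_config counts must be positive")
  }
  if (cfg$n_chains < 2L) stop("n_chains must be >= 2")
  structure(cfg, class = "mcmc_config")
}

#' Specify a Bayesian model for posterior sampling
#'
#' Bundles BUGS-language model code with its data block, the parameters to
#' monitor, and optional per-chain initial values. This is the joint-density
#' specification consumed by [sample_posterior()].
#'
#' @param code Model code (BUGS language, character scalar).
#' @param data Named list of data nodes.
#' @param params Character vector of parameters to monitor.
#' @param inits Optional `function(chain)` returning a named list of initial
#'   values for that chain.
#' @return A `bianus_model` object.
#' @export
bianus_model <- function(code, data, params, inits = NULL) {
  stopifnot(is.character(code), length(code) == 1L, is.list(data),
            is.character(params))
  structure(list(code = code, data = data, params = params, inits = inits),
            class = "bianus_model")
}

.chain_inits <- function(model, config) {
  lapply(seq_len(config$n_chains), function(chain) {
    ini <- if (is.null(model$inits)) list() else model$inits(chain)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- (config$seed %% 190000000L) + 7919L * chain
    ini
  })
}

#' Draw posterior samples by MCMC
#'
#' Runs JAGS on a [bianus_model()]: adaptation, burn-in, then `n_samples`
#' retained draws per chain at the configured thinning stride. Runs are
#' reproducible: the same model, data, config and seed give identical draws.
#' Split-R-hat and effective sample size are computed for every monitored
#' scalar; threshold violations (R-hat >= 1.01 or ESS <= 100) are recorded in
#' the `flags` field of the result — they annotate, they never trigger a
#' rerun.
#'
#' @param model A [bianus_model()].
#' @param config An [mcmc_config()].
#' @param rhat_threshold,ess_threshold Annotation thresholds.
#' @return A `posterior_samples` object: `draws` (named list, one
#'   chains-by-iterations matrix per scalar parameter), `diagnostics` (data
#'   frame: parameter, rhat, ess), `flags`, `converged`, `config`, and the
#'   underlying `coda::mcmc.list` in `coda`.
#' @export
sample_posterior <- function(model, config = mcmc_config(),
                             rhat_threshold = 1.01, ess_threshold = 100) {
  stopifnot(inherits(model, "bianus_model"), inherits(config, "mcmc_config"))
  jm <- tryCatch(
    rjags::jags.model(textConnection(model$code), data = model$data,
                      n.chains = config$n_chains, n.adapt = config$n_adapt,
                      inits = .chain_inits(model, config), quiet = TRUE),
    error = function(e) {
      stop("model initialization failed (non-finite density or graph error): ",
           conditionMessage(e), call. = FALSE)
    })
  stats::update(jm, n.iter = config$n_burnin, progress.bar = "none")
  cs <- rjags::coda.samples(jm, variable.names = model$params,
                            n.iter = config$n_samples * config$thin,
                            thin = config$thin, progress.bar = "none")
  mats <- lapply(cs, as.matrix)
  vars <- colnames(mats[[1L]])
  draws <- lapply(vars, function(v) {
    do.call(rbind, lapply(mats, function(m) m[, v]))  # chains x iterations
  })
  names(draws) <- vars

  keep <- vapply(draws, function(m) stats::var(as.numeric(m)) > 0 ||
                   all(is.finite(m)), logical(1))
  rhat <- vapply(draws, split_rhat, numeric(1))
  ess <- tryCatch(as.numeric(coda::effectiveSize(cs))[seq_along(vars)],
                  error = function(e) rep(NA_real_, length(vars)))
  diagnostics <- data.frame(parameter = vars, rhat = unname(rhat),
                            ess = ess, stringsAsFactors = FALSE)
  variable <- vapply(draws, function(m) stats::var(as.numeric(m)) > 0, logical(1))
  bad_rhat <- diagnostics$parameter[variable & !is.na(rhat) & rhat >= rhat_threshold]
  bad_ess <- diagnostics$parameter[variable & !is.na(ess) & ess <= ess_threshold]
  flags <- character(0)
  if (length(bad_rhat)) {
    flags <- c(flags, paste0("split-Rhat >= ", rhat_threshold, " for: ",
                             paste(utils::head(bad_rhat, 12L), collapse = ", "),
                             if (length(bad_rhat) > 12L) ", ..."))
  }
  if (length(bad_ess)) {
    flags <- c(flags, paste0("ESS <= ", ess_threshold, " for: ",
                             paste(utils::head(bad_ess, 12L), collapse = ", "),
                             if (length(bad_ess) > 12L) ", ..."))
  }
  structure(list(draws = draws, diagnostics = diagnostics, flags = flags,
                 converged = length(flags) == 0L, config = config, coda = cs),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %d parameters, %d chains x %d iterations\n",
              length(x$draws), x$config$n_chains, x$config$n_samples))
  if (length(x$flags)) {
    cat("  convergence flags:\n")
    for (f in x$flags) cat("   - ", f, "\n", sep = "")
  } else cat("  no convergence flags\n")
  invisible(x)
}

#' Split-R-hat for a single parameter
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so that within-chain drift also inflates the statistic.
#'
#' @param m Chains-by-iterations matrix of draws.
#' @return Scalar split-R-hat (`NA` for constant draws or < 4 total halves'
#'   worth of iterations).
#' @export
split_rhat <- function(m) {
  m <- as.matrix(m)
  n <- ncol(m)
  if (n < 4L) return(NA_real_)
  if (stats::var(as.numeric(m)) == 0) return(1)
  half <- floor(n / 2)
  pieces <- do.call(rbind, lapply(seq_len(nrow(m)), function(c1) {
    rbind(m[c1, seq_len(half)], m[c1, (n - half + 1L):n])
  }))
  cm <- rowMeans(pieces)
  cv <- apply(pieces, 1L, stats::var)
  W <- mean(cv)
  B <- half * stats::var(cm)
  if (W == 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Pool draws into a matrix
#'
#' @param samples A `posterior_samples` object.
#' @param params Optional subset of parameter names.
#' @return Matrix with one row per pooled draw (chains concatenated) and one
#'   column per scalar parameter.
#' @export
as_draws_matrix <- function(samples, params = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (is.null(params)) params <- names(samples$draws)
  unknown <- setdiff(params, names(samples$draws))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  sapply(params, function(v) as.numeric(t(samples$draws[[v]])))
}

#' Gather the elements of a vector-valued parameter from one draw
#'
#' JAGS reports vector parameters as scalars named `name[1]`, `name[2]`, ...;
#' this gathers them back into a numeric vector in index order.
#'
#' @param draw Named numeric vector (one row of [as_draws_matrix()]).
#' @param name Base parameter name.
#' @return Numeric vector ordered by index.
#' @export
extract_vector <- function(draw, name) {
  pat <- paste0("^", gsub("([.\\[\\]])", "\\\\\\1", name), "\\[")
  hits <- grep(pat, names(draw), value = TRUE)
  if (!length(hits)) {
    if (name %in% names(draw)) return(unname(draw[name]))
    stop("no elements of '", name, "' in draw")
  }
  idx <- as.integer(sub("^.*\\[(\\d+)\\]$", "\\1", hits))
  unname(draw[hits][order(idx)])
}

#' Posterior means and central 95% credible intervals
#'
#' Pools all chains and reports, for each requested parameter, the posterior
#' mean and the central 95% interval (2.5% and 97.5% quantiles, type-7
#' linear-interpolation rule). Results are invariant to the order in which
#' chains are concatenated.
#'
#' @param samples A `posterior_samples` object.
#' @param params Parameter names; default all monitored scalars.
#' @param level Interval mass (default 0.95).
#' @return Data frame: `parameter`, `mean`, `ci_low`, `ci_high`.
#' @export
summarize_draws <- function(samples, params = NULL, level = 0.95) {
  m <- as_draws_matrix(samples, params)
  a <- (1 - level) / 2
  out <- data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    ci_low = apply(m, 2L, stats::quantile, probs = a, type = 7, names = FALSE),
    ci_high = apply(m, 2L, stats::quantile, probs = 1 - a, type = 7,
                    names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Deviance information criterion from posterior draws
#'
#' Classic DIC: `dbar` is the posterior mean deviance over all retained
#' draws, `dhat` the deviance at the posterior mean of the parameters, the
#' complexity penalty is `pD = dbar - dhat`, and `dic = dbar + pD =
#' 2*dbar - dhat` (an exact identity of the result object).
#'
#' @param samples A `posterior_samples` object.
#' @param deviance_fn Function mapping one draw (a named numeric vector; use
#'   [extract_vector()] for vector parameters) to the model deviance
#'   `-2 log p(data | theta)`.
#' @param params Parameters the evaluator needs; default all.
#' @return A `dic_result` list: `dbar`, `dhat`, `pd`, `dic`, `n_draws`.
#' @export
compute_dic <- function(samples, deviance_fn, params = NULL) {
  m <- as_draws_matrix(samples, params)
  dev <- apply(m, 1L, deviance_fn)
  if (any(!is.finite(dev))) {
    stop("non-finite deviance at draw index(es): ",
         paste(utils::head(which(!is.finite(dev)), 10L), collapse = ", "))
  }
  dbar <- mean(dev)
  dhat <- deviance_fn(colMeans(m))
  pd <- dbar - dhat
  structure(list(dbar = dbar, dhat = dhat, pd = pd, dic = dbar + pd,
                 n_draws = length(dev)),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("<dic_result> DIC %.2f (dbar %.2f, pD %.2f)\n",
              x$dic, x$dbar, x$pd))
  invisible(x)
}
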