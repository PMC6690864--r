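#' Candidate age-change function families
#'
#' Four parametric families describe how expected performance changes with
#' age within one career phase:
#' \describe{
#'   \item{power}{\eqn{\alpha \cdot age^{\beta}} — change slows near the peak.}
#'   \item{exponential}{\eqn{\alpha \cdot e^{\beta \cdot age}} — constant
#'     proportional rate of change.}
#'   \item{logistic}{\eqn{\delta / (1 + \alpha e^{\beta \cdot age})} —
#'     S-shaped approach to an upper limit \eqn{\delta}.}
#'   \item{linear}{\eqn{\alpha + \beta \cdot age}.}
#' }
#' `alpha` sets the baseline/scale, `beta` the rate of change, and `delta`
#' (logistic only) the upper performance limit.
#'
#' @param family One of `"power"`, `"exponential"`, `"logistic"`, `"linear"`.
#' @param alpha,beta Real parameters.
#' @param delta Upper limit; required for (and only for) the logistic family,
#'   must be positive.
#' @return An `age_function` object.
#' @examples
#' f <- age_function("exponential", alpha = 1.2, beta = 0.05)
#' predict(f, age = 19:27)
#' @export
age_function <- function(family = c("power", "exponential", "logistic", "linear"),
                         alpha, beta, delta = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L)
  if (family == "logistic") {
    if (is.null(delta)) stop("logistic family requires delta")
    if (delta <= 0) stop("logistic delta must be > 0")
  } else if (!is.null(delta)) {
    stop("delta is only meaningful for the logistic family")
  }
  structure(list(family = family, alpha = alpha, beta = beta, delta = delta),
            class = "age_function")
}

#' @export
print.age_function <- function(x, ...) {
  eq <- switch(x$family,
    power       = sprintf("%.4g * age^%.4g", x$alpha, x$beta),
    exponential = sprintf("%.4g * exp(%.4g * age)", x$alpha, x$beta),
    logistic    = sprintf("%.4g / (1 + %.4g * exp(%.4g * age))",
                          x$delta, x$alpha, x$beta),
    linear      = sprintf("%.4g + %.4g * age", x$alpha, x$beta))
  cat(sprintf("<age_function> %s: %s\n", x$family, eq))
  invisible(x)
}

#' Evaluate an age-change function
#'
#' @param object An [age_function()].
#' @param age Numeric vector of ages in years; must be strictly positive for
#'   the power family.
#' @param ... Unused.
#' @return Expected performance at each age.
#' @export
predict.age_function <- function(object, age, ...) {
  stopifnot(is.numeric(age))
  f <- object
  if (f$family == "power" && any(age <= 0)) {
    stop("power family requires age > 0")
  }
  out <- switch(f$family,
    power       = f$alpha * age^f$beta,
    exponential = f$alpha * exp(f$beta * age),
    logistic    = {
      den <- 1 + f$alpha * exp(f$beta * age)
      if (any(den == 0)) stop("logistic denominator 1 + alpha*exp(beta*age) is zero")
      f$delta / den
    },
    linear      = f$alpha + f$beta * age)
  out
}

#' Default log-offset for a performance vector
#'
#' Smallest offset making `min(performance + offset)` equal `floor_at`
#' (default 0.1), so that logarithms are defined for metrics (such as win
#' shares) that can be zero or negative. Zero when the data are already
#' comfortably positive.
#'
#' @param performance Numeric vector.
#' @param floor_at Target minimum of the shifted data.
#' @return Non-negative scalar offset.
#' @export
default_offset <- function(performance, floor_at = 0.1) {
  m <- min(performance, na.rm = TRUE)
  max(0, floor_at - m)
}

#' Linearize performance-age data for a function family
#'
#' Power-law and exponential mean curves become straight lines after log
#' transforms: for the power family both performance and age are
#' log-transformed (log-log), for the exponential family only performance is
#' (log-linear). The offset added to performance before the log, and the kind
#' of transform, are recorded so that model predictions can be mapped back to
#' the raw scale.
#'
#' @param family `"power"`, `"exponential"`, or `"linear"` (identity
#'   transform, provided so all linearizable families share one code path).
#' @param data A `career_table` (or any data frame with `player_id`, `age`,
#'   `performance`).
#' @param offset Offset added to performance before the log; default
#'   [default_offset()] of the data. Ignored (forced 0) for `"linear"`.
#' @return A `transformed_data` list: `y`, `x`, `player_id`, `age`,
#'   `offset`, `transform_kind` (`"log_log"`, `"log_linear"` or
#'   `"identity"`), `family`.
#' @export
linearize <- function(family = c("power", "exponential", "linear"),
                      data, offset = NULL) {
  family <- match.arg(family)
  perf <- data$performance
  age <- data$age
  if (family != "linear" && any(age <= 0)) stop("ages must be > 0")
  if (family == "linear") {
    return(structure(list(y = as.numeric(perf), x = as.numeric(age),
                          player_id = as.character(data$player_id),
                          age = as.numeric(age), offset = 0,
                          transform_kind = "identity", family = family),
                     class = "transformed_data"))
  }
  if (is.null(offset)) offset <- default_offset(perf)
  shifted <- perf + offset
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0)
    need <- default_offset(perf)
    stop("performance + offset must be > 0; offending row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         "; smallest adequate offset is ", format(need))
  }
  structure(list(
    y = log(shifted),
    x = if (family == "power") log(as.numeric(age)) else as.numeric(age),
    player_id = as.character(data$player_id),
    age = as.numeric(age),
    offset = offset,
    transform_kind = if (family == "power") "log_log" else "log_linear",
    family = family), class = "transformed_data")
}

#' Map transformed-scale values back to raw performance
#'
#' Inverse of the performance transform recorded in a `transformed_data`
#' object: `exp(y) - offset` for log transforms, identity otherwise.
#'
#' @param transformed A `transformed_data` object.
#' @param y Values on the transformed scale; defaults to `transformed$y`.
#' @return Raw-scale performance values.
#' @export
back_transform <- function(transformed, y = NULL) {
  stopifnot(inherits(transformed, "transformed_data"))
  if (is.null(y)) y <- transformed$y
  if (transformed$transform_kind == "identity") return(y)
  exp(y) - transformed$offset
}

#' Gaussian log-likelihood on the linearized scale
#'
#' Log-likelihood of transformed observations under the linearized mean of an
#' age-change function with per-player slopes: each observation contributes a
#' Gaussian log-density of `y` around `intercept + slope_p * x`, where the
#' intercept is `log(alpha)` for log-transformed families and `alpha` for the
#' linear family, and `slope_p` is the player's entry in `slopes` (fall back
#' to a single unnamed global slope by passing one unnamed value).
#'
#' @param f An [age_function()] of a linearizable family matching the
#'   transform in `data`.
#' @param sigma Residual standard deviation on the transformed scale; > 0.
#' @param data A `transformed_data` from [linearize()].
#' @param slopes Named numeric vector of per-player slopes covering every
#'   player in `data`, or a single unnamed global slope.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(f, sigma, data, slopes) {
  stopifnot(inherits(f, "age_function"), inherits(data, "transformed_data"))
  if (sigma <= 0) stop("sigma must be > 0")
  if (f$family != data$family) {
    stop("function family '", f$family, "' does not match transform family '",
         data$family, "'")
  }
  if (length(slopes) == 1L && is.null(names(slopes))) {
    slope_i <- rep(as.numeric(slopes), length(data$y))
  } else {
    missing_p <- setdiff(unique(data$player_id), names(slopes))
    if (length(missing_p) > 0L) {
      stop("no slope supplied for player(s): ",
           paste(utils::head(missing_p, 10L), collapse = ", "))
    }
    slope_i <- as.numeric(slopes[data$player_id])
  }
  intercept <- if (data$transform_kind == "identity") f$alpha else log(f$alpha)
  mu <- intercept + slope_i * data$x
  sum(stats::dnorm(data$y, mean = mu, sd = sigma, log = TRUE))
}
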