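#' Ordinal codes for the five playing positions
#'
#' Guard-to-center ordinal scale used whenever position enters a model as a
#' numeric covariate: PG = 1, SG = 2, SF = 3, PF = 4, C = 5. The coding is a
#' package convention (court-role order); any strictly monotone recoding can
#' be supplied to [encode_position()].
#'
#' @format Named integer vector of length 5.
#' @export
position_codes <- c(PG = 1L, SG = 2L, SF = 3L, PF = 4L, C = 5L)

#' Encode playing position as a numeric covariate
#'
#' @param position Character vector of position codes; must be one of
#'   `"PG"`, `"SG"`, `"SF"`, `"PF"`, `"C"` (strict, case-sensitive).
#' @param codes Named numeric vector mapping codes to numbers; defaults to
#'   [position_codes].
#' @return Numeric vector of the same length as `position`.
#' @examples
#' encode_position(c("PG", "C"))
#' @export
encode_position <- function(position, codes = position_codes) {
  position <- as.character(position)
  bad <- setdiff(unique(position[!is.na(position)]), names(codes))
  if (length(bad) > 0L) {
    stop("unknown position code(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(names(codes), collapse = ", "))
  }
  unname(codes[position])
}

.required_cols <- function(metric) {
  c("player_id", "season", "age", metric, "mp_per_game", "position")
}

#' Construct and validate a career table
#'
#' A career table is a long-format data frame with one row per player-season,
#' the unit of data every fitter in the package consumes. Rows that violate
#' row-level invariants (age outside 17-45, negative minutes, unknown
#' position, non-finite performance) are dropped and reported; structural
#' violations (duplicate player-season pairs) are errors.
#'
#' @param df Data frame with columns `player_id`, `season`, `age`, the
#'   performance metric, `mp_per_game`, `position`.
#' @param metric Name of the performance column (default `"performance"`).
#' @return A `career_table`: a data frame with standardized columns
#'   `player_id`, `season`, `age`, `performance`, `mp_per_game`, `position`,
#'   sorted by player then age, with attributes `metric_name` and
#'   `validation` (a row-level rejection report, see [validation_report()]).
#' @export
career_table <- function(df, metric = "performance") {
  req <- .required_cols(metric)
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    player_id   = as.character(df$player_id),
    season      = as.integer(df$season),
    age         = as.integer(df$age),
    performance = as.numeric(df[[metric]]),
    mp_per_game = as.numeric(df$mp_per_game),
    position    = as.character(df$position),
    stringsAsFactors = FALSE
  )

  reasons <- character(nrow(out))
  flag <- function(cond, why) {
    cond <- !is.na(cond) & cond
    reasons[cond] <<- ifelse(nzchar(reasons[cond]),
                             paste(reasons[cond], why, sep = "; "), why)
  }
  flag(is.na(out$age) | out$age < 17L | out$age > 45L, "age outside [17, 45]")
  flag(is.na(out$mp_per_game) | out$mp_per_game < 0, "mp_per_game < 0 or missing")
  flag(!out$position %in% names(position_codes),
       paste0("position not in {", paste(names(position_codes), collapse = ", "), "}"))
  flag(!is.finite(out$performance), "non-finite performance")
  flag(is.na(out$season), "missing season")

  rejected <- data.frame(row = which(nzchar(reasons)),
                         player_id = out$player_id[nzchar(reasons)],
                         season = out$season[nzchar(reasons)],
                         reason = reasons[nzchar(reasons)],
                         stringsAsFactors = FALSE)
  out <- out[!nzchar(reasons), , drop = FALSE]

  key <- paste(out$player_id, out$season, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (player_id, season) pair(s): ",
         paste(gsub("\r", "/", dup), collapse = ", "))
  }

  out <- out[order(out$player_id, out$age), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            metric_name = metric,
            validation = list(n_input = nrow(df), n_kept = nrow(out),
                              rejected = rejected),
            class = c("career_table", "data.frame"))
}

#' Read a career table from CSV
#'
#' @param path Path to a CSV file with a header row.
#' @param metric Name of the performance column to use (e.g. `"ws"`).
#' @return A validated [career_table()] whose `performance` column is the
#'   requested metric.
#' @export
read_careers <- function(path, metric = "ws") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  career_table(df, metric = metric)
}

#' Write a career table back to CSV
#'
#' Writes the retained (validated) rows in the same long format that
#' [read_careers()] accepts, with the performance column named after the
#' metric in use, plus an optional JSON validation report.
#'
#' @param data A `career_table`.
#' @param path Output CSV path.
#' @param report_path Optional path for a JSON validation report.
#' @return `path`, invisibly.
#' @export
write_careers <- function(data, path, report_path = NULL) {
  stopifnot(inherits(data, "career_table"))
  out <- as.data.frame(data)
  names(out)[names(out) == "performance"] <- attr(data, "metric_name")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(validation_report(data), report_path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Row-level validation report of a career table
#'
#' @param data A `career_table`.
#' @return List with `n_input`, `n_kept` and a `rejected` data frame
#'   (row, player_id, season, reason).
#' @export
validation_report <- function(data) {
  stopifnot(inherits(data, "career_table"))
  attr(data, "validation")
}

#' @export
print.career_table <- function(x, ...) {
  v <- attr(x, "validation")
  cat(sprintf("<career_table> %d rows, %d players, metric '%s'\n",
              nrow(x), length(unique(x$player_id)), attr(x, "metric_name")))
  if (!is.null(v) && nrow(v$rejected) > 0L) {
    cat(sprintf("  %d input row(s) rejected at validation\n", nrow(v$rejected)))
  }
  NextMethod()
}

.subset_careers <- function(data, keep) {
  out <- as.data.frame(data)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, metric_name = attr(data, "metric_name"),
            class = c("career_table", "data.frame"))
}

#' Split a career table into pre-peak and post-peak phases
#'
#' The cutoff convention is that the cutoff age itself belongs to the rising
#' (pre-peak) phase: the growth function is taken to be active up to and
#' including the cutoff season, so `prepeak` holds ages `<= cutoff_age` and
#' `postpeak` ages `> cutoff_age`. The split is an exact partition.
#'
#' @param data A `career_table`.
#' @param cutoff_age Integer cutoff age in years, in `[20, 35]`; default 27,
#'   the age at which aggregate performance change turns negative in elite
#'   basketball.
#' @return A `phase_split` list with elements `cutoff_age`, `prepeak`,
#'   `postpeak` (both `career_table`s).
#' @export
split_phases <- function(data, cutoff_age = 27L) {
  stopifnot(inherits(data, "career_table"))
  cutoff_age <- as.integer(cutoff_age)
  if (cutoff_age < 20L || cutoff_age > 35L) {
    stop("cutoff_age must be in [20, 35], got ", cutoff_age)
  }
  structure(list(cutoff_age = cutoff_age,
                 prepeak  = .subset_careers(data, data$age <= cutoff_age),
                 postpeak = .subset_careers(data, data$age > cutoff_age)),
            class = "phase_split")
}

#' @export
print.phase_split <- function(x, ...) {
  cat(sprintf("<phase_split> cutoff %d: %d pre-peak rows, %d post-peak rows\n",
              x$cutoff_age, nrow(x$prepeak), nrow(x$postpeak)))
  invisible(x)
}

#' Aggregate a per-season covariate into per-player phase values
#'
#' Collapses a season-level covariate (minutes per game by default) into one
#' pre-peak value `X1` (ages `<= cutoff_age`) and one post-peak value `X2`
#' (ages `> cutoff_age`) per player. A player with no seasons in a phase gets
#' `NA` for that phase, never a silent zero. The player's (modal) position is
#' carried along as a numeric code for use as an additional indicator.
#'
#' @param data A `career_table`.
#' @param cutoff_age Integer cutoff age; default 27.
#' @param covariate Column to aggregate; default `"mp_per_game"`.
#' @param method `"mean"` (default) or `"sum"`.
#' @return Data frame with columns `player_id`, `X1`, `X2`, `position_code`,
#'   class `covariate_summary`.
#' @export
aggregate_covariates <- function(data, cutoff_age = 27L,
                                 covariate = "mp_per_game",
                                 method = c("mean", "sum")) {
  stopifnot(inherits(data, "career_table"))
  method <- match.arg(method)
  if (!covariate %in% names(data)) stop("no such covariate column: ", covariate)
  v <- data[[covariate]]
  if (!is.numeric(v)) stop("covariate must be numeric: ", covariate)
  agg <- switch(method, mean = mean, sum = sum)
  players <- sort(unique(data$player_id))
  one <- function(p) {
    rows <- data$player_id == p
    pre <- v[rows & data$age <= cutoff_age]
    post <- v[rows & data$age > cutoff_age]
    pos <- data$position[rows]
    pos_mode <- names(sort(table(pos), decreasing = TRUE))[1L]
    c(X1 = if (length(pre)) agg(pre) else NA_real_,
      X2 = if (length(post)) agg(post) else NA_real_,
      position_code = encode_position(pos_mode))
  }
  m <- t(vapply(players, one, numeric(3)))
  structure(data.frame(player_id = players, m, row.names = NULL,
                       stringsAsFactors = FALSE),
            cutoff_age = as.integer(cutoff_age), covariate = covariate,
            method = method,
            class = c("covariate_summary", "data.frame"))
}
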