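#' Write and read the analytic dataset
#'
#' The analytic export is a CSV with exactly the columns `person_id`,
#' `survey_year`, `sex`, `age_group`, `econ_activity`, `income_q`, `imd_q`,
#' `region`, `responded`, `attempts`, `int_weight`, `drinks_now`,
#' `drink_days`, `max_day_units`, `weekly_units`, one row per sampled adult,
#' with missing values written as empty fields. The truth table (true
#' drinking values for every sampled adult, used only for oracle checks) can
#' be written alongside. The round trip is lossless for the analytic schema.
#'
#' @param data A `cor_survey` data frame.
#' @param path Output CSV path for the analytic table.
#' @param truth_path Optional path for the truth table attached to `data`.
#' @return `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(data, path, truth_path = NULL) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(analytic_columns, names(data))
  if (length(missing_cols)) {
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  write.csv(data[analytic_columns], path, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    truth <- attr(data, "truth")
    if (is.null(truth)) stop("dataset carries no truth table")
    write.csv(truth, truth_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_dataset
#' @param truth_path For `read_dataset()`, an optional truth-table CSV to
#'   re-attach.
#' @return `read_dataset()` returns a validated `cor_survey` data frame.
#' @export
read_dataset <- function(path, truth_path = NULL) {
  raw <- read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(analytic_columns, names(raw))
  if (length(missing_cols)) {
    stop(
      "schema error reading '", path, "': missing column(s) ",
      paste(missing_cols, collapse = ", ")
    )
  }
  out <- raw[analytic_columns]
  out$sex <- as_survey_factor(out$sex, sex_levels, "sex")
  out$age_group <- as_survey_factor(out$age_group, age_levels, "age_group")
  out$econ_activity <-
    as_survey_factor(out$econ_activity, econ_levels, "econ_activity")
  out$region <- as_survey_factor(out$region, region_levels, "region")
  out$responded <- as.logical(out$responded)
  out$drinks_now <- as.logical(out$drinks_now)
  class(out) <- c("cor_survey", "data.frame")
  validate_dataset(out)
  if (!is.null(truth_path)) {
    attr(out, "truth") <- read.csv(truth_path, na.strings = "")
  }
  attr(out, "response_rate") <- mean(out$responded)
  out
}

#' Validate the analytic schema
#'
#' Enforces the row-level invariants of the analytic dataset: participants
#' have attempts in `[1, max_attempts]` and a positive interview weight;
#' non-participants have no attempts, no weight and no drinking fields;
#' drinking days lie in 0-7 and unit variables are non-negative. Errors name
#' the offending column and first offending row.
#'
#' @param data A `cor_survey` data frame.
#' @param max_attempts Upper cap for attempts (default 18).
#' @return The dataset, invisibly, if valid.
#' @export
validate_dataset <- function(data, max_attempts = 18L) {
  fail <- function(column, rows, why) {
    stop(
      "invalid dataset: column '", column, "', row ", rows[1], ": ", why,
      call. = FALSE
    )
  }
  if (anyNA(data$responded)) {
    fail("responded", which(is.na(data$responded)), "must be TRUE/FALSE")
  }
  resp <- data$responded
  bad <- resp & (is.na(data$attempts) | data$attempts < 1 |
                   data$attempts > max_attempts)
  if (any(bad)) {
    fail("attempts", which(bad), "participants need attempts in 1..cap")
  }
  bad <- !resp & !is.na(data$attempts)
  if (any(bad)) fail("attempts", which(bad), "non-participant with attempts")
  bad <- resp & (is.na(data$int_weight) | data$int_weight <= 0)
  if (any(bad)) {
    fail("int_weight", which(bad), "participants need a positive weight")
  }
  for (col in c("drinks_now", "drink_days", "max_day_units",
                "weekly_units")) {
    bad <- !resp & !is.na(data[[col]])
    if (any(bad)) fail(col, which(bad), "non-participant with drinking data")
  }
  bad <- !is.na(data$drink_days) &
    (data$drink_days < 0 | data$drink_days > 7)
  if (any(bad)) fail("drink_days", which(bad), "must lie in 0..7")
  for (col in c("max_day_units", "weekly_units")) {
    bad <- !is.na(data[[col]]) & data[[col]] < 0
    if (any(bad)) fail(col, which(bad), "must be non-negative")
  }
  invisible(data)
}
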