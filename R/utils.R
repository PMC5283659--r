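# Internal helpers shared across modules.

# Deterministic per-stage sub-seed derived from one top-level seed, so that
# each simulation stage has its own reproducible stream. Arithmetic is kept
# below 2^53 so it is exact in doubles.
stage_seed <- function(seed, stage) {
  stages <- c(population = 1, fielding = 2, drinking = 3, missingness = 4)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  s <- (as.numeric(seed) %% 2147483647) * 16807 + stages[[stage]] * 2654435
  as.integer(s %% 2147483647) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a p-value the way epidemiology tables print them.
format_pvalue <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

fmt1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))

sex_levels <- c("men", "women")
age_levels <- c("18-34", "35-54", "55+")
econ_levels <- c("in work", "not in work")
region_levels <- c(
  "North East", "North West", "Yorkshire & The Humber", "East Midlands",
  "West Midlands", "East of England", "London", "South East", "South West"
)

# Columns of the analytic export, in order.
analytic_columns <- c(
  "person_id", "survey_year", "sex", "age_group", "econ_activity",
  "income_q", "imd_q", "region", "responded", "attempts", "int_weight",
  "drinks_now", "drink_days", "max_day_units", "weekly_units"
)

as_survey_factor <- function(x, levels, column) {
  bad <- !is.na(x) & !x %in% levels
  if (any(bad)) {
    stop(
      "invalid value(s) in column '", column, "': ",
      paste(unique(x[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  factor(x, levels = levels)
}
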