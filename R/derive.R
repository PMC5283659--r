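#' Sex-specific drinking guideline thresholds
#'
#' The pre-2016 UK guideline thresholds, in UK units (1 unit = 8 g ethanol;
#' inputs are assumed to be unit totals already, no conversion is done):
#' more than 4 (men) / 3 (women) units on the heaviest drinking day for the
#' daily guideline, more than 8/6 units for heavy episodic drinking and more
#' than 21/14 units per week for the weekly guideline. All comparisons are
#' strictly greater than, so a value exactly at the threshold does not
#' exceed it.
#'
#' @param daily_limit,heavy_episodic,weekly_limit Named numeric vectors
#'   with elements `men` and `women`. Override to run sensitivity settings,
#'   e.g. `weekly_limit = c(men = 14, women = 14)` for the post-2016
#'   guideline.
#' @return A list of class `drinking_thresholds`.
#' @examples
#' drinking_thresholds()
#' @export
drinking_thresholds <- function(daily_limit = c(men = 4, women = 3),
                                heavy_episodic = c(men = 8, women = 6),
                                weekly_limit = c(men = 21, women = 14)) {
  thr <- list(
    daily_limit = daily_limit,
    heavy_episodic = heavy_episodic,
    weekly_limit = weekly_limit
  )
  for (nm in names(thr)) {
    v <- thr[[nm]]
    if (!all(c("men", "women") %in% names(v))) {
      stop("threshold '", nm, "' needs named elements men and women")
    }
    if (any(v <= 0)) stop("threshold '", nm, "' must be positive")
    if (v[["men"]] < v[["women"]]) {
      stop("threshold '", nm, "': men's limit must be >= women's")
    }
  }
  class(thr) <- "drinking_thresholds"
  thr
}

#' Contact-attempt dichotomy
#'
#' Splits total contact attempts into the easy-to-contact group (1-6 calls,
#' about 80% of participants) and the hard-to-contact group (7 or more).
#'
#' @param attempts Integer vector of total contact attempts (participants
#'   only; must be `>= 1`, `NA` not allowed).
#' @return A factor with levels `LOW` (1-6) and `HIGH` (7+).
#' @examples
#' contact_group(c(1L, 6L, 7L, 18L))
#' @export
contact_group <- function(attempts) {
  if (anyNA(attempts)) {
    stop("attempts must not be missing: non-participants have no group")
  }
  if (any(attempts < 1)) stop("attempts must be >= 1")
  factor(ifelse(attempts <= 6, "LOW", "HIGH"), levels = c("LOW", "HIGH"))
}

#' Derive analytic indicators from raw drinking fields
#'
#' Adds to the dataset the guideline-exceedance indicators (`exceed_daily`,
#' `heavy_episodic`, `exceed_weekly`), the current-drinker indicator
#' (`is_drinker`) and the contact-attempt group (`contact_group`, `NA` for
#' non-participants). Exceedance is a strictly-greater-than comparison of
#' the unit variable against the sex-specific threshold; indicator
#' missingness exactly mirrors the missingness of the source field
#' (complete-case propagation). Non-drinkers stay in the denominators of
#' the exceedance indicators. `drink_days` and `max_day_units` are measured
#' only among adults who drank in the last week; downstream tables restrict
#' them to rows with `drink_days >= 1`. Re-deriving an already-derived
#' dataset simply recomputes the same columns.
#'
#' @param data A `cor_survey` data frame.
#' @param thresholds A [drinking_thresholds()] object.
#' @return The dataset with the five derived columns appended.
#' @examples
#' svy <- simulate_survey(default_config(n_sampled = 2000L))
#' head(derive_indicators(svy))
#' @export
derive_indicators <- function(data, thresholds = drinking_thresholds()) {
  stopifnot(is.data.frame(data))
  if (!inherits(thresholds, "drinking_thresholds")) {
    stop("thresholds must come from drinking_thresholds()")
  }
  sex <- as.character(data$sex)
  known <- sex %in% c("men", "women") | is.na(sex)
  if (!all(known)) {
    stop("unknown sex code: ", paste(unique(sex[!known]), collapse = ", "))
  }
  thr_of <- function(limit) unname(limit[sex])
  out <- data
  out$is_drinker <- data$drinks_now
  out$exceed_daily <- data$max_day_units > thr_of(thresholds$daily_limit)
  out$heavy_episodic <-
    data$max_day_units > thr_of(thresholds$heavy_episodic)
  out$exceed_weekly <- data$weekly_units > thr_of(thresholds$weekly_limit)
  out$contact_group <- factor(NA_character_, levels = c("LOW", "HIGH"))
  has <- !is.na(data$attempts)
  out$contact_group[has] <- contact_group(data$attempts[has])
  attrs <- attributes(data)
  for (a in setdiff(names(attrs), c("names", "row.names", "class"))) {
    attr(out, a) <- attrs[[a]]
  }
  out
}
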