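#' Continuum-of-resistance non-response adjustment
#'
#' The population value of a measure is estimated as the participant
#' estimate and the non-participant estimate weighted by the response
#' proportion: `p * r + h * (1 - r)`, where under the continuum of
#' resistance model the non-participant estimate `h` is taken to be the
#' estimate among the participants who were hardest to contact (7+
#' attempts). The same formula is applied to prevalences and to means. The
#' result always lies between its two estimate arguments, is monotone in
#' each, and is linear in `r`.
#'
#' @param participant_estimate Survey-weighted estimate among all
#'   participants (proportion in `[0, 1]` or non-negative mean).
#' @param hard_group_estimate Survey-weighted estimate among the 7+
#'   attempts group, on the same scale as `participant_estimate`.
#' @param r Response proportion in `(0, 1]`.
#' @return The adjusted estimate.
#' @examples
#' cor_adjust(0.128, 0.172, 0.58) # 0.14648
#' @export
cor_adjust <- function(participant_estimate, hard_group_estimate, r) {
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1)) {
    stop("r must lie in (0, 1]")
  }
  p <- participant_estimate
  h <- hard_group_estimate
  if (any(!is.finite(p)) || any(!is.finite(h))) {
    stop("estimates must be finite")
  }
  if (any(p < 0) || any(h < 0)) stop("estimates must be non-negative")
  is_prop <- function(x) all(x <= 1)
  if (is_prop(p) != is_prop(h)) {
    stop("estimates look like different kinds (proportion vs mean)")
  }
  p * r + h * (1 - r)
}

#' Population consumption estimates under the continuum of resistance
#'
#' Computes, per sex, the seven headline alcohol measures three ways:
#' unadjusted (unweighted participant estimate), survey-weighted, and
#' further adjusted with [cor_adjust()] using the hard-to-contact group's
#' weighted estimate as the stand-in for non-participants. Differences and
#' percentage changes compare the adjusted column with the weighted one and
#' are computed from unrounded intermediates.
#'
#' Measures: prevalence of drinking nowadays; mean drinking days in the
#' last week among last-week drinkers; mean units on the heaviest drinking
#' day among last-week drinkers; prevalence above the daily guideline;
#' prevalence of heavy episodic drinking; mean weekly units (all adults,
#' zeros included); prevalence above the weekly guideline.
#'
#' @param data A derived `cor_survey` dataset.
#' @param r Response proportion(s) used for the adjustment. Default is the
#'   overall individual response rate carried by the dataset (participants
#'   / sampled adults). May also be a named vector with elements `men` and
#'   `women` to use sex-specific proportions.
#' @return A data frame of class `cor_table` with columns `sex`, `measure`,
#'   `kind`, `unadjusted`, `weighted`, `hard_group`, `r`, `adjusted`,
#'   `difference` (adjusted minus weighted) and `pct_change` (100 *
#'   difference / weighted). Prevalence rows are on the percentage scale.
#' @examples
#' svy <- derive_indicators(simulate_survey(default_config(n_sampled = 4000L)))
#' cor_table(svy)
#' @export
cor_table <- function(data, r = NULL) {
  data <- if ("contact_group" %in% names(data)) {
    data
  } else {
    derive_indicators(data)
  }
  if (is.null(r)) {
    r <- attr(data, "response_rate")
    if (is.null(r)) {
      if (all(data$responded)) {
        stop(
          "dataset has no response_rate attribute and contains only ",
          "participants; supply r explicitly"
        )
      }
      r <- response_rate(data)
    }
  }
  r_of <- function(sex) {
    if (length(r) == 1 && is.null(names(r))) r else r[[sex]]
  }
  part <- participants(data)
  measures <- list(
    list(name = "Prevalence of drinking nowadays", var = "is_drinker",
         kind = "percent", last_week = FALSE),
    list(name = "Drinking days in last week, among drinkers (mean number)",
         var = "drink_days", kind = "mean", last_week = TRUE),
    list(name = paste("Alcohol consumed on heaviest drinking day in the",
                      "last week (mean units)"),
         var = "max_day_units", kind = "mean", last_week = TRUE),
    list(name = "Prevalence of drinking above daily guidelines (>4/3 units)",
         var = "exceed_daily", kind = "percent", last_week = FALSE),
    list(name = "Prevalence of heavy episodic drinking (>8/6 units)",
         var = "heavy_episodic", kind = "percent", last_week = FALSE),
    list(name = "Average weekly alcohol consumption (mean units)",
         var = "weekly_units", kind = "mean", last_week = FALSE),
    list(name = "Prevalence of drinking above weekly guidelines (>21/14 units)",
         var = "exceed_weekly", kind = "percent", last_week = FALSE)
  )
  rows <- list()
  for (sex in sex_levels) {
    s <- part[part$sex == sex, ]
    for (m in measures) {
      d <- s[!is.na(s[[m$var]]), ]
      if (m$last_week) d <- d[!is.na(d$drink_days) & d$drink_days >= 1, ]
      hard <- d[d$contact_group == "HIGH", ]
      scale <- if (m$kind == "percent") 100 else 1
      if (m$kind == "percent") {
        unadj <- mean(as.numeric(d[[m$var]]))
        wtd <- weighted_proportion(d[[m$var]], d$int_weight)$estimate
        hg <- weighted_proportion(hard[[m$var]], hard$int_weight)$estimate
      } else {
        unadj <- mean(d[[m$var]])
        wtd <- weighted_mean_sd(d[[m$var]], d$int_weight)$estimate
        hg <- weighted_mean_sd(hard[[m$var]], hard$int_weight)$estimate
      }
      adj <- cor_adjust(wtd, hg, r_of(sex))
      rows[[length(rows) + 1]] <- data.frame(
        sex = sex, measure = m$name, kind = m$kind,
        unadjusted = scale * unadj, weighted = scale * wtd,
        hard_group = scale * hg, r = r_of(sex), adjusted = scale * adj,
        difference = scale * (adj - wtd),
        pct_change = if (wtd != 0) 100 * (adj - wtd) / wtd else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cor_table", "data.frame")
  out
}

#' Coverage of per-capita alcohol sales by survey estimates
#'
#' Survey-estimated mean weekly consumption among all adults divided by
#' per-capita alcohol sales for the same period, as a percentage.
#'
#' @param mean_weekly_units Survey estimate of mean weekly units per adult.
#' @param sales_units_per_capita Per-capita sales, units per adult per week
#'   (e.g. 19.1 for England averaged over the 2011-13 financial years).
#' @return Coverage in percent.
#' @examples
#' sales_coverage(10.9, 19.1) # 57.07
#' @export
sales_coverage <- function(mean_weekly_units, sales_units_per_capita) {
  if (any(mean_weekly_units <= 0) || any(sales_units_per_capita <= 0)) {
    stop("both arguments must be positive")
  }
  100 * mean_weekly_units / sales_units_per_capita
}
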