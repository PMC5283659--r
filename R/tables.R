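#' Demographic characteristics by contact-attempt group
#'
#' For each demographic variable, the interview-weighted row percentages of
#' participants falling in the easy (1-6 attempts) and hard (7+) contact
#' groups, with unweighted counts and a Pearson chi-squared p-value (one
#' test per variable) comparing the two groups, computed on the weighted
#' table via [weighted_chisq()]. If one contact group is empty its columns
#' are `NA` and no test is reported.
#'
#' @param data A derived `cor_survey` dataset (see [derive_indicators()]).
#' @return A data frame with one row per category: `variable`, `category`,
#'   `n_low`, `pct_low`, `n_high`, `pct_high`, weighted bases `wn_low`,
#'   `wn_high`, and `p_value` on the last row of each variable.
#' @export
demographic_table <- function(data) {
  part <- derived_participants(data)
  vars <- c(
    "sex", "age_group", "econ_activity", "income_q", "imd_q", "region"
  )
  rows <- list()
  for (v in vars) {
    d <- part[!is.na(part[[v]]), ]
    p_chi <- tryCatch(
      weighted_chisq(d$contact_group, d[[v]], d$int_weight)$p_value,
      error = function(e) NA_real_
    )
    cats <- if (is.factor(d[[v]])) levels(d[[v]]) else sort(unique(d[[v]]))
    for (cat_i in seq_along(cats)) {
      ci <- d[[v]] == cats[cat_i]
      wt <- tapply(
        d$int_weight[ci], d$contact_group[ci], sum, default = 0
      )
      wt[is.na(wt)] <- 0
      nn <- table(d$contact_group[ci])
      pct <- if (sum(wt) > 0) 100 * wt / sum(wt) else wt * NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, category = as.character(cats[cat_i]),
        n_low = as.integer(nn[["LOW"]]), pct_low = pct[["LOW"]],
        n_high = as.integer(nn[["HIGH"]]), pct_high = pct[["HIGH"]],
        wn_low = wt[["LOW"]], wn_high = wt[["HIGH"]],
        p_value = if (cat_i == length(cats)) p_chi else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Drinking characteristics by contact-attempt group, per sex
#'
#' The drinking analogue of [demographic_table()]: for each binary drinking
#' indicator the weighted percentage in each contact group with a Pearson
#' chi-squared p-value, and for each continuous measure the weighted mean
#' and SD per group with a weighted Welch t-test p-value. Drinking days and
#' heaviest-day units are restricted to adults who drank in the last week
#' (`drink_days >= 1`); all other rows keep non-drinkers in the
#' denominator. Missingness is handled per variable (pairwise complete
#' case), so unweighted bases differ slightly across rows. If one contact
#' group is empty its columns are `NA` and no test is reported.
#'
#' @param data A derived `cor_survey` dataset.
#' @return A data frame with one row per sex x measure: `est_low`,
#'   `est_high` (percentages for binary rows, means for continuous rows),
#'   `sd_low`/`sd_high` for continuous rows, unweighted (`n_low`, `n_high`)
#'   and weighted (`wn_low`, `wn_high`) bases, and the test `p_value`.
#' @export
drinking_table <- function(data) {
  part <- derived_participants(data)
  binary <- c(
    "Whether drinks nowadays" = "is_drinker",
    "Drank more than daily guideline (>4/3 units)" = "exceed_daily",
    "Heavy episodic drinking (>8/6 units)" = "heavy_episodic",
    "Drank more than weekly guideline (21/14 units)" = "exceed_weekly"
  )
  continuous <- c(
    "Number of drinking days in the past week" = "drink_days",
    "Units consumed on heaviest drinking day in the last week" =
      "max_day_units",
    "Weekly alcohol consumption (UK units)" = "weekly_units"
  )
  last_week_only <- c("drink_days", "max_day_units")
  group_est <- function(d, v, fun) {
    lapply(c(LOW = "LOW", HIGH = "HIGH"), function(g) {
      di <- d[d$contact_group == g, ]
      if (!nrow(di)) {
        return(list(
          estimate = NA_real_, sd_or_se = NA_real_,
          weighted_n = 0, unweighted_n = 0L
        ))
      }
      fun(di[[v]], di$int_weight)
    })
  }
  rows <- list()
  for (sex in sex_levels) {
    s <- part[part$sex == sex, ]
    for (m_i in seq_along(binary)) {
      v <- binary[[m_i]]
      d <- s[!is.na(s[[v]]), ]
      est <- group_est(d, v, weighted_proportion)
      p <- tryCatch(
        weighted_chisq(d$contact_group, d[[v]], d$int_weight)$p_value,
        error = function(e) NA_real_
      )
      rows[[length(rows) + 1]] <- data.frame(
        sex = sex, measure = names(binary)[m_i], kind = "percent",
        est_low = 100 * est$LOW$estimate, est_high = 100 * est$HIGH$estimate,
        sd_low = NA_real_, sd_high = NA_real_,
        n_low = est$LOW$unweighted_n, n_high = est$HIGH$unweighted_n,
        wn_low = est$LOW$weighted_n, wn_high = est$HIGH$weighted_n,
        p_value = p
      )
    }
    for (m_i in seq_along(continuous)) {
      v <- continuous[[m_i]]
      d <- s[!is.na(s[[v]]), ]
      if (v %in% last_week_only) {
        d <- d[!is.na(d$drink_days) & d$drink_days >= 1, ]
      }
      est <- group_est(d, v, weighted_mean_sd)
      p <- tryCatch(
        weighted_t_test(d[[v]], d$int_weight, d$contact_group)$p_value,
        error = function(e) NA_real_
      )
      rows[[length(rows) + 1]] <- data.frame(
        sex = sex, measure = names(continuous)[m_i], kind = "mean",
        est_low = est$LOW$estimate, est_high = est$HIGH$estimate,
        sd_low = est$LOW$sd_or_se, sd_high = est$HIGH$sd_or_se,
        n_low = est$LOW$unweighted_n, n_high = est$HIGH$unweighted_n,
        wn_low = est$LOW$weighted_n, wn_high = est$HIGH$weighted_n,
        p_value = p
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Both descriptive tables at once
#'
#' @param data A derived `cor_survey` dataset.
#' @return A list with elements `demographics` ([demographic_table()]) and
#'   `drinking` ([drinking_table()]).
#' @export
descriptive_tables <- function(data) {
  list(
    demographics = demographic_table(data),
    drinking = drinking_table(data)
  )
}

derived_participants <- function(data) {
  if (!"contact_group" %in% names(data)) {
    data <- derive_indicators(data)
  }
  part <- participants(data)
  if (!nrow(part)) stop("no participants in dataset")
  part
}
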