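#' Generate a synthetic sampled adult population
#'
#' Draws `n_sampled` adults with independent demographic marginals (sex, age
#' band, economic activity, equivalised income quintile, deprivation
#' quintile, region, survey year) and a latent contact-resistance score:
#' the linear predictor of the resistance loadings plus standard-normal
#' noise. Resistance is the single factor coupling the fielding process and
#' (through the realized contact group) drinking behaviour, which is the
#' smallest mechanism producing "heavier drinkers are harder to reach".
#'
#' @param config A `cor_config`, e.g. [default_config()].
#' @param seed Integer seed; defaults to `config$seed`. The population draw
#'   uses a sub-seed derived deterministically from it.
#' @return A data frame of class `cor_population` with one row per sampled
#'   adult: `person_id`, `survey_year`, `sex`, `age_group`, `econ_activity`,
#'   `income_q`, `imd_q`, `region` and the latent `resistance` (simulation
#'   only; never part of the analytic export).
#' @examples
#' pop <- generate_population(default_config(n_sampled = 500L))
#' table(pop$age_group)
#' @export
generate_population <- function(config, seed = config$seed) {
  validate_config(config)
  set.seed(stage_seed(seed, "population"))
  n <- as.integer(config$n_sampled)
  m <- config$demographic_marginals
  draw <- function(p, levels = names(p)) {
    factor(sample(levels, n, replace = TRUE, prob = p), levels = levels)
  }
  pop <- data.frame(
    person_id = seq_len(n),
    survey_year = sample(config$survey_years, n, replace = TRUE),
    sex = draw(m$sex),
    age_group = draw(m$age_group),
    econ_activity = draw(m$econ_activity),
    income_q = sample.int(5L, n, replace = TRUE, prob = m$income_quintile),
    imd_q = sample.int(5L, n, replace = TRUE, prob = m$deprivation_quintile),
    region = draw(m$region)
  )
  lo <- config$resistance_loadings
  pop$resistance <- lo$age_group[as.character(pop$age_group)] +
    lo$econ_activity[as.character(pop$econ_activity)] +
    lo$region[as.character(pop$region)] +
    rnorm(n, sd = config$resistance_noise_sd %||% 1)
  names(pop$resistance) <- NULL
  class(pop) <- c("cor_population", "data.frame")
  pop
}

#' Simulate survey fielding and drinking behaviour
#'
#' Runs the two-stage contact process for every sampled adult. A person is
#' first either willing to ever cooperate (Bernoulli with probability
#' `plogis(willingness_intercept - willingness_slope * resistance)`), which
#' separates refusal from non-contact. A willing person is then contacted on
#' attempt k with probability
#' `plogis(contact_intercept - contact_slope * resistance + f(k))`, where
#' `f` is the piecewise-linear attempt effect of the configuration; the
#' first success is the recorded number of attempts, and anyone not reached
#' within `max_attempts` is a non-respondent. Interview weights are added
#' with [compute_weights()].
#'
#' Drinking variables are then drawn from the per-sex drinking model given
#' demographics and the person's contact stratum: participants who needed 7+
#' attempts form the hard-to-contact stratum, and non-participants are
#' assigned to the same stratum (optionally shifted by
#' `nonparticipant_extra_logodds`), which is exactly the continuum of
#' resistance assumption. True drinking values for everyone, including
#' non-participants, are kept in the attached truth table; in the analytic
#' columns the drinking fields of non-participants are missing.
#'
#' @param population A `cor_population` from [generate_population()].
#' @param config The same `cor_config` used to generate the population.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data frame of class `cor_survey` with the analytic columns
#'   (`person_id`, `survey_year`, demographics, `responded`, `attempts`,
#'   `int_weight`, drinking fields) and two attributes: `truth`, a data
#'   frame with complete drinking values for every sampled adult, and
#'   `response_rate`, participants divided by sampled adults.
#' @examples
#' cfg <- default_config(n_sampled = 2000L)
#' svy <- simulate_fielding(generate_population(cfg), cfg)
#' mean(svy$responded)
#' @export
simulate_fielding <- function(population, config, seed = config$seed) {
  stopifnot(inherits(population, "cor_population"))
  validate_config(config)
  n <- nrow(population)
  r <- population$resistance

  set.seed(stage_seed(seed, "fielding"))
  willing <- runif(n) < plogis(
    config$willingness_intercept - config$willingness_slope * r
  )
  attempts <- rep(NA_integer_, n)
  pending <- willing
  base_eta <- config$contact_intercept - config$contact_slope * r
  for (k in seq_len(config$max_attempts)) {
    if (!any(pending)) break
    p_k <- plogis(base_eta[pending] + attempt_effect(k, config))
    hit <- runif(sum(pending)) < p_k
    attempts[which(pending)[hit]] <- k
    pending[pending] <- !hit
  }
  responded <- willing & !is.na(attempts)
  attempts[!responded] <- NA_integer_

  out <- population
  out$resistance <- NULL
  out$responded <- responded
  out$attempts <- attempts
  out$int_weight <- NA_real_

  hard <- (responded & attempts >= 7L) | !responded
  drink <- draw_drinking(
    population, hard, nonpart = !responded, config,
    stage_seed(seed, "drinking")
  )
  truth <- cbind(
    out[c("person_id", "survey_year", "sex", "age_group", "econ_activity",
          "income_q", "imd_q", "region", "responded", "attempts")],
    drink
  )

  out <- cbind(out, drink)
  out[!responded, names(drink)] <- NA

  # item non-response among participants (missing completely at random)
  set.seed(stage_seed(seed, "missingness"))
  miss <- config$item_missingness
  if (!is.null(miss) && any(miss > 0)) {
    idx <- which(responded)
    for (col in c("drinks_now", "drink_days", "max_day_units",
                  "weekly_units")) {
      drop <- idx[runif(length(idx)) < miss[["drinking"]]]
      out[drop, col] <- NA
    }
    drop <- idx[runif(length(idx)) < miss[["income"]]]
    out[drop, "income_q"] <- NA
  }

  out <- out[analytic_columns]
  class(out) <- c("cor_survey", "data.frame")
  out <- compute_weights(out)
  attr(out, "truth") <- truth
  attr(out, "response_rate") <- mean(responded)
  out
}

# Piecewise-linear attempt effect with knots after attempts 6 and 8.
attempt_effect <- function(k, config) {
  s <- config$contact_attempt_effects
  km1 <- k - 1
  s[["upto6"]] * pmin(km1, 5) +
    s[["upto8"]] * pmin(pmax(km1 - 5, 0), 2) +
    s[["beyond8"]] * pmax(km1 - 7, 0)
}

# Draw all drinking variables given demographics and contact stratum.
# A single uniform drives the nested binary outcomes (heavy episodic <=
# exceeded daily <= drank last week <= drinks nowadays), so each outcome's
# marginal is exactly logistic in the covariates while consistency between
# the indicators and the continuous unit variables holds by construction.
draw_drinking <- function(population, hard, nonpart, config, seed) {
  set.seed(seed)
  n <- nrow(population)
  thr <- config$thresholds
  extra <- config$nonparticipant_extra_logodds

  drinks_now <- logical(n)
  last_week <- logical(n)
  exceed_daily <- logical(n)
  heavy <- logical(n)
  exceed_weekly <- logical(n)
  drink_days <- integer(n)
  max_day <- numeric(n)
  weekly <- numeric(n)

  u1 <- runif(n)
  u2 <- runif(n)

  for (sex in sex_levels) {
    i <- population$sex == sex
    if (!any(i)) next
    blk <- config$drinking_model[[sex]]
    eta <- function(cf) {
      cf[["intercept"]] +
        cf[["age_18_34"]] * (population$age_group[i] == "18-34") +
        cf[["age_35_54"]] * (population$age_group[i] == "35-54") +
        cf[["in_work"]] * (population$econ_activity[i] == "in work") +
        cf[["income"]] * (population$income_q[i] - 3) +
        cf[["imd"]] * (population$imd_q[i] - 3) +
        cf[["group"]] * hard[i] +
        extra * nonpart[i]
    }
    p_dr <- plogis(eta(blk$binary$drinks_now))
    p_lw <- plogis(eta(blk$binary$last_week))
    p_d <- plogis(eta(blk$binary$exceed_daily))
    p_h <- plogis(eta(blk$binary$heavy_episodic))
    p_w <- plogis(eta(blk$binary$exceed_weekly))

    u <- u1[i]
    heavy[i] <- u < p_h
    exceed_daily[i] <- u < p_d
    last_week[i] <- u < p_lw
    drinks_now[i] <- u < p_dr
    # weekly exceedance nested within current drinkers via a second uniform,
    # keeping its marginal exactly logistic: P = p_dr * (p_w / p_dr) = p_w
    exceed_weekly[i] <- drinks_now[i] & (u2[i] < p_w / p_dr)

    # days drinking last week: 1 + beta-binomial(6) for last-week drinkers
    dc <- blk$days$coef
    mu <- plogis(
      dc[["intercept"]] +
        dc[["age_18_34"]] * (population$age_group[i] == "18-34") +
        dc[["age_35_54"]] * (population$age_group[i] == "35-54") +
        dc[["group"]] * hard[i]
    )
    phi <- blk$days$dispersion
    p_i <- rbeta(sum(i), mu * phi, (1 - mu) * phi)
    days_i <- 1L + rbinom(sum(i), 6L, p_i)
    days_i[!last_week[i]] <- 0L
    drink_days[i] <- days_i

    # heaviest-day units, consistent with the indicator bands
    thr_d <- thr$daily_limit[[sex]]
    thr_h <- thr$heavy_episodic[[sex]]
    md <- blk$max_day
    ni <- sum(i)
    units <- thr_d * rbeta(ni, md$low_shape[1], md$low_shape[2])
    mid <- exceed_daily[i] & !heavy[i]
    units[mid] <- thr_d +
      (thr_h - thr_d) * rbeta(sum(mid), md$mid_shape[1], md$mid_shape[2])
    units[heavy[i]] <- thr_h +
      rgamma(sum(heavy[i]), shape = md$tail_shape, scale = md$tail_scale)
    units[!last_week[i]] <- 0
    max_day[i] <- units

    # average weekly units, consistent with the weekly-guideline indicator
    thr_w <- thr$weekly_limit[[sex]]
    wk <- blk$weekly
    wu <- thr_w * rbeta(ni, wk$mid_shape[1], wk$mid_shape[2])
    wu[exceed_weekly[i]] <- thr_w +
      rgamma(sum(exceed_weekly[i]), shape = wk$tail_shape,
             scale = wk$tail_scale)
    wu[!drinks_now[i]] <- 0
    weekly[i] <- wu
  }

  drink_days[!drinks_now] <- 0L
  max_day[!drinks_now] <- 0
  weekly[!drinks_now] <- 0

  data.frame(
    drinks_now = drinks_now,
    drink_days = drink_days,
    max_day_units = max_day,
    weekly_units = weekly
  )
}

#' Simulate a complete survey in one call
#'
#' Convenience wrapper: [generate_population()] followed by
#' [simulate_fielding()] under the same configuration and seed.
#'
#' @inheritParams generate_population
#' @return A `cor_survey` data frame; see [simulate_fielding()].
#' @examples
#' svy <- simulate_survey(default_config(n_sampled = 2000L), seed = 7)
#' @export
simulate_survey <- function(config = default_config(), seed = config$seed) {
  simulate_fielding(generate_population(config, seed), config, seed)
}

#' Participants-only analytic view
#'
#' @param data A `cor_survey` data frame.
#' @return The participant rows (responded, with an interview weight).
#' @export
participants <- function(data) {
  stopifnot(is.data.frame(data), "responded" %in% names(data))
  data[which(data$responded), , drop = FALSE]
}

#' Overall individual response rate
#'
#' Participants divided by sampled adults, the set-sample definition of the
#' individual response rate.
#'
#' @param data A `cor_survey` data frame covering all sampled adults.
#' @return A single proportion.
#' @export
response_rate <- function(data) {
  stopifnot("responded" %in% names(data))
  mean(data$responded)
}
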