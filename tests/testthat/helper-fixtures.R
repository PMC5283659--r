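# Shared fixtures, all generated in code at test time.

# Cache of derived default-configuration simulations, one per seed, reused
# across test files so the expensive full-size runs happen once.
.sim_cache <- new.env(parent = emptyenv())

default_sim <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- derive_indicators(
      simulate_survey(default_config(), seed = seed)
    )
  }
  .sim_cache[[key]]
}

# Configuration with no drinking-contact coupling: every hard-group effect
# (and the non-participant shift) is zero.
null_coupling_config <- function(..., zero_econ_loading = FALSE) {
  cfg <- default_config(...)
  for (sex in c("men", "women")) {
    for (oc in names(cfg$drinking_model[[sex]]$binary)) {
      cfg$drinking_model[[sex]]$binary[[oc]][["group"]] <- 0
    }
    cfg$drinking_model[[sex]]$days$coef[["group"]] <- 0
  }
  cfg$nonparticipant_extra_logodds <- 0
  if (zero_econ_loading) {
    cfg$resistance_loadings$econ_activity[] <- 0
  }
  validate_config(cfg)
  cfg
}

# Configuration under which non-participants are exactly exchangeable with
# the 7+ participants: response is independent of demographics (all
# resistance loadings zero), so both groups share covariate distribution
# and the hard-stratum drinking model.
exchangeable_config <- function(...) {
  cfg <- default_config(...)
  cfg$resistance_loadings$age_group[] <- 0
  cfg$resistance_loadings$econ_activity[] <- 0
  cfg$resistance_loadings$region[] <- 0
  validate_config(cfg)
  cfg
}

# Hand-built analytic dataset for estimator and weighting tests.
manual_survey <- function(n, responded = rep(TRUE, n),
                          sex = rep("men", n),
                          age_group = rep("35-54", n),
                          region = rep("London", n),
                          attempts = rep(1L, n),
                          int_weight = rep(1, n),
                          drinks_now = rep(TRUE, n),
                          drink_days = rep(2L, n),
                          max_day_units = rep(2, n),
                          weekly_units = rep(5, n)) {
  attempts[!responded] <- NA_integer_
  int_weight[!responded] <- NA_real_
  out <- data.frame(
    person_id = seq_len(n),
    survey_year = 2011L,
    sex = factor(sex, levels = c("men", "women")),
    age_group = factor(age_group, levels = c("18-34", "35-54", "55+")),
    econ_activity = factor("in work", levels = c("in work", "not in work")),
    income_q = 3L, imd_q = 3L,
    region = factor(region, levels = levels(default_sim_region_levels())),
    responded = responded, attempts = attempts, int_weight = int_weight,
    drinks_now = drinks_now, drink_days = drink_days,
    max_day_units = max_day_units, weekly_units = weekly_units
  )
  for (col in c("drinks_now", "drink_days", "max_day_units",
                "weekly_units")) {
    out[[col]][!responded] <- NA
  }
  class(out) <- c("cor_survey", "data.frame")
  out
}

default_sim_region_levels <- function() {
  factor(character(), levels = c(
    "North East", "North West", "Yorkshire & The Humber", "East Midlands",
    "West Midlands", "East of England", "London", "South East",
    "South West"
  ))
}

analytic_cols <- function() corsurvey:::analytic_columns
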