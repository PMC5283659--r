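#' Packaged default generator configuration
#'
#' Returns the configuration under which the fielding simulator reproduces
#' the published fielding profile of a large English general-population
#' health survey over three years: an individual response rate of 58% of
#' sampled adults, a mean of 4.44 contact attempts (SD 2.84) among
#' participants, 18.8% of participants (interview-weighted) requiring 7 or
#' more attempts, and 90% of interviews completed within 8 attempts.
#'
#' The drinking model embeds the fully-adjusted conditional odds ratios for
#' the hard-to-contact (7+ attempts) group reported for that survey: for
#' women, 1.19 for exceeding the daily guideline and 1.23 for heavy episodic
#' drinking; for men, 1.14 (drinks nowadays), 1.12 (daily guideline), 1.10
#' (heavy episodic) and 1.09 (weekly guideline). Marginal prevalences in the
#' 7+ group are calibrated to the published weighted descriptive table
#' (e.g. heavy episodic drinking 24.3% in men, 17.2% in women).
#'
#' The latent-resistance, willingness and contact parameters were calibrated
#' once by moment matching against the five fielding tolerances and are
#' frozen here; see the methods vignette for the calibration procedure.
#'
#' @param ... Named elements overriding parts of the default configuration,
#'   merged recursively (e.g. `n_sampled = 1000`).
#'
#' @return An object of class `cor_config`: a named list with components
#'   `n_sampled`, `survey_years`, `demographic_marginals`,
#'   `resistance_loadings`, `willingness_intercept`, `willingness_slope`,
#'   `contact_intercept`, `contact_slope`, `contact_attempt_effects`,
#'   `max_attempts`, `thresholds`, `drinking_model`, `item_missingness`,
#'   `nonparticipant_extra_logodds` and `seed`.
#'
#' @examples
#' cfg <- default_config()
#' cfg$max_attempts
#' exp(cfg$drinking_model$women$binary$heavy_episodic[["group"]])
#' @export
default_config <- function(...) {
  cfg <- list(
    n_sampled = 44303L,
    survey_years = c(2011L, 2012L, 2013L),
    demographic_marginals = list(
      sex = c(men = 0.487, women = 0.513),
      age_group = c("18-34" = 0.286, "35-54" = 0.359, "55+" = 0.355),
      econ_activity = c("in work" = 0.580, "not in work" = 0.420),
      income_quintile = c(0.186, 0.187, 0.193, 0.221, 0.213),
      deprivation_quintile = c(0.201, 0.211, 0.211, 0.193, 0.184),
      region = c(
        "North East" = 0.0507, "North West" = 0.1331,
        "Yorkshire & The Humber" = 0.1012, "East Midlands" = 0.0867,
        "West Midlands" = 0.1057, "East of England" = 0.1096,
        "London" = 0.1475, "South East" = 0.1631, "South West" = 0.1024
      )
    ),
    resistance_loadings = list(
      age_group = c("18-34" = 0.50, "35-54" = 0.25, "55+" = 0.00),
      econ_activity = c("in work" = 0.30, "not in work" = 0.00),
      region = c(
        "North East" = 0.15, "North West" = 0.10,
        "Yorkshire & The Humber" = -0.25, "East Midlands" = 0.00,
        "West Midlands" = 0.05, "East of England" = -0.05,
        "London" = 0.40, "South East" = -0.10, "South West" = -0.15
      )
    ),
    resistance_noise_sd = 1,
    # Willingness to ever cooperate: P(willing) = plogis(a - b * resistance).
    willingness_intercept = 0.8655222345,
    willingness_slope = 1.0723016848,
    # Per-attempt contact success: P(success at attempt k) =
    # plogis(a - b * resistance + attempt effect(k)); the attempt effect is
    # piecewise linear in (k - 1) with knots after attempts 6 and 8,
    # reflecting appointment-making once a household has been identified and
    # slower progress on long-running cases.
    contact_intercept = -2.0327663917,
    contact_slope = 0.8143825463,
    contact_attempt_effects = c(
      upto6 = 0.3888830696, upto8 = -0.2079926121, beyond8 = 0.3854280526
    ),
    max_attempts = 18L,
    thresholds = NULL, # filled below with drinking_thresholds()
    drinking_model = list(
      men = drinking_block_men(),
      women = drinking_block_women()
    ),
    item_missingness = c(drinking = 0.01, income = 0.15),
    # Extra log-odds applied to every binary drinking outcome for
    # non-participants, on top of the hard-group effect. Zero means
    # non-participants drink like hard-to-contact participants with the
    # same covariates (the continuum of resistance holds in the generator).
    nonparticipant_extra_logodds = 0,
    seed = 1L
  )
  cfg$thresholds <- drinking_thresholds()
  override <- list(...)
  if (length(override)) {
    if (is.null(names(override)) || any(names(override) == "")) {
      stop("overrides to default_config() must be named")
    }
    cfg <- modifyList(cfg, override)
  }
  class(cfg) <- "cor_config"
  validate_config(cfg)
  cfg
}

# Binary-outcome coefficients share the layout
# (intercept, age_18_34, age_35_54, in_work, income, imd, group):
# age contrasts are against 55+, income and deprivation enter linearly as
# (quintile - 3), and `group` is the conditional log-odds effect of being in
# the hard-to-contact (7+ attempts) stratum. Intercepts were calibrated so
# the interview-weighted marginal prevalence in the 7+ group matches the
# published weighted descriptive values.
drinking_block_men <- function() {
  list(
    binary = list(
      drinks_now = c(
        intercept = 1.08116, age_18_34 = 0.25, age_35_54 = 0.20,
        in_work = 0.50, income = 0.18, imd = -0.08, group = log(1.14)
      ),
      last_week = c(
        intercept = 0.12549, age_18_34 = 0.45, age_35_54 = 0.35,
        in_work = 0.35, income = 0.12, imd = -0.02, group = log(1.05)
      ),
      exceed_daily = c(
        intercept = -1.16892, age_18_34 = 1.10, age_35_54 = 0.55,
        in_work = 0.30, income = 0.10, imd = 0.05, group = log(1.12)
      ),
      heavy_episodic = c(
        intercept = -2.05278, age_18_34 = 1.10, age_35_54 = 0.55,
        in_work = 0.30, income = 0.10, imd = 0.05, group = log(1.10)
      ),
      exceed_weekly = c(
        intercept = -1.71057, age_18_34 = 0.45, age_35_54 = 0.40,
        in_work = 0.30, income = 0.15, imd = -0.03, group = log(1.09)
      )
    ),
    days = list(
      coef = c(
        intercept = -0.22701, age_18_34 = -0.55, age_35_54 = -0.25,
        group = -0.12
      ),
      dispersion = 1.4
    ),
    max_day = list(
      low_shape = c(1.4, 1.4), mid_shape = c(1.5, 1.5),
      tail_shape = 1.1, tail_scale = 7.0
    ),
    weekly = list(
      mid_shape = c(1.3, 2.0), tail_shape = 1.0, tail_scale = 20
    )
  )
}

drinking_block_women <- function() {
  list(
    binary = list(
      drinks_now = c(
        intercept = 0.64044, age_18_34 = 0.20, age_35_54 = 0.20,
        in_work = 0.50, income = 0.20, imd = -0.08, group = log(0.96)
      ),
      last_week = c(
        intercept = -0.40778, age_18_34 = 0.50, age_35_54 = 0.35,
        in_work = 0.30, income = 0.12, imd = -0.02, group = log(1.00)
      ),
      exceed_daily = c(
        intercept = -1.80435, age_18_34 = 1.30, age_35_54 = 0.60,
        in_work = 0.35, income = 0.10, imd = 0.05, group = log(1.19)
      ),
      heavy_episodic = c(
        intercept = -2.76030, age_18_34 = 1.30, age_35_54 = 0.60,
        in_work = 0.35, income = 0.10, imd = 0.05, group = log(1.23)
      ),
      exceed_weekly = c(
        intercept = -2.07016, age_18_34 = 0.50, age_35_54 = 0.45,
        in_work = 0.30, income = 0.18, imd = -0.03, group = log(1.05)
      )
    ),
    days = list(
      coef = c(
        intercept = -0.59627, age_18_34 = -0.55, age_35_54 = -0.25,
        group = -0.12
      ),
      dispersion = 1.4
    ),
    max_day = list(
      low_shape = c(1.4, 1.4), mid_shape = c(1.5, 1.5),
      tail_shape = 1.1, tail_scale = 5.5
    ),
    weekly = list(
      mid_shape = c(1.3, 2.2), tail_shape = 1.0, tail_scale = 12
    )
  )
}

#' Validate a generator configuration
#'
#' Checks the structural invariants of a `cor_config`: category
#' probabilities are non-negative and sum to one (within 1e-9) for every
#' demographic variable, sample size and attempt cap are positive, and the
#' binary drinking outcomes are properly nested (heavy episodic implies
#' exceeding the daily guideline implies last-week drinking implies drinking
#' nowadays, and weekly exceedance implies drinking nowadays) for every
#' covariate combination, so that a single latent uniform can drive them.
#'
#' @param config A `cor_config` object.
#' @return The configuration, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "cor_config")) stop("not a cor_config object")
  m <- config$demographic_marginals
  for (nm in names(m)) {
    p <- m[[nm]]
    if (any(p < 0)) stop("negative probability in marginal '", nm, "'")
    if (abs(sum(p) - 1) > 1e-9) {
      stop("marginal '", nm, "' does not sum to 1 (sum = ", sum(p), ")")
    }
  }
  if (config$n_sampled < 1) stop("n_sampled must be >= 1")
  if (config$max_attempts < 1) stop("max_attempts must be >= 1")
  stopifnot(
    is.finite(config$willingness_intercept),
    is.finite(config$willingness_slope),
    is.finite(config$contact_intercept),
    is.finite(config$contact_slope)
  )
  check_drinking_nesting(config)
  invisible(config)
}

# Enumerate all covariate combinations and verify the pointwise probability
# ordering needed for the nested single-uniform construction.
check_drinking_nesting <- function(config) {
  grid <- expand.grid(
    age_group = age_levels, econ_activity = econ_levels,
    income_q = 1:5, imd_q = 1:5, group = c(0, 1), nonpart = c(0, 1),
    stringsAsFactors = FALSE
  )
  extra <- config$nonparticipant_extra_logodds
  for (sex in sex_levels) {
    blk <- config$drinking_model[[sex]]$binary
    eta <- function(cf) {
      cf[["intercept"]] +
        cf[["age_18_34"]] * (grid$age_group == "18-34") +
        cf[["age_35_54"]] * (grid$age_group == "35-54") +
        cf[["in_work"]] * (grid$econ_activity == "in work") +
        cf[["income"]] * (grid$income_q - 3) +
        cf[["imd"]] * (grid$imd_q - 3) +
        cf[["group"]] * grid$group +
        extra * grid$nonpart
    }
    p_dr <- plogis(eta(blk$drinks_now))
    p_lw <- plogis(eta(blk$last_week))
    p_d <- plogis(eta(blk$exceed_daily))
    p_h <- plogis(eta(blk$heavy_episodic))
    p_w <- plogis(eta(blk$exceed_weekly))
    if (any(p_h > p_d) || any(p_d > p_lw) || any(p_lw > p_dr) ||
          any(p_w > p_dr)) {
      stop(
        "drinking model for ", sex, " violates outcome nesting ",
        "(heavy <= daily <= last week <= drinks nowadays, ",
        "weekly <= drinks nowadays) for some covariate combination"
      )
    }
  }
  invisible(TRUE)
}

#' Read or write a generator configuration as YAML
#'
#' The YAML file mirrors the field names of the configuration list.
#' `read_config()` merges the file over the packaged defaults, so a partial
#' file overriding only some fields is valid.
#'
#' @param path Path to a YAML file.
#' @param config A `cor_config` object.
#' @return `read_config()` returns a validated `cor_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- rehydrate_numeric(yaml::read_yaml(path))
  cfg <- modifyList(unclass(default_config()), raw)
  cfg$n_sampled <- as.integer(cfg$n_sampled)
  cfg$max_attempts <- as.integer(cfg$max_attempts)
  if (!inherits(cfg$thresholds, "drinking_thresholds")) {
    cfg$thresholds <- do.call(drinking_thresholds, cfg$thresholds[
      c("daily_limit", "heavy_episodic", "weekly_limit")
    ])
  }
  class(cfg) <- "cor_config"
  validate_config(cfg)
  cfg
}

# YAML maps come back as named lists; coefficient blocks and marginals are
# named numeric vectors in the configuration, so collapse any all-scalar
# numeric map back into a named vector.
rehydrate_numeric <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, rehydrate_numeric)
  scalar_num <- vapply(
    x, function(e) is.numeric(e) && length(e) == 1, logical(1)
  )
  if (length(x) && all(scalar_num) && !is.null(names(x))) {
    return(unlist(x))
  }
  x
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(dehydrate_numeric(unclass(config)), path,
                   precision = 15L)
  invisible(path)
}

# yaml serialises named atomic vectors as plain sequences, losing the
# names; write them as maps (named lists) instead. rehydrate_numeric()
# reverses this on read.
dehydrate_numeric <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, dehydrate_numeric)
    attr(x, "class") <- NULL
    return(x)
  }
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

#' @export
print.cor_config <- function(x, ...) {
  cat("Survey fielding generator configuration\n")
  cat(sprintf(
    "  sampled adults: %d over years %s\n", x$n_sampled,
    paste(x$survey_years, collapse = ", ")
  ))
  cat(sprintf(
    "  willingness: plogis(%.3f - %.3f * resistance)\n",
    x$willingness_intercept, x$willingness_slope
  ))
  cat(sprintf(
    "  contact/attempt: plogis(%.3f - %.3f * resistance + attempt effects), cap %d\n",
    x$contact_intercept, x$contact_slope, x$max_attempts
  ))
  cat(sprintf(
    "  hard-group ORs (women): daily %.2f, heavy episodic %.2f\n",
    exp(x$drinking_model$women$binary$exceed_daily[["group"]]),
    exp(x$drinking_model$women$binary$heavy_episodic[["group"]])
  ))
  invisible(x)
}
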