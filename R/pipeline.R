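#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the generator
#' configuration, thresholds, how to obtain the response proportion used by
#' the adjustment, the per-capita sales figure, output directory, seed and
#' table format.
#'
#' @param generator A `cor_config` (or path to a YAML file readable by
#'   [read_config()]).
#' @param thresholds A [drinking_thresholds()] object.
#' @param r_source `"simulated"` to use the simulated response proportion,
#'   or a fixed number in `(0, 1]`.
#' @param sales_units_per_week Per-capita weekly alcohol sales in UK units
#'   used for the coverage line (default 19.1).
#' @param out_dir Output directory for tables and the run log.
#' @param seed Top-level seed for the run.
#' @param format `"csv"` or `"markdown"`; full-precision CSVs are always
#'   written, `"markdown"` additionally writes formatted twins.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = default_config(),
                       thresholds = drinking_thresholds(),
                       r_source = "simulated",
                       sales_units_per_week = 19.1,
                       out_dir = tempfile("corsurvey_run_"),
                       seed = 1L,
                       format = c("markdown", "csv")) {
  if (is.character(generator)) generator <- read_config(generator)
  validate_config(generator)
  if (!identical(r_source, "simulated")) {
    r_source <- as.numeric(r_source)
    if (is.na(r_source) || r_source <= 0 || r_source > 1) {
      stop("fixed r must lie in (0, 1]")
    }
  }
  structure(
    list(
      generator = generator, thresholds = thresholds, r_source = r_source,
      sales_units_per_week = sales_units_per_week, out_dir = out_dir,
      seed = as.integer(seed), format = match.arg(format)
    ),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' simulate -> derive -> describe -> regress -> adjust, writing every table
#' to the output directory along with a run log. The run is deterministic
#' given the configuration and seed. Outputs: `dataset.csv` and
#' `truth.csv` (analytic data and generator truth), `response_rates.csv`
#' (fielding summary by survey year), `demographics.csv`, `drinking.csv`
#' (descriptive tables by contact group), `odds_ratios.csv` (24 weighted
#' logistic models), `cor_adjustment.csv` (adjusted consumption estimates
#' with the sales-coverage line appended to the log), and `run_log.txt`
#' (seeds, sample sizes, complete-case counts, calibration checks against
#' the packaged fielding tolerances). With `format = "markdown"`,
#' formatted `.md` twins of the tables are written as well, rounded the
#' way the field prints them (percentages and means to 1 decimal place,
#' odds ratios to 2, p-values to 3 with `<0.001`).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the dataset and all computed tables
#'   (`dataset`, `fielding`, `demographics`, `drinking`, `odds_ratios`,
#'   `cor`, `coverage`, `calibration`, `paths`).
#' @examples
#' \donttest{
#' rc <- run_config(default_config(n_sampled = 3000L), seed = 1)
#' res <- run_pipeline(rc)
#' res$coverage
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("corsurvey pipeline run, seed %d", config$seed),
    sprintf("n_sampled: %d", config$generator$n_sampled)
  )

  svy <- simulate_survey(config$generator, seed = config$seed)
  svy <- derive_indicators(svy, config$thresholds)
  r_sim <- attr(svy, "response_rate")
  r_used <- if (identical(config$r_source, "simulated")) {
    r_sim
  } else {
    config$r_source
  }
  log_lines <- c(
    log_lines,
    sprintf("participants: %d of %d sampled adults (response rate %.4f)",
            sum(svy$responded), nrow(svy), r_sim),
    sprintf("r used for adjustment: %.4f (%s)", r_used,
            if (identical(config$r_source, "simulated")) "simulated"
            else "fixed")
  )

  fielding <- fielding_summary(svy)
  calib <- calibration_checks(svy)
  demo <- demographic_table(svy)
  drink <- drinking_table(svy)
  ors <- regression_table(svy)
  cor_tab <- cor_table(svy, r = r_used)
  weekly_all <- weighted_all_adult_mean(svy, "weekly_units")
  weekly_adj_all <- adjusted_all_adult_mean(svy, r_used)
  coverage <- data.frame(
    estimate = c("survey-weighted", "continuum-of-resistance adjusted"),
    mean_weekly_units = c(weekly_all, weekly_adj_all),
    sales_units_per_week = config$sales_units_per_week,
    coverage_pct = sales_coverage(
      c(weekly_all, weekly_adj_all), config$sales_units_per_week
    )
  )

  paths <- c(
    dataset = file.path(config$out_dir, "dataset.csv"),
    truth = file.path(config$out_dir, "truth.csv"),
    fielding = file.path(config$out_dir, "response_rates.csv"),
    demographics = file.path(config$out_dir, "demographics.csv"),
    drinking = file.path(config$out_dir, "drinking.csv"),
    odds_ratios = file.path(config$out_dir, "odds_ratios.csv"),
    cor = file.path(config$out_dir, "cor_adjustment.csv"),
    coverage = file.path(config$out_dir, "sales_coverage.csv"),
    log = file.path(config$out_dir, "run_log.txt")
  )
  write_dataset(svy, paths[["dataset"]], truth_path = paths[["truth"]])
  for (nm in c("fielding", "demographics", "drinking", "odds_ratios",
               "cor", "coverage")) {
    tab <- switch(nm,
      fielding = fielding, demographics = demo, drinking = drink,
      odds_ratios = ors, cor = cor_tab, coverage = coverage
    )
    write.csv(tab, paths[[nm]], row.names = FALSE, na = "")
    if (config$format == "markdown") {
      md_path <- sub("\\.csv$", ".md", paths[[nm]])
      writeLines(format_markdown_table(round_for_print(tab)), md_path)
    }
  }
  log_lines <- c(
    log_lines,
    "complete-case n by model:",
    sprintf("  %s / %s / %s: %d", ors$stratum, ors$outcome, ors$adjustment,
            ors$n_complete),
    "calibration checks (value / target band / pass):",
    sprintf(
      "  %s: %.4f / [%.4f, %.4f] / %s", calib$metric, calib$value,
      calib$lower, calib$upper, ifelse(calib$pass, "pass", "FAIL")
    ),
    sprintf(
      "sales coverage: %.1f%% weighted -> %.1f%% adjusted (sales %.1f units/wk)",
      coverage$coverage_pct[1], coverage$coverage_pct[2],
      config$sales_units_per_week
    )
  )
  writeLines(log_lines, paths[["log"]])
  invisible(list(
    dataset = svy, fielding = fielding, demographics = demo,
    drinking = drink, odds_ratios = ors, cor = cor_tab,
    coverage = coverage, calibration = calib, paths = paths
  ))
}

# Fielding summary by survey year (response rate, interviews, attempts).
fielding_summary <- function(data) {
  rows <- lapply(
    c(split(data, data$survey_year), list(Overall = data)),
    function(d) {
      part <- d[d$responded, ]
      data.frame(
        response_rate_pct = 100 * mean(d$responded),
        interviews = nrow(part),
        mean_attempts = mean(part$attempts),
        sd_attempts = stats::sd(part$attempts)
      )
    }
  )
  out <- do.call(rbind, rows)
  out <- cbind(survey_year = rownames(out), out)
  rownames(out) <- NULL
  out
}

# The five packaged fielding calibration tolerances, evaluated on a run.
calibration_checks <- function(data) {
  part <- participants(data)
  w7 <- weighted_proportion(part$attempts >= 7, part$int_weight)$estimate
  data.frame(
    metric = c(
      "response_rate", "mean_attempts", "sd_attempts",
      "weighted_share_7plus", "share_within_8"
    ),
    value = c(
      response_rate(data), mean(part$attempts), stats::sd(part$attempts),
      w7, mean(part$attempts <= 8)
    ),
    lower = c(0.57, 4.34, 2.69, 0.178, 0.89),
    upper = c(0.59, 4.54, 2.99, 0.198, 0.91)
  ) -> out
  out$pass <- out$value >= out$lower & out$value <= out$upper
  out
}

weighted_all_adult_mean <- function(data, var) {
  part <- participants(data)
  d <- part[!is.na(part[[var]]), ]
  weighted_mean_sd(d[[var]], d$int_weight)$estimate
}

adjusted_all_adult_mean <- function(data, r) {
  part <- participants(data)
  d <- part[!is.na(part$weekly_units), ]
  hard <- d[d$contact_group == "HIGH", ]
  cor_adjust(
    weighted_mean_sd(d$weekly_units, d$int_weight)$estimate,
    weighted_mean_sd(hard$weekly_units, hard$int_weight)$estimate,
    r
  )
}

# Round a table the way the printed tables do, keeping ids intact.
round_for_print <- function(tab) {
  out <- tab
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    out[[nm]] <- switch(nm,
      p_value = format_pvalue(out[[nm]]),
      or = , ci_low = , ci_high = , table_or = fmt2(out[[nm]]),
      n_low = , n_high = , n_complete = , interviews = ,
      survey_year = format(out[[nm]]),
      fmt1(out[[nm]])
    )
  }
  out
}

format_markdown_table <- function(tab) {
  cells <- vapply(tab, function(x) as.character(x), character(nrow(tab)))
  if (nrow(tab) == 1) cells <- matrix(cells, nrow = 1)
  cells[is.na(cells)] <- ""
  header <- paste("|", paste(names(tab), collapse = " | "), "|")
  rule <- paste(
    "|", paste(rep("---", ncol(tab)), collapse = " | "), "|"
  )
  body <- apply(cells, 1, function(r) {
    paste("|", paste(r, collapse = " | "), "|")
  })
  c(header, rule, body)
}
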