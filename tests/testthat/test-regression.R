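test_that("single-predictor fit equals the 2x2 cross-product ratio", {
  # HIGH: 20 cases / 80 non-cases; LOW: 10 / 90 -> OR 2.25
  att <- rep(c(8L, 2L), each = 100)
  heavy <- c(rep(c(TRUE, FALSE), c(20, 80)), rep(c(TRUE, FALSE), c(10, 90)))
  d <- manual_survey(200, attempts = att,
                     max_day_units = ifelse(heavy, 10, 2),
                     drink_days = rep(2L, 200))
  d <- compute_weights(d)
  res <- fit_weighted_logistic(d, "heavy_episodic", "unadjusted", "men")
  expect_equal(res$or, (20 * 90) / (80 * 10), tolerance = 1e-8)
  expect_equal(res$n_complete, 200L)
})

test_that("no association gives OR 1 and weight scale does not matter", {
  att <- rep(c(8L, 2L), each = 100)
  heavy <- rep(rep(c(TRUE, FALSE), c(30, 70)), 2)
  d <- manual_survey(200, attempts = att,
                     max_day_units = ifelse(heavy, 10, 2))
  d <- compute_weights(d)
  res <- fit_weighted_logistic(d, "heavy_episodic", "unadjusted", "men")
  expect_equal(res$or, 1, tolerance = 1e-8)
  expect_gt(res$p_value, 0.99)
  d10 <- d
  d10$int_weight <- d10$int_weight * 10
  res10 <- fit_weighted_logistic(d10, "heavy_episodic", "unadjusted", "men")
  expect_equal(res10$or, res$or, tolerance = 1e-10)
  expect_equal(res10$ci_low, res$ci_low, tolerance = 1e-10)
  expect_equal(res10$p_value, res$p_value, tolerance = 1e-10)
})

test_that("the full model grid has 24 rows with sensible structure", {
  svy <- default_sim(1)
  tab <- regression_table(svy)
  expect_equal(nrow(tab), 24)
  expect_equal(
    nrow(unique(tab[c("stratum", "outcome", "adjustment")])), 24
  )
  expect_true(all(tab$ci_low <= tab$or & tab$or <= tab$ci_high))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$flag == ""))
  # complete-case n cannot grow as covariates are added
  by_model <- split(tab, list(tab$stratum, tab$outcome))
  for (m in by_model) {
    expect_true(
      m$n_complete[m$adjustment == "fully"][1] <=
        m$n_complete[m$adjustment == "unadjusted"][1]
    )
  }
  # age confounding attenuates the men's daily-guideline association
  men_daily <- tab[tab$stratum == "men" & tab$outcome == "exceed_daily", ]
  expect_gte(
    men_daily$or[men_daily$adjustment == "unadjusted"],
    men_daily$or[men_daily$adjustment == "fully"]
  )
  # the table-derived OR is reported alongside the unadjusted model OR
  expect_true(all(!is.na(tab$table_or[tab$adjustment == "unadjusted"])))
  expect_true(all(is.na(tab$table_or[tab$adjustment != "unadjusted"])))
})

test_that("null coupling is recovered: confidence intervals cover OR 1", {
  covered <- total <- 0
  for (seed in 1:4) {
    cfg <- null_coupling_config(n_sampled = 8000L)
    svy <- derive_indicators(simulate_survey(cfg, seed = seed))
    tab <- regression_table(svy)
    covered <- covered + sum(tab$ci_low <= 1 & 1 <= tab$ci_high)
    total <- total + nrow(tab)
  }
  # nominal coverage is 95%; 85% guards against simulation noise
  expect_gte(covered / total, 0.85)
})

test_that("empty strata and unknown outcomes error cleanly", {
  svy <- default_sim(1)
  expect_error(fit_weighted_logistic(svy, "no_such_column", "fully", "men"),
               "unknown outcome")
  only_men <- svy[svy$sex == "men", ]
  expect_error(
    fit_weighted_logistic(only_men, "heavy_episodic", "fully", "women"),
    "empty stratum"
  )
})
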