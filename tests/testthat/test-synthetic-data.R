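test_that("degenerate marginals and zero loadings behave as specified", {
  cfg <- default_config(n_sampled = 400L)
  cfg$demographic_marginals$region[] <- 0
  cfg$demographic_marginals$region[["London"]] <- 1
  pop <- generate_population(cfg, seed = 3)
  expect_true(all(pop$region == "London"))

  cfg <- default_config(n_sampled = 400L, resistance_noise_sd = 0)
  cfg$resistance_loadings$age_group[] <- 0
  cfg$resistance_loadings$econ_activity[] <- 0
  cfg$resistance_loadings$region[] <- 0
  pop <- generate_population(cfg, seed = 3)
  expect_true(all(pop$resistance == 0))
})

test_that("higher latent resistance goes with heavier drinking", {
  # positive resistance -> hard-stratum coupling: compare true mean weekly
  # units between resistance tertiles on the truth table
  cfg <- default_config(n_sampled = 20000L)
  pop <- generate_population(cfg, seed = 11)
  svy <- simulate_fielding(pop, cfg, seed = 11)
  truth <- attr(svy, "truth")
  ter <- cut(pop$resistance, stats::quantile(pop$resistance, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = c("low", "mid", "top"))
  top <- truth$weekly_units[ter == "top"]
  bot <- truth$weekly_units[ter == "low"]
  tt <- stats::t.test(top, bot, alternative = "greater")
  expect_lt(tt$p.value, 0.001)
})

test_that("fielding honours degenerate willingness and contact settings", {
  cfg <- default_config(
    n_sampled = 300L,
    willingness_intercept = 50, willingness_slope = 0,
    contact_intercept = 50, contact_slope = 0
  )
  svy <- simulate_survey(cfg, seed = 2)
  expect_true(all(svy$responded))
  expect_true(all(svy$attempts == 1L))
  expect_equal(response_rate(svy), 1)

  cfg <- default_config(n_sampled = 300L, willingness_intercept = -50,
                        willingness_slope = 0)
  svy <- simulate_survey(cfg, seed = 2)
  expect_equal(response_rate(svy), 0)
  expect_equal(nrow(participants(svy)), 0L)
})

test_that("identical configuration and seed give identical datasets", {
  cfg <- default_config(n_sampled = 3000L)
  a <- simulate_survey(cfg, seed = 9)
  b <- simulate_survey(cfg, seed = 9)
  expect_identical(a, b)
  c <- simulate_survey(cfg, seed = 10)
  expect_false(identical(a$attempts, c$attempts))
})

test_that("resistance penalties act monotonically on the fielding", {
  # stronger willingness penalty -> (weakly) lower response rate;
  # stronger contact penalty -> more attempts among participants
  base <- default_config(n_sampled = 15000L)
  rr <- att <- numeric(0)
  for (seed in 1:3) {
    lo <- simulate_survey(base, seed = seed)
    hi_w <- simulate_survey(
      default_config(n_sampled = 15000L, willingness_slope = base$willingness_slope + 0.8),
      seed = seed
    )
    hi_c <- simulate_survey(
      default_config(n_sampled = 15000L, contact_slope = base$contact_slope + 0.8),
      seed = seed
    )
    rr <- c(rr, response_rate(hi_w) - response_rate(lo))
    att <- c(att, mean(participants(hi_c)$attempts) -
               mean(participants(lo)$attempts))
  }
  expect_lte(mean(rr), 0)
  expect_gt(mean(att), 0)
})

test_that("participant drinking estimates understate heavy episodic drinking", {
  # with positive coupling the weighted participant estimate sits below the
  # truth-table population prevalence; with no coupling (and response
  # independent of the economic-activity channel) the two coincide
  thr <- drinking_thresholds()
  pop_prev <- function(truth, sex) {
    t_s <- truth[truth$sex == sex, ]
    mean(t_s$max_day_units > thr$heavy_episodic[[sex]])
  }
  part_prev <- function(svy, sex) {
    p <- participants(derive_indicators(svy))
    p <- p[p$sex == sex & !is.na(p$heavy_episodic), ]
    weighted_proportion(p$heavy_episodic, p$int_weight)$estimate
  }
  cfg <- default_config(n_sampled = 100000L)
  svy <- simulate_survey(cfg, seed = 5)
  truth <- attr(svy, "truth")
  expect_lt(part_prev(svy, "men"), pop_prev(truth, "men"))
  expect_lt(part_prev(svy, "women"), pop_prev(truth, "women"))

  cfg0 <- null_coupling_config(n_sampled = 100000L, zero_econ_loading = TRUE)
  svy0 <- simulate_survey(cfg0, seed = 5)
  truth0 <- attr(svy0, "truth")
  for (sex in c("men", "women")) {
    p <- pop_prev(truth0, sex)
    mc_se <- sqrt(p * (1 - p) / sum(svy0$responded & svy0$sex == sex)) * 2
    expect_lt(abs(part_prev(svy0, sex) - p), 3 * mc_se)
  }
})

test_that("analytic export hides what non-participants would have answered", {
  svy <- simulate_survey(default_config(n_sampled = 4000L), seed = 4)
  non <- svy[!svy$responded, ]
  expect_true(all(is.na(non$attempts)))
  expect_true(all(is.na(non$int_weight)))
  expect_true(all(is.na(non$drinks_now)))
  expect_true(all(is.na(non$weekly_units)))
  truth <- attr(svy, "truth")
  expect_equal(nrow(truth), nrow(svy))
  expect_false(anyNA(truth$weekly_units))
  # participants' non-missing analytic values agree with the truth table
  part <- svy[svy$responded, ]
  tr <- truth[truth$person_id %in% part$person_id, ]
  ok <- !is.na(part$weekly_units)
  expect_identical(part$weekly_units[ok], tr$weekly_units[ok])
})

test_that("drinking fields respect their supports and non-drinker zeros", {
  svy <- simulate_survey(default_config(n_sampled = 20000L), seed = 6)
  truth <- attr(svy, "truth")
  expect_true(all(truth$drink_days %in% 0:7))
  expect_true(all(truth$max_day_units >= 0))
  expect_true(all(truth$weekly_units >= 0))
  nd <- truth[!truth$drinks_now, ]
  expect_true(all(nd$drink_days == 0))
  expect_true(all(nd$max_day_units == 0))
  expect_true(all(nd$weekly_units == 0))
})
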