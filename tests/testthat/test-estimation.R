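test_that("weighted proportion and mean/SD match the replication oracle", {
  # integer weights are equivalent to replicating each row w times
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    x <- rnorm(n)
    b <- rbinom(n, 1, 0.4)
    w <- sample(1:5, n, replace = TRUE)
    rep_x <- rep(x, w)
    rep_b <- rep(b, w)
    expect_equal(weighted_proportion(b, w)$estimate, mean(rep_b))
    est <- weighted_mean_sd(x, w)
    expect_equal(est$estimate, mean(rep_x))
    expect_equal(
      est$sd_or_se,
      sqrt(mean((rep_x - mean(rep_x))^2))
    )
  }
})

test_that("weighted proportion handles simple cases and errors", {
  expect_equal(weighted_proportion(c(1, 0, 1, 0), rep(1, 4))$estimate, 0.5)
  expect_equal(weighted_proportion(c(1, 0), c(3, 1))$estimate, 0.75)
  expect_equal(
    weighted_proportion(c(TRUE, NA, FALSE), c(1, 1, NA))$unweighted_n, 1L
  )
  expect_error(weighted_proportion(c(NA, NA), c(1, 1)), "no complete")
  expect_error(weighted_proportion(c(1, 0), c(1, -1)), "positive")
  expect_error(weighted_proportion(c(2, 0), c(1, 1)), "binary")
})

test_that("weighted mean/SD reduces to population formulas and flags n = 1", {
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  est <- weighted_mean_sd(x, rep(1, 8))
  expect_equal(est$estimate, 5)
  expect_equal(est$sd_or_se, 2) # population SD of the classic example
  expect_equal(weighted_mean_sd(rep(3, 5), rep(2, 5))$sd_or_se, 0)
  single <- weighted_mean_sd(4, 1)
  expect_true(is.na(single$sd_or_se))
  expect_match(single$flag, "single")
})

test_that("weighted chi-squared reproduces the hand-computed statistic", {
  g <- rep(c("a", "b"), each = 100)
  x <- rep(c(1, 0, 1, 0), c(10, 90, 20, 80))
  res <- weighted_chisq(g, x, rep(1, 200))
  expect_equal(res$statistic, 3.921, tolerance = 5e-4)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE))
  # identical distributions give statistic 0, p 1
  res0 <- weighted_chisq(
    rep(c("a", "b"), each = 10), rep(c(1, 0), 10), rep(1, 20)
  )
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # scale invariance of the weights
  res2 <- weighted_chisq(g, x, rep(7.3, 200))
  expect_equal(res2$statistic, res$statistic)
  expect_equal(res2$p_value, res$p_value)
  expect_error(weighted_chisq(rep("a", 5), rep(1, 5), rep(1, 5)),
               "two groups")
})

test_that("on a 2x2 table the chi-squared equals the squared z statistic", {
  set.seed(7)
  for (i in 1:5) {
    n1 <- sample(30:80, 1); n2 <- sample(30:80, 1)
    x1 <- rbinom(n1, 1, 0.3); x2 <- rbinom(n2, 1, 0.5)
    g <- rep(c("a", "b"), c(n1, n2))
    res <- weighted_chisq(g, c(x1, x2), rep(1, n1 + n2))
    p1 <- mean(x1); p2 <- mean(x2)
    p <- (sum(x1) + sum(x2)) / (n1 + n2)
    z <- (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
    expect_equal(res$statistic, z^2, tolerance = 1e-6)
  }
})

test_that("weighted t-test reduces to Welch and is weight-scale invariant", {
  set.seed(21)
  x <- c(rnorm(25, 0), rnorm(30, 0.7))
  g <- rep(c("a", "b"), c(25, 30))
  res <- weighted_t_test(x, rep(1, 55), g)
  ref <- stats::t.test(x[g == "a"], x[g == "b"])
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$p_value, ref$p.value)
  res_c <- weighted_t_test(x, rep(0.37, 55), g)
  expect_equal(res_c$t, res$t)
  expect_equal(res_c$p_value, res$p_value)
  # identical groups: t = 0, p = 1
  res0 <- weighted_t_test(rep(c(1, 2), 4), rep(1, 8), rep(c("a", "b"), each = 4))
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)
  expect_error(
    weighted_t_test(rep(1, 6), rep(1, 6), rep(c("a", "b"), 3)),
    "zero variance"
  )
})

test_that("all estimates are invariant to a common weight rescaling", {
  svy <- default_sim(1)
  part <- participants(svy)
  d <- part[part$sex == "women" & !is.na(part$heavy_episodic), ][1:500, ]
  a <- weighted_proportion(d$heavy_episodic, d$int_weight)
  b <- weighted_proportion(d$heavy_episodic, d$int_weight * 13)
  expect_equal(a$estimate, b$estimate)
  m1 <- weighted_mean_sd(d$weekly_units, d$int_weight)
  m2 <- weighted_mean_sd(d$weekly_units, d$int_weight * 13)
  expect_equal(m1$estimate, m2$estimate)
  expect_equal(m1$sd_or_se, m2$sd_or_se)
})

test_that("descriptive tables have the published layout and bases", {
  svy <- default_sim(1)
  demo <- demographic_table(svy)
  expect_equal(
    unique(demo$variable),
    c("sex", "age_group", "econ_activity", "income_q", "imd_q", "region")
  )
  expect_equal(sum(demo$variable == "region"), 9)
  # row-percentages sum to 100 within category
  expect_equal(demo$pct_low + demo$pct_high, rep(100, nrow(demo)))
  # complete-case counts: sex rows cover all participants
  expect_equal(
    sum(demo$n_low[demo$variable == "sex"]) +
      sum(demo$n_high[demo$variable == "sex"]),
    nrow(participants(svy))
  )
  drink <- drinking_table(svy)
  expect_equal(nrow(drink), 14) # 7 measures x 2 sexes
  # per-variable complete-case bases match a direct recount
  part <- participants(svy)
  for (sex in c("men", "women")) {
    row <- drink[drink$sex == sex &
                   drink$measure == "Heavy episodic drinking (>8/6 units)", ]
    d <- part[part$sex == sex & !is.na(part$heavy_episodic), ]
    expect_equal(row$n_low + row$n_high, nrow(d))
  }
  # women's hard-to-contact group drinks more heavily
  w <- drink[drink$sex == "women" &
               drink$measure == "Heavy episodic drinking (>8/6 units)", ]
  expect_gt(w$est_high, w$est_low)
})

test_that("tables degrade gracefully when one contact group is absent", {
  d <- manual_survey(30, attempts = rep(2L, 30),
                     sex = rep(c("men", "women"), 15))
  d <- compute_weights(d)
  drink <- drinking_table(d)
  expect_true(all(is.na(drink$est_high)))
  expect_true(all(is.na(drink$p_value)))
  expect_true(all(drink$n_high == 0))
})
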