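test_that("the adjustment formula is the response-weighted mixture", {
  expect_equal(cor_adjust(0.5, 0.5, 0.7), 0.5)
  expect_equal(cor_adjust(0.31, 0.9, 1), 0.31)
  expect_equal(cor_adjust(12.8, 17.2, 0.58), 14.648)
  expect_error(cor_adjust(0.5, 0.5, 0), "\\(0, 1\\]")
  expect_error(cor_adjust(0.5, 0.5, 1.2), "\\(0, 1\\]")
  expect_error(cor_adjust(-0.1, 0.5, 0.5), "non-negative")
  expect_error(cor_adjust(0.5, 12, 0.5), "different kinds")
})

test_that("the adjustment is bounded, monotone and linear in r", {
  set.seed(31)
  for (i in 1:25) {
    p <- runif(1); h <- runif(1); r <- runif(1, 0.05, 1)
    a <- cor_adjust(p, h, r)
    expect_gte(a, min(p, h))
    expect_lte(a, max(p, h))
    expect_gte(cor_adjust(p + 0.01 * (1 - p), h, r), a)
    expect_gte(cor_adjust(p, h + 0.01 * (1 - h), r), a)
  }
  # linearity in r
  p <- 0.2; h <- 0.5
  mid <- (cor_adjust(p, h, 0.3) + cor_adjust(p, h, 0.7)) / 2
  expect_equal(cor_adjust(p, h, 0.5), mid)
})

test_that("sales coverage is plain arithmetic with guarded inputs", {
  expect_equal(sales_coverage(19.1, 19.1), 100)
  expect_equal(sales_coverage(10.9, 19.1), 57.07, tolerance = 5e-4)
  expect_equal(sales_coverage(12.7, 19.1), 66.49, tolerance = 5e-4)
  expect_error(sales_coverage(0, 19.1), "positive")
  expect_error(sales_coverage(10, -1), "positive")
})

test_that("cor_table collapses to the weighted column when r = 1 or groups are identical", {
  svy <- default_sim(1)
  tab1 <- cor_table(svy, r = 1)
  expect_equal(tab1$adjusted, tab1$weighted)
  expect_equal(tab1$difference, rep(0, nrow(tab1)))

  # identical drinking in LOW and HIGH: duplicate one set of rows (both
  # sexes) into each contact group
  part <- participants(svy)
  base <- part[c(which(part$sex == "men")[1:300],
                 which(part$sex == "women")[1:300]), ]
  hi <- base; hi$attempts <- 9L
  lo <- base; lo$attempts <- 2L
  both <- rbind(hi, lo)
  both$person_id <- seq_len(nrow(both))
  class(both) <- c("cor_survey", "data.frame")
  both <- derive_indicators(both)
  tab <- cor_table(both, r = 0.6)
  expect_equal(tab$adjusted, tab$weighted, tolerance = 1e-12)
  expect_equal(tab$pct_change, rep(0, nrow(tab)), tolerance = 1e-9)
})

test_that("cor_table reports seven measures per sex with exact identities", {
  svy <- default_sim(1)
  tab <- cor_table(svy)
  expect_equal(nrow(tab), 14)
  expect_equal(tab$difference, tab$adjusted - tab$weighted)
  nonzero <- tab$weighted != 0
  expect_equal(
    tab$pct_change[nonzero],
    100 * tab$difference[nonzero] / tab$weighted[nonzero]
  )
  expect_true(all(
    tab$adjusted >= pmin(tab$weighted, tab$hard_group) - 1e-12 &
      tab$adjusted <= pmax(tab$weighted, tab$hard_group) + 1e-12
  ))
  # sex-specific response proportions are accepted
  tab2 <- cor_table(svy, r = c(men = 0.6, women = 0.55))
  expect_equal(unique(tab2$r[tab2$sex == "men"]), 0.6)
  expect_equal(unique(tab2$r[tab2$sex == "women"]), 0.55)
})
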