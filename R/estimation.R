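#' Weighted proportion
#'
#' Survey-weighted proportion of a binary variable: `sum(w * x) / sum(w)`.
#' Pairs with a missing value or weight are excluded. Estimates are
#' invariant to rescaling all weights by a positive constant, and with
#' integer weights they equal the unweighted proportion on the
#' row-replicated dataset.
#'
#' @param x Binary (logical or 0/1) values.
#' @param w Positive weights, same length as `x`.
#' @return An object of class `weighted_estimate` with fields `estimate`,
#'   `sd_or_se` (SE of the weighted proportion under the Kish effective
#'   sample size), `weighted_n` and `unweighted_n`.
#' @examples
#' weighted_proportion(c(1, 0), c(3, 1))$estimate # 0.75
#' @export
weighted_proportion <- function(x, w) {
  d <- check_weighted_pairs(x, w)
  x <- as.numeric(d$x)
  if (!all(x %in% c(0, 1))) stop("x must be binary (0/1 or logical)")
  p <- sum(d$w * x) / sum(d$w)
  n_eff <- kish_n(d$w)
  new_weighted_estimate(
    estimate = p,
    sd_or_se = sqrt(p * (1 - p) / n_eff),
    weighted_n = sum(d$w),
    unweighted_n = length(x),
    type = "proportion"
  )
}

#' Weighted mean and standard deviation
#'
#' Survey-weighted mean `sum(w * x) / sum(w)` and the weighted population
#' standard deviation `sqrt(sum(w * (x - mean)^2) / sum(w))`. With unit
#' weights the SD is the population (divide-by-n) standard deviation. A
#' single observation leaves the SD undefined and flags the estimate.
#'
#' @inheritParams weighted_proportion
#' @param x Numeric values.
#' @return A `weighted_estimate` with the weighted SD in `sd_or_se`.
#' @examples
#' weighted_mean_sd(c(1, 2, 3), c(1, 1, 1))
#' @export
weighted_mean_sd <- function(x, w) {
  d <- check_weighted_pairs(x, w)
  m <- sum(d$w * d$x) / sum(d$w)
  if (length(d$x) < 2) {
    out <- new_weighted_estimate(
      estimate = m, sd_or_se = NA_real_, weighted_n = sum(d$w),
      unweighted_n = length(d$x), type = "mean"
    )
    out$flag <- "single observation: SD undefined"
    return(out)
  }
  new_weighted_estimate(
    estimate = m,
    sd_or_se = sqrt(sum(d$w * (d$x - m)^2) / sum(d$w)),
    weighted_n = sum(d$w),
    unweighted_n = length(d$x),
    type = "mean"
  )
}

#' Pearson chi-squared test on a weighted contingency table
#'
#' Rescales the weights to sum to the unweighted sample size, forms the
#' weighted group x category table and computes the Pearson chi-squared
#' statistic with `(r - 1)(c - 1)` degrees of freedom. The rescaling makes
#' the statistic invariant to the overall scale of the weights and makes it
#' coincide with the classical test when all weights are equal.
#'
#' @param group Group labels (e.g. contact-attempt group).
#' @param category Category labels.
#' @param w Positive weights.
#' @return A list with `statistic`, `df`, `p_value` and the weighted
#'   `table`.
#' @examples
#' g <- rep(c("a", "b"), c(100, 100))
#' x <- rep(c(1, 0, 1, 0), c(10, 90, 20, 80))
#' weighted_chisq(g, x, rep(1, 200))$statistic # 3.921 to 2 dp
#' @export
weighted_chisq <- function(group, category, w) {
  keep <- !is.na(group) & !is.na(category) & !is.na(w)
  group <- group[keep]; category <- category[keep]; w <- w[keep]
  if (!length(w)) stop("no complete observations")
  if (any(w <= 0)) stop("weights must be positive")
  group <- droplevels(factor(group))
  category <- droplevels(factor(category))
  if (nlevels(group) < 2 || nlevels(category) < 2) {
    stop("need at least two groups and two categories")
  }
  w <- w * length(w) / sum(w)
  tab <- tapply(w, list(group, category), sum, default = 0)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate weighted table (empty row or column)")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(
    statistic = stat, df = df,
    p_value = pchisq(stat, df, lower.tail = FALSE), table = tab
  )
}

#' Weighted two-sample t-test
#'
#' Unequal-variance (Welch) two-sample t-test on weighted means. The
#' variance of each group's weighted mean is its weighted variance divided
#' by the Kish effective sample size `(sum(w))^2 / sum(w^2)`, and the
#' degrees of freedom follow Welch-Satterthwaite. With unit weights this is
#' exactly the classical Welch t-test, and the result is invariant to
#' rescaling all weights by a positive constant.
#'
#' @param x Numeric values.
#' @param w Positive weights.
#' @param group A factor (or coercible) with exactly two levels.
#' @return A list with `t`, `df`, `p_value`, and per-group means.
#' @export
weighted_t_test <- function(x, w, group) {
  keep <- !is.na(x) & !is.na(w) & !is.na(group)
  x <- x[keep]; w <- w[keep]
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(w <= 0)) stop("weights must be positive")
  stats_of <- function(i) {
    if (sum(i) < 2) stop("need at least two observations per group")
    m <- sum(w[i] * x[i]) / sum(w[i])
    v <- sum(w[i] * (x[i] - m)^2) / sum(w[i])
    n_eff <- kish_n(w[i])
    # unbiased-style scaling of the weighted variance by effective n
    v <- v * n_eff / (n_eff - 1)
    list(mean = m, var_of_mean = v / n_eff, v = v, n_eff = n_eff)
  }
  g1 <- stats_of(group == levels(group)[1])
  g2 <- stats_of(group == levels(group)[2])
  se2 <- g1$var_of_mean + g2$var_of_mean
  if (se2 == 0) stop("zero variance in both groups")
  t_stat <- (g1$mean - g2$mean) / sqrt(se2)
  df <- se2^2 / (
    g1$var_of_mean^2 / (g1$n_eff - 1) + g2$var_of_mean^2 / (g2$n_eff - 1)
  )
  list(
    t = t_stat, df = df,
    p_value = 2 * pt(-abs(t_stat), df),
    means = c(g1$mean, g2$mean)
  )
}

kish_n <- function(w) sum(w)^2 / sum(w^2)

check_weighted_pairs <- function(x, w) {
  if (length(x) != length(w)) stop("x and w must have equal length")
  keep <- !is.na(x) & !is.na(w)
  x <- x[keep]; w <- w[keep]
  if (!length(x)) stop("no complete observations after missing exclusion")
  if (any(w <= 0)) stop("weights must be positive")
  list(x = x, w = w)
}

new_weighted_estimate <- function(estimate, sd_or_se, weighted_n,
                                  unweighted_n, type) {
  structure(
    list(
      estimate = estimate, sd_or_se = sd_or_se, weighted_n = weighted_n,
      unweighted_n = unweighted_n, type = type
    ),
    class = "weighted_estimate"
  )
}

#' @export
print.weighted_estimate <- function(x, ...) {
  cat(sprintf(
    "weighted %s: %.4f (%s %.4f), weighted n %.1f, unweighted n %d\n",
    x$type, x$estimate, if (x$type == "mean") "SD" else "SE",
    x$sd_or_se, x$weighted_n, x$unweighted_n
  ))
  invisible(x)
}
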