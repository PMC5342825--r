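# Hypothesis-test wrappers with the display conventions used throughout:
# significance tiers *, **, *** at p < 0.05 / 0.01 / 0.001, "ns" otherwise.

#' Significance tier of a p-value
#'
#' @param p p-value in \code{[0, 1]}.
#' @return \code{"***"} (p < 0.001), \code{"**"} (p < 0.01), \code{"*"}
#'   (p < 0.05) or \code{"ns"}.
#' @export
significance_tier <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Bundle a test statistic, p-value and significance tier
#'
#' @param test test name.
#' @param statistic numeric test statistic.
#' @param p_value p-value; values marginally outside \code{[0, 1]} from
#'   floating-point round-off are clipped.
#' @param n sample size (total observations or trials).
#' @return object of class \code{test_result}.
#' @export
test_result <- function(test, statistic, p_value, n) {
  p_value <- min(max(p_value, 0), 1)
  structure(list(test = test, statistic = unname(statistic),
                 p_value = p_value, n = n,
                 tier = significance_tier(p_value)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s), n = %s\n",
              x$test, x$statistic, x$p_value, x$tier, x$n))
  invisible(x)
}

#' One-proportion z-test
#'
#' Two-sided normal-approximation test of an observed proportion against
#' \code{p0}, without continuity correction:
#' \code{z = (k/n - p0) / sqrt(p0 (1 - p0) / n)}. Used to compare observed
#' trans-heterozygote survival against its Mendelian expectation (1/3 for
#' the balancer complementation cross).
#'
#' @param k number of successes.
#' @param n number of trials (> 0).
#' @param p0 null proportion in (0, 1).
#' @return a [test_result()] with the z statistic.
#' @seealso [one_proportion_exact()] for the exact-binomial cross-check.
#' @examples
#' one_proportion_ztest(100, 300, 1 / 3) # z = 0, p = 1
#' @export
one_proportion_ztest <- function(k, n, p0) {
  if (!(n > 0)) stop("n must be > 0")
  if (!(p0 > 0 && p0 < 1)) stop("p0 must be in (0, 1)")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  p <- 2 * pnorm(-abs(z))
  test_result("one-proportion z-test", z, p, n)
}

#' Exact binomial test of one proportion
#'
#' Exact counterpart of [one_proportion_ztest()], via [stats::binom.test()].
#'
#' @inheritParams one_proportion_ztest
#' @return a [test_result()] with the observed proportion as statistic.
#' @export
one_proportion_exact <- function(k, n, p0) {
  if (!(n > 0)) stop("n must be > 0")
  bt <- binom.test(k, n, p = p0)
  test_result("exact binomial test", unname(bt$estimate), bt$p.value, n)
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Two-tailed p by the probability-mass rule: the sum of hypergeometric
#' probabilities (margins fixed) of every table at most as probable as the
#' observed one, the convention of [stats::fisher.test()], which performs
#' the computation.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   row and column margins.
#' @return a [test_result()] with the conditional odds-ratio estimate as
#'   statistic.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)) # p = 1
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all row and column margins must be positive")
  }
  ft <- fisher.test(table, alternative = "two.sided")
  test_result("Fisher's exact test (two-tailed)",
              unname(ft$estimate), ft$p.value, sum(table))
}
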