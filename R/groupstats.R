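# Group comparison of peak responses: one-way ANOVA across the
# experimental and the two control genotypes, followed by post-hoc
# Student's two-sample t-tests of the experimental group against each
# control, Bonferroni-corrected. Asterisks are displayed only when the
# experimental group differs significantly from BOTH controls, and the
# displayed tier is that of the less significant comparison.

#' One-way ANOVA across groups
#'
#' Classic fixed-effects one-way ANOVA (equal-variance F test), via
#' [stats::oneway.test()].
#'
#' @param groups named list of numeric vectors, one per group; at least 2
#'   groups with at least 2 observations each.
#' @return a [test_result()] with the F statistic.
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(1, 2, 3))) # F = 0, p = 1
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 observations")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), sizes))
  ot <- oneway.test(value ~ grp, var.equal = TRUE)
  f <- unname(ot$statistic)
  p <- ot$p.value
  if (is.nan(f)) { # all observations identical: no variance anywhere
    f <- 0; p <- 1
  }
  test_result("one-way ANOVA", f, p, length(value))
}

#' Post-hoc t-tests against two controls with Bonferroni correction
#'
#' Unpaired two-sample Student's t-tests of the experimental group against
#' each control; each raw p is Bonferroni-adjusted as \code{min(1, m * p)}.
#' The display rule: asterisks are shown only if the experimental group is
#' significantly different (adjusted p < 0.05) from both controls, and the
#' displayed tier is that of the larger (less significant) adjusted p.
#'
#' @param experimental,control_a,control_b numeric vectors of per-ROI
#'   (normalized) peak values; each of length >= 2.
#' @param m number of comparisons for the Bonferroni correction
#'   (default 2).
#' @param var_equal pooled-variance Student's t-test when TRUE (default);
#'   Welch when FALSE.
#' @return list of class \code{posthoc_result}: \code{vs_control_a},
#'   \code{vs_control_b} ([test_result()]s carrying adjusted p-values),
#'   \code{raw_p}, \code{display} (logical: show asterisks) and
#'   \code{display_tier} (\code{"ns"} when not displayed).
#' @examples
#' ph <- posthoc_bonferroni(rnorm(10, 3), rnorm(10), rnorm(10))
#' @export
posthoc_bonferroni <- function(experimental, control_a, control_b, m = 2,
                               var_equal = TRUE) {
  if (m < 1) stop("m must be >= 1")
  if (length(experimental) < 2 || length(control_a) < 2 ||
      length(control_b) < 2) {
    stop("every group needs at least 2 observations")
  }
  one <- function(ctrl, label) {
    tt <- t.test(experimental, ctrl, var.equal = var_equal)
    raw <- tt$p.value
    adj <- min(1, m * raw)
    list(result = test_result(paste0("t-test vs ", label, " (Bonferroni)"),
                              unname(tt$statistic), adj,
                              length(experimental) + length(ctrl)),
         raw = raw)
  }
  a <- one(control_a, "control_a")
  b <- one(control_b, "control_b")
  both_sig <- a$result$p_value < 0.05 && b$result$p_value < 0.05
  worst_p <- max(a$result$p_value, b$result$p_value)
  structure(
    list(vs_control_a = a$result, vs_control_b = b$result,
         raw_p = c(control_a = a$raw, control_b = b$raw),
         display = both_sig,
         display_tier = if (both_sig) significance_tier(worst_p) else "ns"),
    class = "posthoc_result"
  )
}
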