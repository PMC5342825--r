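# Delta-delta-Ct relative transcript quantification. Technical replicates
# are averaged per biological replicate; the per-replicate delta Ct is
# Ct(target) - Ct(reference); the headline percentage assumes ideal PCR
# doubling:
#   % transcript = 100 * 2^(mean dCt_ND - mean dCt_D)
# and significance is an unpaired two-sample t-test on the per-replicate
# delta Ct values. Measured primer efficiencies are metadata, not used in
# the correction.

#' Relative transcript level by the delta-delta-Ct method
#'
#' @param ct a Ct table (data frame) with columns \code{genotype}
#'   (\code{"ND"} non-disrupting / \code{"D"} disrupting), \code{gene}
#'   (\code{"target"} / \code{"reference"}), \code{bio_rep},
#'   \code{tech_rep}, \code{ct}; e.g. from [generate_ct_table()] or
#'   [read_ct_csv()].
#' @param var_equal pooled-variance Student's t-test when TRUE (default);
#'   Welch when FALSE.
#' @return list of class \code{ddct_result}:
#'   \describe{
#'     \item{percent}{transcript level of D relative to ND, percent.}
#'     \item{per_replicate}{data frame with per-biological-replicate
#'       \code{delta_ct} and \code{normalized_pct}, the replicate's
#'       relative level normalized so the ND group mean is 100.}
#'     \item{test}{[test_result()] of the t-test on delta Ct values.}
#'   }
#' @examples
#' ct <- generate_ct_table(0.5, replicate_sd = 0, n_bio = 3)
#' delta_delta_ct(ct)$percent # 50
#' @export
delta_delta_ct <- function(ct, var_equal = TRUE) {
  req <- c("genotype", "gene", "bio_rep", "tech_rep", "ct")
  if (!all(req %in% names(ct))) {
    stop("Ct table is missing column(s): ",
         paste(setdiff(req, names(ct)), collapse = ", "))
  }
  if (!all(c("ND", "D") %in% ct$genotype)) {
    stop("Ct table must contain both genotypes 'ND' and 'D'")
  }
  if (!all(c("target", "reference") %in% ct$gene)) {
    stop("Ct table must contain both 'target' and 'reference' genes")
  }
  # mean of technical replicates per genotype x gene x biological replicate
  m <- aggregate(ct ~ genotype + gene + bio_rep, data = ct, FUN = mean)
  wide <- merge(m[m$gene == "target", c("genotype", "bio_rep", "ct")],
                m[m$gene == "reference", c("genotype", "bio_rep", "ct")],
                by = c("genotype", "bio_rep"),
                suffixes = c("_target", "_reference"))
  if (nrow(wide) == 0 || !all(c("ND", "D") %in% wide$genotype)) {
    stop("every biological replicate needs both target and reference Cts")
  }
  wide$delta_ct <- wide$ct_target - wide$ct_reference
  dct_nd <- wide$delta_ct[wide$genotype == "ND"]
  dct_d <- wide$delta_ct[wide$genotype == "D"]
  percent <- 100 * 2^(mean(dct_nd) - mean(dct_d))

  # per-replicate relative levels, ND mean anchored at 100
  level <- 2^(-wide$delta_ct)
  wide$normalized_pct <- 100 * level / mean(level[wide$genotype == "ND"])

  test <- if (length(dct_nd) >= 2 && length(dct_d) >= 2) {
    if (sd(dct_nd) == 0 && sd(dct_d) == 0) {
      # degenerate noiseless samples: identical means are maximally
      # compatible, different means maximally incompatible
      if (isTRUE(all.equal(mean(dct_nd), mean(dct_d)))) {
        test_result("two-sample t-test on delta Ct", 0, 1, nrow(wide))
      } else {
        test_result("two-sample t-test on delta Ct", Inf, 0, nrow(wide))
      }
    } else {
      tt <- t.test(dct_nd, dct_d, var.equal = var_equal)
      test_result("two-sample t-test on delta Ct",
                  unname(tt$statistic), tt$p.value, nrow(wide))
    }
  } else {
    test_result("two-sample t-test on delta Ct", NA_real_, 1, nrow(wide))
  }

  structure(
    list(percent = percent,
         per_replicate = wide[, c("genotype", "bio_rep", "delta_ct",
                                  "normalized_pct")],
         test = test),
    class = "ddct_result"
  )
}
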