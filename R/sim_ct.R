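# Synthetic qPCR cycle-threshold tables. A disrupting (D) sample carrying
# a fraction `true_fraction` of the non-disrupting (ND) transcript level
# has its target-gene Ct raised by -log2(true_fraction) cycles (ideal
# doubling); the reference gene is shared between genotypes.

#' Generate a synthetic Ct table with known relative transcript level
#'
#' @param true_fraction transcript level of the disrupting genotype
#'   relative to the non-disrupting genotype, in \code{(0, 1]}... values
#'   above 1 (over-expression) are also accepted.
#' @param replicate_sd SD in cycles of the Gaussian measurement noise added
#'   independently to every technical replicate.
#' @param n_bio biological replicates per genotype.
#' @param n_tech technical replicates per biological replicate and gene.
#' @param seed integer seed.
#' @param target_ct_nd mean target-gene Ct of the ND genotype.
#' @param reference_ct mean reference-gene Ct (shared by both genotypes).
#' @return data frame of class \code{ct_table} with columns
#'   \code{genotype} (\code{"ND"}/\code{"D"}), \code{gene}
#'   (\code{"target"}/\code{"reference"}), \code{bio_rep},
#'   \code{tech_rep}, \code{ct}; the true fraction is stored in
#'   \code{attr(, "true_fraction")}.
#' @examples
#' ct <- generate_ct_table(0.5, replicate_sd = 0, n_bio = 3, n_tech = 4)
#' delta_delta_ct(ct)$percent # 50
#' @export
generate_ct_table <- function(true_fraction, replicate_sd = 0.1,
                              n_bio = 4L, n_tech = 4L, seed = 1L,
                              target_ct_nd = 20, reference_ct = 15) {
  if (!(true_fraction > 0)) stop("true_fraction must be > 0")
  if (replicate_sd < 0) stop("replicate_sd must be >= 0")
  if (n_bio < 1 || n_tech < 1) stop("need >= 1 replicate of each kind")
  set.seed(substream_seed(seed, "ct_table"))
  target_ct_d <- target_ct_nd - log2(true_fraction)
  rows <- expand.grid(tech_rep = seq_len(n_tech),
                      bio_rep = seq_len(n_bio),
                      gene = c("target", "reference"),
                      genotype = c("ND", "D"),
                      stringsAsFactors = FALSE)
  mu <- ifelse(rows$gene == "reference", reference_ct,
               ifelse(rows$genotype == "ND", target_ct_nd, target_ct_d))
  rows$ct <- mu + if (replicate_sd > 0) {
    rnorm(nrow(rows), 0, replicate_sd)
  } else 0
  rows <- rows[, c("genotype", "gene", "bio_rep", "tech_rep", "ct")]
  if (any(rows$ct <= 0)) stop("generated Ct values must be positive")
  structure(rows, class = c("ct_table", "data.frame"),
            true_fraction = true_fraction)
}
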