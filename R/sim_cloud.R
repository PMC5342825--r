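# Synthetic 3D cell-body point clouds with a planted double-labelled
# fraction, emulating GFP-positive cell bodies of which a known subset also
# carries the inversion reporter.

#' Generate a pair of 3D spot clouds with a planted colocalized fraction
#'
#' Channel-A spots are uniform in a cube of the requested volume. Exactly
#' \code{round(coloc_fraction * n_a)} of them receive a channel-B partner
#' displaced by at most \code{jitter_um} (uniform direction, uniform radius
#' on \code{[0, jitter_um]}); \code{decoys} additional B spots are placed
#' uniformly in the same cube.
#'
#' @param n_a number of channel-A spots (> 0).
#' @param coloc_fraction fraction of A spots with a planted B partner, in
#'   \code{[0, 1]}.
#' @param jitter_um maximum planted-pair displacement, micrometres (>= 0).
#' @param decoys number of unpaired B spots.
#' @param volume_um3 cube volume in cubic micrometres.
#' @param seed integer seed.
#' @return list with \code{a}, \code{b} ([spot_set()]s) and \code{truth},
#'   a list holding \code{pairs} (data frame \code{a_index},
#'   \code{b_index} into the returned sets) and \code{planted_fraction}.
#' @examples
#' cl <- generate_cell_cloud(20, 0.9, jitter_um = 1, decoys = 5, seed = 1)
#' nrow(cl$truth$pairs)
#' @export
generate_cell_cloud <- function(n_a, coloc_fraction, jitter_um = 1,
                                decoys = 0L, volume_um3 = 50^3, seed = 1L) {
  if (!(n_a >= 1)) stop("n_a must be >= 1")
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    stop("coloc_fraction must be in [0, 1]")
  }
  if (jitter_um < 0) stop("jitter_um must be >= 0")
  if (decoys < 0) stop("decoys must be >= 0")
  set.seed(substream_seed(seed, "cell_cloud"))
  side <- volume_um3^(1 / 3)
  A <- matrix(runif(3 * n_a, 0, side), ncol = 3,
              dimnames = list(NULL, c("x_um", "y_um", "z_um")))
  n_match <- round(coloc_fraction * n_a)
  matched_a <- if (n_match > 0) sort(sample.int(n_a, n_match)) else integer(0)
  planted <- NULL
  if (n_match > 0) {
    u <- matrix(rnorm(3 * n_match), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- runif(n_match, 0, jitter_um)
    planted <- A[matched_a, , drop = FALSE] + u * r
  }
  decoy_pts <- if (decoys > 0) {
    matrix(runif(3 * decoys, 0, side), ncol = 3)
  } else NULL
  B <- rbind(planted, decoy_pts)
  n_b <- if (is.null(B)) 0L else nrow(B)
  perm <- if (n_b > 0) sample.int(n_b) else integer(0)
  if (n_b > 0) {
    B <- B[perm, , drop = FALSE]
    colnames(B) <- c("x_um", "y_um", "z_um")
  } else {
    B <- matrix(numeric(0), ncol = 3,
                dimnames = list(NULL, c("x_um", "y_um", "z_um")))
  }
  b_index <- if (n_match > 0) match(seq_len(n_match), perm) else integer(0)
  list(
    a = spot_set(A, channel = "gfp"),
    b = spot_set(B, channel = "tdtomato"),
    truth = list(pairs = data.frame(a_index = matched_a, b_index = b_index),
                 planted_fraction = coloc_fraction)
  )
}
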