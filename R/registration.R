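# Rigid x/y registration by integer translation. Each frame is compared
# against a reference (the mean of the first frames) over all candidate
# integer shifts within a search radius, and shifted to the displacement
# maximizing the Pearson correlation on the overlapping region. This is a
# deliberately simple translation-only registration; it handles the slow
# drift typical of head-fixed preparations, not rotation or warping.

shift_frame <- function(frame, dy, dx, fill) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[which(ok_r), which(ok_c)] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

overlap_correlation <- function(ref, frame, dy, dx) {
  h <- nrow(ref); w <- ncol(ref)
  r1 <- max(1, 1 + dy); r2 <- min(h, h + dy)
  c1 <- max(1, 1 + dx); c2 <- min(w, w + dx)
  if (r2 - r1 < 2 || c2 - c1 < 2) return(-Inf)
  a <- ref[r1:r2, c1:c2]
  b <- frame[(r1:r2) - dy, (c1:c2) - dx]
  if (sd(a) == 0 || sd(b) == 0) return(-Inf)
  stats::cor(as.vector(a), as.vector(b))
}

#' Register a frame stack by integer x/y translation
#'
#' The reference image is the mean of the first \code{ref_frames} frames.
#' Each frame is shifted by the integer displacement (within
#' \code{max_shift} pixels) that maximizes its correlation with the
#' reference; ties go to the smaller displacement. Frames whose best
#' displacement sits on the search boundary are flagged with a warning:
#' featureless (pure-noise) frames cannot be registered reliably and their
#' shifts are capped rather than trusted.
#'
#' @param stack numeric array, height x width x frames (>= 2 frames).
#' @param max_shift search radius in pixels.
#' @param ref_frames number of leading frames averaged into the reference.
#' @return list with \code{stack} (aligned array; vacated pixels filled
#'   with the frame median) and \code{shifts} (frames x 2 integer matrix,
#'   columns \code{dy}, \code{dx}).
#' @export
register_frames <- function(stack, max_shift = 5L, ref_frames = 10L) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 2) stop("stack must have at least 2 frames")
  ref <- apply(stack[, , seq_len(min(ref_frames, d[3])), drop = FALSE],
               c(1, 2), mean)
  cand <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  # order by displacement magnitude so ties resolve to the smaller shift
  cand <- cand[order(cand$dy^2 + cand$dx^2), ]
  shifts <- matrix(0L, d[3], 2, dimnames = list(NULL, c("dy", "dx")))
  aligned <- stack
  at_bound <- FALSE
  for (fr in seq_len(d[3])) {
    frame <- stack[, , fr]
    best <- c(0L, 0L); best_cor <- -Inf
    for (i in seq_len(nrow(cand))) {
      cc <- overlap_correlation(ref, frame, cand$dy[i], cand$dx[i])
      if (cc > best_cor) {
        best_cor <- cc
        best <- c(cand$dy[i], cand$dx[i])
      }
    }
    if (any(abs(best) == max_shift)) at_bound <- TRUE
    shifts[fr, ] <- as.integer(best)
    if (any(best != 0)) {
      aligned[, , fr] <- shift_frame(frame, best[1], best[2],
                                     fill = median(frame))
    }
  }
  if (at_bound) {
    warning("some frames hit the max_shift search boundary; ",
            "their displacements are capped and may be unreliable")
  }
  list(stack = aligned, shifts = shifts)
}
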