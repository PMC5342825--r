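# End-to-end movie fixture: ROI traces rendered as uniform disc blobs on a
# constant background, so that the mean over the blob's own mask minus the
# background mean recovers the generating trace exactly up to 16-bit
# quantization. Discs (not Gaussians) are used on purpose: with a profile
# that is 1 on every masked pixel the ROI mean equals the trace value
# without a profile-dependent scale factor.

#' Render synthetic ROI traces as a movie with masks
#'
#' @param cfg a [sim_config()]; its traces are generated internally with
#'   [generate_roi_traces()] (one blob per ROI, up to \code{max_blobs}).
#' @param frame_dim \code{c(height, width)} in pixels.
#' @param blob_radius_px disc radius in pixels.
#' @param background_level background intensity, same units as F.
#' @param max_blobs cap on the number of rendered ROIs (the fixture is for
#'   extraction tests, not bulk simulation).
#' @return list with \code{stack} (height x width x frames array, raw
#'   intensity units), \code{masks} (named list of logical matrices, one
#'   per rendered ROI), \code{background_mask} (logical matrix),
#'   \code{traces} (the generating \code{roi_trace}s), \code{log} and
#'   \code{truth} as in [generate_roi_traces()].
#' @export
generate_movie <- function(cfg, frame_dim = c(48L, 48L), blob_radius_px = 4,
                           background_level = 10, max_blobs = 4L) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- generate_roi_traces(cfg)
  traces <- sim$traces[seq_len(min(length(sim$traces), max_blobs))]
  h <- frame_dim[1]; w <- frame_dim[2]
  n_blobs <- length(traces)
  # blob centres on a fixed grid, margin of one diameter from the edges
  margin <- 2 * blob_radius_px + 1
  if (2 * margin >= min(h, w)) stop("blobs do not fit inside the frame")
  cx <- round(seq(margin, w - margin, length.out = max(n_blobs, 2)))[seq_len(n_blobs)]
  cy <- round(seq(margin, h - margin, length.out = max(n_blobs, 2)))[seq_len(n_blobs)]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  masks <- vector("list", n_blobs)
  for (b in seq_len(n_blobs)) {
    masks[[b]] <- (rr - cy[b])^2 + (cc - cx[b])^2 <= blob_radius_px^2
  }
  names(masks) <- names(traces)
  if (n_blobs > 1) {
    for (b in 2:n_blobs) {
      if (any(masks[[b]] & Reduce(`|`, masks[seq_len(b - 1)]))) {
        stop("blobs overlap; reduce blob_radius_px or max_blobs")
      }
    }
  }
  any_blob <- Reduce(`|`, masks)
  # background mask: a clear strip along the top edge
  background_mask <- matrix(FALSE, h, w)
  background_mask[seq_len(max(1, blob_radius_px)), ] <- TRUE
  background_mask <- background_mask & !any_blob

  n_frames <- length(traces[[1]]$times_s)
  stack <- array(background_level, dim = c(h, w, n_frames))
  for (b in seq_len(n_blobs)) {
    idx <- which(masks[[b]])
    Fb <- traces[[b]]$F
    for (fr in seq_len(n_frames)) {
      frame <- stack[, , fr]
      frame[idx] <- background_level + Fb[fr]
      stack[, , fr] <- frame
    }
  }
  stack <- round(pmax(stack, 0)) # 16-bit-style integer quantization
  list(stack = stack, masks = masks, background_mask = background_mask,
       traces = traces, log = sim$log,
       truth = sim$truth[names(traces)])
}
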