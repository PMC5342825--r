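# Core trace processing: ROI extraction, two-exponential bleach
# correction, and deltaF/F. The bleaching envelope is fit by nonlinear
# least squares (Levenberg-Marquardt) either over all frames (search
# stimulus: deltaF/F = 0 at the mean response) or over frames in the last
# 25% of each gray period (flash stimulus: deltaF/F = 0 at the resting
# baseline the cell returns to between flashes).

#' Construct an ROI fluorescence trace
#'
#' @param roi_id character scalar.
#' @param times_s strictly increasing frame times in seconds.
#' @param F background-subtracted fluorescence, same length as
#'   \code{times_s}, finite.
#' @param meta list with \code{fly_id}, \code{compartment},
#'   \code{genotype} (free-form; used for grouping downstream).
#' @return object of class \code{roi_trace}.
#' @export
roi_trace <- function(roi_id, times_s, F, meta = list()) {
  if (length(times_s) != length(F)) stop("times_s and F must match in length")
  if (any(!is.finite(times_s)) || any(!is.finite(F))) {
    stop("times and fluorescence must be finite")
  }
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  structure(list(roi_id = as.character(roi_id), times_s = times_s,
                 F = as.numeric(F), meta = meta),
            class = "roi_trace")
}

#' Construct a deltaF/F trace directly
#'
#' Normally produced by [compute_dff()]; the constructor is exposed for
#' pre-computed deltaF/F tables.
#'
#' @inheritParams roi_trace
#' @param dff dimensionless deltaF/F values.
#' @return object of class \code{dff_trace}.
#' @export
dff_trace <- function(roi_id, times_s, dff, meta = list()) {
  if (length(times_s) != length(dff)) {
    stop("times_s and dff must match in length")
  }
  if (any(!is.finite(times_s)) || any(!is.finite(dff))) {
    stop("times and dff must be finite")
  }
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  structure(list(roi_id = as.character(roi_id), times_s = times_s,
                 dff = as.numeric(dff), meta = meta),
            class = "dff_trace")
}

#' Extract a background-subtracted ROI trace from a frame stack
#'
#' For each frame, pixel values inside the ROI mask are averaged and the
#' mean over the background mask (a region without cells) is subtracted.
#'
#' @param stack numeric array, height x width x frames.
#' @param roi_mask,background_mask logical matrices matching the frame
#'   size; both nonempty and disjoint.
#' @param frame_rate frames per second used to assign frame times.
#' @param roi_id,meta passed to [roi_trace()].
#' @return a [roi_trace()].
#' @export
extract_roi_trace <- function(stack, roi_mask, background_mask,
                              frame_rate = 38.9, roi_id = "roi",
                              meta = list()) {
  d <- dim(stack)
  if (length(d) != 3) stop("stack must be a height x width x frames array")
  if (!all(dim(roi_mask) == d[1:2]) || !all(dim(background_mask) == d[1:2])) {
    stop("masks must match the frame dimensions")
  }
  if (!any(roi_mask)) stop("roi_mask is empty")
  if (!any(background_mask)) stop("background_mask is empty")
  if (any(roi_mask & background_mask)) {
    stop("roi_mask and background_mask overlap")
  }
  flat <- matrix(stack, nrow = d[1] * d[2], ncol = d[3])
  F <- colMeans(flat[as.vector(roi_mask), , drop = FALSE]) -
    colMeans(flat[as.vector(background_mask), , drop = FALSE])
  t <- (seq_len(d[3]) - 1L) / frame_rate
  roi_trace(roi_id, t, F, meta = meta)
}

# frames whose time falls in the final quarter of any gray period
last_quarter_gray_mask <- function(times_s, log, fraction = 0.25) {
  gp <- gray_periods(log)
  mask <- rep(FALSE, length(times_s))
  for (i in seq_len(nrow(gp))) {
    lo <- gp$end[i] - fraction * (gp$end[i] - gp$start[i])
    mask <- mask | (times_s >= lo & times_s < gp$end[i])
  }
  mask
}

# deterministic multistart grid for the two-exponential fit
bleach_start_grid <- function(T_span, f_first, f_last, with_offset) {
  off0 <- if (with_offset) 0.8 * min(f_last, f_first) else 0
  amp <- f_first - off0
  starts <- list()
  for (s1 in c(0.1, 0.02, 0.3)) {
    for (s2 in c(1, 0.5, 3)) {
      starts[[length(starts) + 1]] <-
        list(a1 = amp / 2, tau1 = s1 * T_span, a2 = amp / 2,
             tau2 = s2 * T_span, off = off0)
    }
  }
  starts
}

#' Fit a two-exponential bleaching baseline to an ROI trace
#'
#' Least-squares fit of
#' \code{F(t) ~ a1 exp(-t/tau1) + a2 exp(-t/tau2) + offset}
#' over the masked frames, by Levenberg-Marquardt with a deterministic
#' multistart grid (time constants seeded at fractions of the trace span,
#' amplitudes from the first/last masked values; among converged fits
#' those with an everywhere-positive baseline are preferred, then the
#' lowest SSE wins). Amplitudes and offset are constrained non-negative: a
#' bleaching envelope decays toward a non-negative plateau, and this keeps
#' the fitted baseline positive wherever it divides the trace. With \code{window_rule = "all_frames"} every frame enters the
#' fit; with \code{"last_25pct_gray"} only frames in the final 25% of each
#' gray period do (375 ms of a 1500 ms interleave), which anchors
#' deltaF/F = 0 at the inter-flash resting baseline.
#'
#' @param trace a [roi_trace()].
#' @param window_rule \code{"all_frames"} or \code{"last_25pct_gray"}.
#' @param log stimulus log; required for \code{"last_25pct_gray"}.
#' @param offset include the additive offset term (default TRUE; the
#'   offset nests the pure two-exponential model and absorbs a plateau).
#' @return object of class \code{bleach_fit}: parameters \code{a1},
#'   \code{tau1_s}, \code{a2}, \code{tau2_s}, \code{offset} (components
#'   ordered so \code{tau1_s <= tau2_s}), the \code{window_rule}, logical
#'   \code{mask} of fitted frames, fitted baseline \code{F0} at every
#'   frame, \code{sse}, and \code{converged}.
#' @examples
#' t <- seq(0, 100, by = 0.5)
#' tr <- roi_trace("r1", t, 700 * exp(-t / 20) + 300 * exp(-t / 80) + 50)
#' fit <- fit_bleach(tr)
#' c(fit$tau1_s, fit$tau2_s)
#' @export
fit_bleach <- function(trace,
                       window_rule = c("all_frames", "last_25pct_gray"),
                       log = NULL, offset = TRUE) {
  stopifnot(inherits(trace, "roi_trace"))
  window_rule <- match.arg(window_rule)
  if (window_rule == "last_25pct_gray") {
    if (is.null(log)) stop("window_rule 'last_25pct_gray' needs a stimulus log")
    mask <- last_quarter_gray_mask(trace$times_s, log)
  } else {
    mask <- rep(TRUE, length(trace$times_s))
  }
  n_par <- if (offset) 5L else 4L
  if (sum(mask) < n_par + 1L) {
    stop("bleach-fit mask selects ", sum(mask),
         " frames; need at least ", n_par + 1L)
  }
  t <- trace$times_s[mask]
  y <- trace$F[mask]
  out <- list(window_rule = window_rule, mask = mask)

  if (sd(y) < 1e-12 * max(abs(y), 1)) {
    # constant trace: the model collapses to the offset
    out <- c(out, list(a1 = 0, tau1_s = 1, a2 = 0, tau2_s = 10,
                       offset = y[1], sse = 0, converged = TRUE))
    out$F0 <- rep(y[1], length(trace$times_s))
    class(out) <- "bleach_fit"
    return(out)
  }

  # fit around the first masked frame: exp(-(t - t0)/tau) keeps the fast
  # component's design column well-scaled even when the window starts late
  t0 <- t[1]
  ts <- t - t0
  T_span <- diff(range(t))
  f_first <- mean(head(y, 3))
  f_last <- mean(tail(y, 3))
  model_resid <- function(par) {
    off_hat <- if (offset) par[["off"]] else 0
    y - (par[["a1"]] * exp(-ts / par[["tau1"]]) +
           par[["a2"]] * exp(-ts / par[["tau2"]]) + off_hat)
  }
  lower <- c(a1 = 0, tau1 = 1e-6, a2 = 0, tau2 = 1e-6)
  if (offset) lower <- c(lower, off = 0)
  best <- NULL
  for (st in bleach_start_grid(T_span, f_first, f_last, offset)) {
    par0 <- c(a1 = st$a1, tau1 = st$tau1, a2 = st$a2, tau2 = st$tau2)
    if (offset) par0 <- c(par0, off = st$off)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = model_resid, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 9)) next
    sse <- fit$deviance
    p <- fit$par
    off_hat <- if (offset) p[["off"]] else 0
    F0_cand <- p[["a1"]] * exp(-(trace$times_s - t0) / p[["tau1"]]) +
      p[["a2"]] * exp(-(trace$times_s - t0) / p[["tau2"]]) + off_hat
    # baselines must stay finite and positive on every frame they will
    # divide; a short fitting window can otherwise extrapolate below zero
    positive <- all(is.finite(F0_cand)) && all(F0_cand > 0)
    better <- is.null(best) ||
      (positive && !best$positive) ||
      (positive == best$positive && sse < best$sse)
    if (better) {
      best <- list(coef = p, off = off_hat, F0 = F0_cand, sse = sse,
                   positive = positive)
    }
    # a positive fit this good will not be beaten; skip remaining starts
    if (positive && sse <= 1e-16 * sum(y^2)) break
  }
  if (is.null(best)) stop("bleach fit failed to converge from every start")
  # report amplitudes in absolute time (a * exp(t0/tau)); a vanishing
  # component keeps amplitude 0 rather than a 0 * Inf artefact
  to_abs <- function(a, tau) if (a <= 1e-12) 0 else a * exp(min(t0 / tau, 700))
  a1 <- to_abs(best$coef[["a1"]], best$coef[["tau1"]])
  tau1 <- best$coef[["tau1"]]
  a2 <- to_abs(best$coef[["a2"]], best$coef[["tau2"]])
  tau2 <- best$coef[["tau2"]]
  off <- best$off
  if (tau1 > tau2) { # order components: fast first
    tmp <- a1; a1 <- a2; a2 <- tmp
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
  }
  F0 <- best$F0
  out <- c(out, list(a1 = a1, tau1_s = tau1, a2 = a2, tau2_s = tau2,
                     offset = off, sse = best$sse, converged = TRUE))
  out$F0 <- F0
  class(out) <- "bleach_fit"
  out
}

#' Compute deltaF/F from a trace and its bleach fit
#'
#' \code{dff(t) = (F(t) - F0(t)) / F0(t)} with the fitted baseline
#' evaluated at every frame as F0.
#'
#' @param trace a [roi_trace()].
#' @param fit a [fit_bleach()] result for the same trace.
#' @return object of class \code{dff_trace}: \code{roi_id},
#'   \code{times_s}, \code{dff}, \code{meta}.
#' @export
compute_dff <- function(trace, fit) {
  stopifnot(inherits(trace, "roi_trace"), inherits(fit, "bleach_fit"))
  if (length(fit$F0) != length(trace$F)) {
    stop("bleach fit does not match the trace length")
  }
  if (any(fit$F0 <= 0)) {
    stop("fitted baseline is non-positive on some frames; deltaF/F undefined")
  }
  structure(list(roi_id = trace$roi_id, times_s = trace$times_s,
                 dff = (trace$F - fit$F0) / fit$F0, meta = trace$meta),
            class = "dff_trace")
}
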