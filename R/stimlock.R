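# Stimulus-locked averaging. Every imaging frame is reassigned a time
# relative to each matching stimulus transition, samples are pooled over
# all transitions, and a simple moving average with a 25 ms window and an
# 8.33 ms shift is taken: this resamples 38.9 Hz data onto a 120 Hz grid
# with 3-point boxcar smoothing without otherwise distorting the signal.

#' Stimulus-locked moving-window average of a deltaF/F trace
#'
#' Reassigned sample times are \code{frame_time - transition_time}, pooled
#' over every transition of \code{transition_type}. The output grid is
#' \code{t_k = -pre_s + k * shift_s}; the value at each grid point is the
#' unweighted mean of all pooled samples whose reassigned time falls in the
#' centered half-open window \code{[t_k - window_s/2, t_k + window_s/2)}.
#' Grid points with no samples are dropped.
#'
#' @param dff a [compute_dff()] result.
#' @param log a \code{stimulus_log}; apply [compensate_delay()] first so
#'   that reassignment uses corrected onset times.
#' @param transition_type one of the log's transition types
#'   (\code{"to_light"}, \code{"to_dark"}, \code{"to_gray"}).
#' @param window_s averaging window in seconds (default 0.025).
#' @param shift_s grid spacing in seconds (default 0.00833, ~120 Hz).
#' @param pre_s,post_s grid extent before/after the transition, seconds.
#' @return object of class \code{stim_locked_average}: \code{grid_s},
#'   \code{mean_dff}, \code{sem_dff} (NA where n < 2), \code{n_per_bin},
#'   plus the parameters used.
#' @examples
#' log <- compensate_delay(build_stimulus_log(stimulus_spec(), 4))
#' @export
stimulus_locked_average <- function(dff, log, transition_type = "to_light",
                                    window_s = 0.025, shift_s = 0.00833,
                                    pre_s = 0.2, post_s = 1.0) {
  stopifnot(inherits(dff, "dff_trace"), inherits(log, "stimulus_log"))
  if (!(window_s >= shift_s)) stop("window_s must be >= shift_s")
  if (!(pre_s >= 0 && post_s > 0)) stop("need pre_s >= 0 and post_s > 0")
  tt <- log$transitions$t_s[log$transitions$type == transition_type]
  if (length(tt) == 0) {
    stop("no transitions of type '", transition_type, "' in the log")
  }
  # pooled reassigned times and values
  rt <- as.vector(outer(dff$times_s, tt, "-"))
  v <- rep(dff$dff, times = length(tt))
  keep <- rt >= -pre_s - window_s / 2 & rt < post_s + window_s / 2
  rt <- rt[keep]; v <- v[keep]
  if (length(rt) == 0) stop("no samples fall in any averaging window")

  ord <- order(rt)
  rt <- rt[ord]; v <- v[ord]
  cs <- c(0, cumsum(v))
  cs2 <- c(0, cumsum(v^2))

  k <- 0:floor((pre_s + post_s) / shift_s)
  grid <- -pre_s + k * shift_s
  lo <- grid - window_s / 2
  hi <- grid + window_s / 2
  i_lo <- findInterval(lo, rt, left.open = TRUE)   # samples strictly < lo
  i_hi <- findInterval(hi, rt, left.open = TRUE)   # samples strictly < hi
  n <- i_hi - i_lo
  s <- cs[i_hi + 1] - cs[i_lo + 1]
  s2 <- cs2[i_hi + 1] - cs2[i_lo + 1]
  mean_dff <- s / n
  var_dff <- (s2 - n * mean_dff^2) / (n - 1)
  sem <- sqrt(pmax(var_dff, 0) / n)
  sem[n < 2] <- NA_real_

  nz <- n >= 1
  structure(
    list(grid_s = grid[nz], mean_dff = mean_dff[nz], sem_dff = sem[nz],
         n_per_bin = n[nz], window_s = window_s, shift_s = shift_s,
         pre_s = pre_s, post_s = post_s,
         transition_type = transition_type),
    class = "stim_locked_average"
  )
}

#' Flag an ROI as responding to the search stimulus
#'
#' An ROI responds when the largest absolute stimulus-locked mean deltaF/F
#' inside the response window exceeds \code{k_sigma} times the SD of the
#' mean trace in the baseline window. The criterion (and k = 3) is this
#' package's interpretation of responder selection; it is configurable.
#'
#' @param avg a [stimulus_locked_average()] result.
#' @param k_sigma threshold multiple of the baseline SD (default 3).
#' @param baseline_window,response_window two-element numeric intervals on
#'   the reassigned-time axis, seconds (defaults: before vs. after onset).
#' @return logical scalar.
#' @export
identify_responder <- function(avg, k_sigma = 3,
                               baseline_window = c(-Inf, 0),
                               response_window = c(0, Inf)) {
  stopifnot(inherits(avg, "stim_locked_average"))
  in_base <- avg$grid_s >= baseline_window[1] & avg$grid_s < baseline_window[2]
  in_resp <- avg$grid_s >= response_window[1] & avg$grid_s < response_window[2]
  if (!any(in_base)) stop("baseline window contains no grid points")
  if (!any(in_resp)) stop("response window contains no grid points")
  base_sd <- sd(avg$mean_dff[in_base])
  if (is.na(base_sd)) base_sd <- 0
  max(abs(avg$mean_dff[in_resp])) > k_sigma * base_sd
}

#' Peak of a stimulus-locked average in the expected response direction
#'
#' The peak is the averaged deltaF/F value farthest from zero in the
#' expected direction of the initial response within the response window:
#' the maximum for \code{direction = "increase"} (a calcium rise), the
#' minimum for \code{"decrease"}.
#'
#' @param avg a [stimulus_locked_average()] result.
#' @param direction \code{"increase"} or \code{"decrease"}.
#' @param response_window_s two-element interval on the reassigned-time
#'   axis, seconds.
#' @return object of class \code{peak_response}: \code{value},
#'   \code{time_s}, \code{expected_direction}.
#' @export
peak_response <- function(avg, direction = c("increase", "decrease"),
                          response_window_s = c(0, 0.5)) {
  stopifnot(inherits(avg, "stim_locked_average"))
  direction <- match.arg(direction)
  sel <- avg$grid_s >= response_window_s[1] &
    avg$grid_s <= response_window_s[2]
  if (!any(sel)) stop("response window contains no grid points")
  vals <- avg$mean_dff[sel]
  ts <- avg$grid_s[sel]
  i <- if (direction == "increase") which.max(vals) else which.min(vals)
  structure(list(value = vals[i], time_s = ts[i],
                 expected_direction = direction),
            class = "peak_response")
}

#' Normalize peak responses to the mean of a control genotype
#'
#' Each peak is divided by the mean peak of the control group, so the
#' control group's normalized mean is exactly 1. When the table has a
#' \code{compartment} column, normalization is done within compartment
#' (each compartment has its own control mean).
#'
#' @param peaks data frame with columns \code{genotype} and \code{peak}
#'   (optionally \code{compartment}).
#' @param control genotype label of the control group (default
#'   \code{"no_flp_control"}).
#' @return \code{peaks} with an added \code{normalized_peak} column.
#' @export
normalize_peaks <- function(peaks, control = "no_flp_control") {
  stopifnot(is.data.frame(peaks),
            all(c("genotype", "peak") %in% names(peaks)))
  normalize_one <- function(df) {
    ctrl <- df$peak[df$genotype == control]
    if (length(ctrl) == 0) stop("control group '", control, "' is empty")
    m <- mean(ctrl)
    if (m == 0) stop("control group mean is zero; cannot normalize")
    df$normalized_peak <- df$peak / m
    df
  }
  if ("compartment" %in% names(peaks)) {
    parts <- split(peaks, peaks$compartment)
    out <- do.call(rbind, lapply(parts, normalize_one))
    rownames(out) <- NULL
    out
  } else {
    normalize_one(peaks)
  }
}
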