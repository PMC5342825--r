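# Stimulus protocols: a slow alternating search stimulus used to find
# responsive ROIs, and brief flashes off a gray interleave used for the
# quantified flash responses. Times are seconds internally; durations in the
# spec are milliseconds because that is how they are usually quoted.

#' Describe a visual stimulus protocol
#'
#' Two protocols are supported: \code{"search_2s"}, alternating full-contrast
#' light and dark flashes of 2 s each with no interleave, and
#' \code{"flash_off_gray"}, 25 ms light and dark flashes alternating with
#' each presentation, separated by 1500 ms of gray. The Michelson contrast of
#' the flashes relative to the gray is 0.5 by default. The projector updates
#' on a discrete stimulus frame (8.33 ms), so true onset times vary within
#' one frame; the mean physical onset lag (6.25 ms) is stored so that
#' imaging data can be shifted onto stimulus time.
#'
#' @param kind protocol name.
#' @param flash_ms flash duration in ms (defaults: 25 for
#'   \code{flash_off_gray}, 2000 for \code{search_2s}).
#' @param gray_ms gray interleave duration in ms (ignored by the search
#'   protocol).
#' @param contrast Michelson contrast of the flashes relative to gray, in
#'   \code{[0, 1]}.
#' @param stimulus_frame_ms duration of one stimulus frame in ms; onset
#'   jitter is uniform within this quantum.
#' @param delay_ms measured mean lag of the physical stimulus onset after
#'   the nominal command time, in ms.
#' @param gray_lum luminance of the gray interleave, arbitrary units.
#' @param screen_span_deg named numeric, horizontal/vertical extent of the
#'   screen in degrees of visual field (metadata only).
#' @return an object of class \code{stimulus_spec}.
#' @examples
#' stimulus_spec("flash_off_gray")
#' @export
stimulus_spec <- function(kind = c("flash_off_gray", "search_2s"),
                          flash_ms = NULL,
                          gray_ms = 1500,
                          contrast = 0.5,
                          stimulus_frame_ms = 8.33,
                          delay_ms = 6.25,
                          gray_lum = 1.0,
                          screen_span_deg = c(horizontal = 80, vertical = 50)) {
  kind <- match.arg(kind)
  if (is.null(flash_ms)) {
    flash_ms <- if (kind == "flash_off_gray") 25 else 2000
  }
  if (kind == "search_2s") gray_ms <- 0
  if (!(flash_ms > 0)) stop("flash_ms must be > 0")
  if (kind == "flash_off_gray" && !(gray_ms > 0)) {
    stop("gray_ms must be > 0 for the flash_off_gray protocol")
  }
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0, 1]")
  if (!(stimulus_frame_ms > 0)) stop("stimulus_frame_ms must be > 0")
  if (delay_ms < 0) stop("delay_ms must be >= 0")
  if (gray_lum < 0) stop("gray_lum must be >= 0")
  structure(
    list(kind = kind, flash_ms = flash_ms, gray_ms = gray_ms,
         contrast = contrast, stimulus_frame_ms = stimulus_frame_ms,
         delay_ms = delay_ms, gray_lum = gray_lum,
         screen_span_deg = screen_span_deg),
    class = "stimulus_spec"
  )
}

#' Build an ordered stimulus transition log
#'
#' Lays out the epoch sequence of a protocol over \code{n_cycles}
#' presentations and returns the ordered transition times. For
#' \code{flash_off_gray} each cycle is gray followed by one flash, with
#' flash polarity alternating light/dark starting with light; transitions
#' are \code{to_light}/\code{to_dark} at flash onset and \code{to_gray} at
#' flash offset. For \code{search_2s} each cycle is a 2 s light then a 2 s
#' dark flash with no gray. With \code{jitter_seed} set, every transition is
#' shifted by an independent uniform draw within one stimulus frame,
#' emulating the quantization of stimulus updates to the projector frame.
#'
#' @param spec a [stimulus_spec()].
#' @param n_cycles number of stimulus cycles (>= 1).
#' @param jitter_seed optional integer; when given, onsets are jittered
#'   uniformly on \code{[0, stimulus_frame_ms)} with this seed.
#' @return an object of class \code{stimulus_log}: a list with the
#'   \code{spec}, a data frame \code{transitions} (\code{t_s},
#'   \code{type}), and \code{delay_applied}.
#' @examples
#' log <- build_stimulus_log(stimulus_spec("flash_off_gray"), n_cycles = 2)
#' log$transitions
#' @export
build_stimulus_log <- function(spec, n_cycles, jitter_seed = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (!(is.numeric(n_cycles) && length(n_cycles) == 1L && n_cycles >= 1)) {
    stop("n_cycles must be >= 1")
  }
  n_cycles <- as.integer(n_cycles)
  flash_s <- spec$flash_ms / 1000
  gray_s <- spec$gray_ms / 1000
  if (spec$kind == "flash_off_gray") {
    k <- seq_len(n_cycles)
    onset <- (k - 1) * (gray_s + flash_s) + gray_s
    polarity <- ifelse(k %% 2 == 1, "to_light", "to_dark")
    t_s <- as.vector(rbind(onset, onset + flash_s))
    type <- as.vector(rbind(polarity, rep("to_gray", n_cycles)))
  } else { # search_2s
    k <- seq_len(n_cycles)
    t0 <- (k - 1) * 2 * flash_s
    t_s <- as.vector(rbind(t0, t0 + flash_s))
    type <- rep(c("to_light", "to_dark"), n_cycles)
  }
  if (!is.null(jitter_seed)) {
    set.seed(as.integer(jitter_seed))
    t_s <- t_s + runif(length(t_s), 0, spec$stimulus_frame_ms / 1000)
  }
  if (any(diff(t_s) <= 0)) stop("transition times must be strictly increasing")
  structure(
    list(spec = spec,
         transitions = data.frame(t_s = t_s, type = type,
                                  stringsAsFactors = FALSE),
         delay_applied = FALSE),
    class = "stimulus_log"
  )
}

#' Shift a stimulus log onto measured stimulus time
#'
#' The physical stimulus lags the nominal command times by a measured mean
#' delay; the corrected onset of every transition is
#' \code{nominal + delay_ms}. The shift may only be applied once: a second
#' call errors rather than silently double-compensating.
#'
#' @param log a [build_stimulus_log()] result.
#' @param delay_ms delay in ms; defaults to the value stored in the spec
#'   (6.25 ms).
#' @return the log with corrected transition times and
#'   \code{delay_applied = TRUE}.
#' @examples
#' log <- build_stimulus_log(stimulus_spec("flash_off_gray"), 2)
#' compensate_delay(log)$transitions$t_s[1] # 1.5 + 0.00625
#' @export
compensate_delay <- function(log, delay_ms = log$spec$delay_ms) {
  stopifnot(inherits(log, "stimulus_log"))
  if (isTRUE(log$delay_applied)) {
    stop("delay compensation has already been applied to this log")
  }
  if (delay_ms < 0) stop("delay_ms must be >= 0")
  log$transitions$t_s <- log$transitions$t_s + delay_ms / 1000
  log$delay_applied <- TRUE
  log
}

#' Michelson contrast of a flash relative to a reference luminance
#'
#' @param flash_lum flash luminance, arbitrary units, >= 0.
#' @param gray_lum reference (gray) luminance, arbitrary units, >= 0.
#' @return \code{|flash - gray| / (flash + gray)}.
#' @examples
#' michelson_contrast(3, 1) # 0.5
#' @export
michelson_contrast <- function(flash_lum, gray_lum) {
  if (any(flash_lum < 0) || any(gray_lum < 0)) {
    stop("luminances must be >= 0")
  }
  if (any(flash_lum + gray_lum == 0)) {
    stop("flash and gray luminance cannot both be zero")
  }
  abs(flash_lum - gray_lum) / (flash_lum + gray_lum)
}

#' Light- and dark-flash luminances realising a target Michelson contrast
#'
#' Inverts [michelson_contrast()] about a gray reference: the returned
#' light and dark luminances each have the requested contrast relative to
#' gray, with \code{light > gray > dark} for contrast > 0.
#'
#' @param gray_lum gray luminance, > 0.
#' @param contrast target Michelson contrast in \code{[0, 1)}. Contrast 1
#'   would require an infinite light luminance and is rejected.
#' @return named numeric \code{c(light =, dark =)}.
#' @examples
#' flash_luminances(1, 0.5) # light 3, dark 1/3
#' @export
flash_luminances <- function(gray_lum, contrast) {
  if (!(gray_lum > 0)) stop("gray_lum must be > 0")
  if (contrast < 0 || contrast >= 1) stop("contrast must be in [0, 1)")
  c(light = gray_lum * (1 + contrast) / (1 - contrast),
    dark = gray_lum * (1 - contrast) / (1 + contrast))
}

#' Gray-epoch intervals of a flash-off-gray stimulus log
#'
#' Returns the [start, end) interval of every gray period, including the
#' initial gray that precedes the first flash. The end of each gray period
#' is the onset of the following flash; a trailing gray with no following
#' flash ends one nominal gray duration after it starts.
#'
#' @param log a \code{stimulus_log} for the \code{flash_off_gray} protocol.
#' @return data frame with columns \code{start}, \code{end} (seconds).
#' @keywords internal
#' @export
gray_periods <- function(log) {
  stopifnot(inherits(log, "stimulus_log"))
  if (log$spec$kind != "flash_off_gray") {
    stop("gray periods are only defined for the flash_off_gray protocol")
  }
  tr <- log$transitions
  flash_onsets <- tr$t_s[tr$type %in% c("to_light", "to_dark")]
  # first gray runs from the recording start (gray_ms before the first
  # flash, floored at 0) to the first flash onset
  gray_starts <- c(max(0, flash_onsets[1] - log$spec$gray_ms / 1000),
                   tr$t_s[tr$type == "to_gray"])
  ends <- vapply(gray_starts, function(s) {
    nxt <- flash_onsets[flash_onsets > s]
    if (length(nxt)) min(nxt) else s + log$spec$gray_ms / 1000
  }, numeric(1))
  data.frame(start = gray_starts, end = ends)
}
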