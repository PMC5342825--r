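# Calcium-indicator impulse response used by the synthetic generator. The
# exact kernel shape is not part of any result; the pipeline only assumes a
# transient that rises fast and decays slower, so a difference of
# exponentials normalized to unit peak is used, with GCaMP6f-scale defaults.

#' Difference-of-exponentials calcium transient kernel, unit peak
#'
#' \code{k(t) = (exp(-t/decay) - exp(-t/rise)) / k_max} for \code{t >= 0},
#' zero before onset, where \code{k_max} makes the peak exactly 1.
#'
#' @param t times in seconds relative to onset.
#' @param rise_s rise time constant, seconds (default 0.05).
#' @param decay_s decay time constant, seconds (default 0.4); must exceed
#'   \code{rise_s}.
#' @return kernel values, peak value 1 at [kernel_peak_time()].
#' @examples
#' gcamp_kernel(kernel_peak_time()) # 1
#' @export
gcamp_kernel <- function(t, rise_s = 0.05, decay_s = 0.4) {
  if (!(rise_s > 0 && decay_s > rise_s)) {
    stop("need 0 < rise_s < decay_s")
  }
  tp <- kernel_peak_time(rise_s, decay_s)
  k_max <- exp(-tp / decay_s) - exp(-tp / rise_s)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay_s) - exp(-t[pos] / rise_s)) / k_max
  out
}

#' Time of the kernel peak
#'
#' @inheritParams gcamp_kernel
#' @return peak time in seconds after onset.
#' @export
kernel_peak_time <- function(rise_s = 0.05, decay_s = 0.4) {
  if (!(rise_s > 0 && decay_s > rise_s)) {
    stop("need 0 < rise_s < decay_s")
  }
  rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
}
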