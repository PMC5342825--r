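# ROI-trace generator. Signal model:
#   F(t) = B(t) * (1 + sum_trials m * k(t - t_onset)) + eps(t)
# with B(t) the two-exponential bleaching envelope, k the unit-peak
# transient kernel, m the effect-map amplitude, and eps i.i.d. noise.
# Physical onsets lag the nominal log by the projector delay plus a uniform
# within-stimulus-frame jitter; the returned log carries nominal times (as
# an acquisition log would) and the ground truth carries the real onsets.

#' Generate synthetic ROI fluorescence traces with ground truth
#'
#' Produces \code{n_rois} traces for every requested genotype-compartment
#' combination, all sharing one nominal stimulus log, together with the
#' ground truth needed for parameter-recovery tests: per-ROI bleach
#' parameters (absolute, i.e. scaled by \code{baseline_F}), the programmed
#' peak deltaF/F, and the true (delayed, jittered) transition onsets per
#' ROI.
#'
#' @param cfg a [sim_config()].
#' @return list with elements \code{traces} (list of \code{roi_trace}),
#'   \code{log} (nominal \code{stimulus_log}, delay not applied) and
#'   \code{truth} (list keyed by \code{roi_id}).
#' @examples
#' sim <- generate_roi_traces(sim_config(seed = 1, n_rois = 1,
#'                                       compartments = "M5", n_cycles = 4))
#' length(sim$traces)
#' @export
generate_roi_traces <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  log <- build_stimulus_log(cfg$stim_spec, cfg$n_cycles)
  tr <- log$transitions
  is_light <- tr$type == "to_light"
  is_dark <- tr$type == "to_dark"
  onset_idx <- which(is_light | is_dark)
  delay_s <- cfg$stim_spec$delay_ms / 1000
  frame_s <- cfg$stim_spec$stimulus_frame_ms / 1000

  duration <- max(tr$t_s) + max(cfg$stim_spec$gray_ms / 1000, 1)
  n_frames <- floor(duration * cfg$frame_rate) + 1L
  t <- (seq_len(n_frames) - 1L) / cfg$frame_rate

  grid <- expand.grid(rep = seq_len(cfg$n_rois),
                      genotype = cfg$genotypes,
                      compartment = cfg$compartments,
                      stringsAsFactors = FALSE)
  set.seed(substream_seed(cfg$seed, "roi_traces"))
  bl <- cfg$bleach
  traces <- vector("list", nrow(grid))
  truth <- vector("list", nrow(grid))
  ids <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid$genotype[i]
    comp <- grid$compartment[i]
    roi_id <- sprintf("%s_%s_r%02d", g, comp, grid$rep[i])
    j <- 1 + runif(4, -cfg$param_jitter, cfg$param_jitter)
    a1 <- cfg$baseline_F * bl$a1 * j[1]
    tau1 <- bl$tau1_s * j[2]
    a2 <- cfg$baseline_F * bl$a2 * j[3]
    tau2 <- bl$tau2_s * j[4]
    off <- cfg$baseline_F * bl$offset
    B <- a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + off

    m_light <- cfg$base_amplitude * effect_multiplier(cfg$effect_map, g, comp)
    m_dark <- m_light * cfg$dark_amplitude_frac
    jit <- runif(length(onset_idx), 0, frame_s)
    true_onsets <- tr$t_s[onset_idx] + delay_s + jit
    amp <- ifelse(is_light[onset_idx], m_light, m_dark)
    S <- numeric(n_frames)
    for (k in seq_along(onset_idx)) {
      if (amp[k] > 0) {
        S <- S + amp[k] * gcamp_kernel(t - true_onsets[k],
                                       cfg$kernel$rise_s, cfg$kernel$decay_s)
      }
    }
    clean <- B * (1 + S)
    F_obs <- if (cfg$noise_model == "poisson") {
      stats::rpois(n_frames, lambda = pmax(clean, 0))
    } else if (cfg$noise_sd > 0) {
      clean + rnorm(n_frames, 0, cfg$noise_sd)
    } else {
      clean
    }
    traces[[i]] <- roi_trace(roi_id, t, F_obs,
                             meta = list(fly_id = sprintf("fly%02d", grid$rep[i]),
                                         compartment = comp, genotype = g))
    truth[[i]] <- list(
      bleach = list(a1 = a1, tau1_s = tau1, a2 = a2, tau2_s = tau2,
                    offset = off),
      true_peak_dff = m_light,
      onsets = data.frame(t_s = true_onsets,
                          type = tr$type[onset_idx],
                          stringsAsFactors = FALSE)
    )
    ids[i] <- roi_id
  }
  names(truth) <- ids
  names(traces) <- ids
  list(traces = traces, log = log, truth = truth)
}
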