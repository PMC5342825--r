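# Generator configuration. Defaults are the study conditions the pipeline
# is designed for: 38.9 Hz acquisition, 25 ms flashes off 1500 ms gray at
# Michelson contrast 0.5, a two-exponential bleaching envelope, GCaMP6f-like
# transient dynamics, and a genotype-by-compartment amplitude map whose
# default reproduces the qualitative disruption pattern (reduced responses
# in the cell body and lobula arbors, unchanged in M1/M8/M10, increased in
# M5 of the experimental genotype).

#' Default genotype-by-compartment amplitude multiplier map
#'
#' Control genotypes have multiplier 1 everywhere. The experimental
#' genotype has reduced amplitude (0.5) in the cell body and the lobula
#' arbors Lo1/Lo4, unchanged amplitude in M1/M8/M10, and increased
#' amplitude (3) in M5. The map is fully configurable; nothing downstream
#' treats these values as truth.
#'
#' @return data frame with columns \code{genotype}, \code{compartment},
#'   \code{multiplier}.
#' @export
default_effect_map <- function() {
  compartments <- c("cell_body", "M1", "M5", "M8", "M10", "Lo1", "Lo4")
  genotypes <- c("experimental", "no_flp_control", "het_control")
  m <- expand.grid(genotype = genotypes, compartment = compartments,
                   stringsAsFactors = FALSE)
  m$multiplier <- 1
  exper <- m$genotype == "experimental"
  m$multiplier[exper & m$compartment %in% c("cell_body", "Lo1", "Lo4")] <- 0.5
  m$multiplier[exper & m$compartment == "M5"] <- 3
  m[order(m$compartment, m$genotype), , drop = FALSE]
}

#' Configuration of the synthetic imaging-data generator
#'
#' @param seed root integer seed; all randomness fans out from it through
#'   named substreams (see [substream_seed()]).
#' @param frame_rate imaging frame rate in Hz (default 38.9).
#' @param stim_spec a [stimulus_spec()] (default: flashes off gray).
#' @param n_cycles number of stimulus cycles presented.
#' @param bleach list \code{(a1, tau1_s, a2, tau2_s, offset)} describing
#'   the fractional bleaching envelope
#'   \code{B(t) = baseline_F * (a1 exp(-t/tau1) + a2 exp(-t/tau2) + offset)}.
#' @param kernel list \code{(rise_s, decay_s)} of the transient kernel.
#' @param baseline_F fluorescence scale at time zero, arbitrary units
#'   (\code{a1 + a2 + offset = 1} makes \code{B(0) = baseline_F}).
#' @param base_amplitude peak deltaF/F of a multiplier-1 response
#'   (dimensionless).
#' @param dark_amplitude_frac amplitude of dark-flash responses as a
#'   fraction of the light-flash amplitude (default 0: the dark response is
#'   minimal and not analysed).
#' @param noise_sd SD of additive Gaussian noise on F, same units as
#'   \code{baseline_F}.
#' @param noise_model \code{"gaussian"} (default) or \code{"poisson"}
#'   (photon-count noise: F drawn as \code{rpois(F_clean)}).
#' @param effect_map data frame \code{(genotype, compartment, multiplier)}.
#' @param genotypes,compartments which groups to generate; every requested
#'   combination must appear in \code{effect_map}.
#' @param n_rois ROIs per genotype-compartment combination.
#' @param param_jitter half-width of the multiplicative uniform jitter
#'   applied per ROI to the bleach amplitudes and time constants (0 makes
#'   every ROI share the configured bleach exactly).
#' @return an object of class \code{sim_config}.
#' @examples
#' cfg <- sim_config(seed = 1, n_rois = 2, compartments = "M5")
#' @export
sim_config <- function(seed = 1L,
                       frame_rate = 38.9,
                       stim_spec = stimulus_spec("flash_off_gray"),
                       n_cycles = 16L,
                       bleach = list(a1 = 0.55, tau1_s = 20, a2 = 0.25,
                                     tau2_s = 200, offset = 0.2),
                       kernel = list(rise_s = 0.05, decay_s = 0.4),
                       baseline_F = 1000,
                       base_amplitude = 0.2,
                       dark_amplitude_frac = 0,
                       noise_sd = 40,
                       noise_model = c("gaussian", "poisson"),
                       effect_map = default_effect_map(),
                       genotypes = c("experimental", "no_flp_control",
                                     "het_control"),
                       compartments = c("M1", "M5"),
                       n_rois = 10L,
                       param_jitter = 0.1) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(stim_spec, "stimulus_spec"))
  if (!(frame_rate > 0)) stop("frame_rate must be > 0")
  if (!(bleach$tau1_s > 0 && bleach$tau2_s > 0)) {
    stop("bleach time constants must be > 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!(baseline_F > 0)) stop("baseline_F must be > 0")
  if (base_amplitude < 0) stop("base_amplitude must be >= 0")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (n_rois < 1) stop("n_rois must be >= 1")
  if (param_jitter < 0 || param_jitter >= 1) {
    stop("param_jitter must be in [0, 1)")
  }
  need <- expand.grid(genotype = genotypes, compartment = compartments,
                      stringsAsFactors = FALSE)
  key <- paste(need$genotype, need$compartment)
  have <- paste(effect_map$genotype, effect_map$compartment)
  if (any(!key %in% have)) {
    stop("effect_map has no entry for: ",
         paste(key[!key %in% have], collapse = ", "))
  }
  if (any(effect_map$multiplier < 0)) {
    stop("amplitude multipliers must be >= 0")
  }
  structure(
    list(seed = as.integer(seed), frame_rate = frame_rate,
         stim_spec = stim_spec, n_cycles = as.integer(n_cycles),
         bleach = bleach, kernel = kernel, baseline_F = baseline_F,
         base_amplitude = base_amplitude,
         dark_amplitude_frac = dark_amplitude_frac,
         noise_sd = noise_sd, noise_model = noise_model,
         effect_map = effect_map, genotypes = genotypes,
         compartments = compartments, n_rois = as.integer(n_rois),
         param_jitter = param_jitter),
    class = "sim_config"
  )
}

# amplitude multiplier lookup; errors when the combination is absent
effect_multiplier <- function(effect_map, genotype, compartment) {
  hit <- effect_map$genotype == genotype &
    effect_map$compartment == compartment
  if (!any(hit)) {
    stop("effect_map has no entry for genotype '", genotype,
         "', compartment '", compartment, "'")
  }
  effect_map$multiplier[which(hit)[1]]
}
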