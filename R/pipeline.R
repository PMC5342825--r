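# End-to-end orchestration: simulate (or load) traces -> bleach fit ->
# deltaF/F -> stimulus-locked average -> responder flag -> peak ->
# normalization -> ANOVA + Bonferroni post-hoc per compartment. Every
# stage is deterministic given the config's seed, and a resolved copy of
# the config is written beside the outputs so runs are auditable.

#' Configuration of an end-to-end run
#'
#' @param seed root integer seed (also fed to the embedded [sim_config()]
#'   unless one is supplied).
#' @param sim a [sim_config()]; built from \code{seed} and \code{...} by
#'   default.
#' @param window_ms moving-average window (default 25).
#' @param shift_ms moving-average shift / output grid spacing
#'   (default 8.33, i.e. ~120 Hz).
#' @param delay_ms stimulus delay compensation (default 6.25).
#' @param window_rule bleach-fit frame selection (see [fit_bleach()]).
#' @param responder_k responder threshold in baseline SDs.
#' @param pre_s,post_s stimulus-locked grid extent, seconds.
#' @param response_window_s window searched for the peak, seconds.
#' @param control control genotype for normalization.
#' @param transition_type transition the average is locked to.
#' @param responders_only restrict group statistics to responding ROIs.
#' @param out_dir optional output directory; when set, peaks, averages,
#'   statistics, ground truth and the resolved config are written there.
#' @param ... forwarded to [sim_config()] when \code{sim} is NULL.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, sim = NULL, window_ms = 25,
                       shift_ms = 8.33, delay_ms = 6.25,
                       window_rule = "last_25pct_gray", responder_k = 3,
                       pre_s = 0.2, post_s = 1.0,
                       response_window_s = c(0, 0.5),
                       control = "no_flp_control",
                       transition_type = "to_light",
                       responders_only = TRUE,
                       out_dir = NULL, ...) {
  if (is.null(sim)) sim <- sim_config(seed = seed, ...)
  stopifnot(inherits(sim, "sim_config"))
  structure(
    list(seed = as.integer(seed), sim = sim, window_ms = window_ms,
         shift_ms = shift_ms, delay_ms = delay_ms,
         window_rule = window_rule, responder_k = responder_k,
         pre_s = pre_s, post_s = post_s,
         response_window_s = response_window_s, control = control,
         transition_type = transition_type,
         responders_only = responders_only, out_dir = out_dir),
    class = "run_config"
  )
}

#' Process one ROI trace through the imaging pipeline
#'
#' Bleach fit, deltaF/F, stimulus-locked average, responder flag, peak.
#'
#' @param trace a [roi_trace()].
#' @param log a delay-compensated \code{stimulus_log}.
#' @param cfg a [run_config()].
#' @return list with \code{fit}, \code{dff}, \code{avg}, \code{responder},
#'   \code{peak}.
#' @export
process_roi <- function(trace, log, cfg) {
  fit <- fit_bleach(trace, window_rule = cfg$window_rule, log = log)
  dff <- compute_dff(trace, fit)
  avg <- stimulus_locked_average(dff, log,
                                 transition_type = cfg$transition_type,
                                 window_s = cfg$window_ms / 1000,
                                 shift_s = cfg$shift_ms / 1000,
                                 pre_s = cfg$pre_s, post_s = cfg$post_s)
  responder <- identify_responder(avg, k_sigma = cfg$responder_k,
                                  baseline_window = c(-cfg$pre_s, 0),
                                  response_window = c(0, cfg$post_s))
  peak <- peak_response(avg, direction = "increase",
                        response_window_s = cfg$response_window_s)
  list(fit = fit, dff = dff, avg = avg, responder = responder, peak = peak)
}

#' Run the full synthetic pipeline
#'
#' Generates traces from the embedded [sim_config()], processes every ROI
#' (see [process_roi()]), normalizes peaks to the control genotype within
#' each compartment, and computes per-compartment one-way ANOVAs plus
#' Bonferroni-corrected post-hoc comparisons of the experimental genotype
#' against both controls. Deterministic given the config.
#'
#' @param cfg a [run_config()].
#' @param traces,log optionally supply pre-loaded traces and a (nominal)
#'   stimulus log instead of simulating; the log must not yet be
#'   delay-compensated.
#' @return list of class \code{run_bundle}: \code{config}, \code{peaks}
#'   (per-ROI data frame), \code{averages} (named list of
#'   \code{stim_locked_average}), \code{stats} (per-compartment list with
#'   \code{anova}, \code{posthoc}), \code{truth} (when simulated).
#' @export
run_end_to_end <- function(cfg, traces = NULL, log = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  truth <- NULL
  if (is.null(traces)) {
    sim <- generate_roi_traces(cfg$sim)
    traces <- sim$traces
    log <- sim$log
    truth <- sim$truth
  }
  if (is.null(log)) stop("a stimulus log is required with supplied traces")
  clog <- compensate_delay(log, cfg$delay_ms)

  averages <- vector("list", length(traces))
  rows <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    res <- tryCatch(process_roi(tr, clog, cfg), error = function(e) {
      stop("pipeline failed at ROI '", tr$roi_id, "': ",
           conditionMessage(e), call. = FALSE)
    })
    averages[[i]] <- res$avg
    rows[[i]] <- data.frame(
      roi_id = tr$roi_id,
      fly_id = tr$meta$fly_id %||% NA_character_,
      compartment = tr$meta$compartment %||% NA_character_,
      genotype = tr$meta$genotype %||% NA_character_,
      responder = res$responder,
      peak = res$peak$value,
      peak_time_s = res$peak$time_s,
      stringsAsFactors = FALSE
    )
  }
  names(averages) <- vapply(traces, `[[`, character(1), "roi_id")
  peaks <- do.call(rbind, rows)

  used <- if (cfg$responders_only) peaks[peaks$responder, , drop = FALSE]
          else peaks
  stats_by_comp <- list()
  if (nrow(used)) {
    used <- normalize_peaks(used, control = cfg$control)
    for (comp in unique(used$compartment)) {
      sub <- used[used$compartment == comp, ]
      groups <- split(sub$normalized_peak, sub$genotype)
      controls <- setdiff(names(groups), "experimental")
      enough <- all(lengths(groups) >= 2)
      if (!("experimental" %in% names(groups)) || length(controls) != 2 ||
          !enough) {
        stats_by_comp[[comp]] <- list(anova = NULL, posthoc = NULL)
        next
      }
      stats_by_comp[[comp]] <- list(
        anova = anova_oneway(groups),
        posthoc = posthoc_bonferroni(groups[["experimental"]],
                                     groups[[controls[1]]],
                                     groups[[controls[2]]])
      )
    }
    peaks <- merge(peaks, used[, c("roi_id", "normalized_peak")],
                   by = "roi_id", all.x = TRUE, sort = FALSE)
  }

  bundle <- structure(
    list(config = cfg, peaks = peaks, averages = averages,
         stats = stats_by_comp, truth = truth),
    class = "run_bundle"
  )
  if (!is.null(cfg$out_dir)) write_run_bundle(bundle, cfg$out_dir)
  bundle
}

#' Write a run bundle's tables and resolved configuration to a directory
#'
#' @param bundle a [run_end_to_end()] result.
#' @param dir output directory (created if needed).
#' @export
write_run_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "run_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$peaks, file.path(dir, "peaks.csv"), row.names = FALSE)
  avg_rows <- lapply(names(bundle$averages), function(id) {
    a <- bundle$averages[[id]]
    data.frame(roi_id = id, grid_s = a$grid_s, mean_dff = a$mean_dff,
               sem_dff = a$sem_dff, n = a$n_per_bin)
  })
  write.csv(do.call(rbind, avg_rows),
            file.path(dir, "stim_locked_averages.csv"), row.names = FALSE)
  stats_out <- lapply(bundle$stats, function(s) {
    if (is.null(s$anova)) return(list(note = "insufficient groups"))
    list(anova = unclass(s$anova),
         posthoc = list(
           vs_control_a = unclass(s$posthoc$vs_control_a),
           vs_control_b = unclass(s$posthoc$vs_control_b),
           raw_p = as.list(s$posthoc$raw_p),
           display = s$posthoc$display,
           display_tier = s$posthoc$display_tier))
  })
  jsonlite::write_json(stats_out, file.path(dir, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  cfgs <- bundle$config
  cfgs$sim$stim_spec <- unclass(cfgs$sim$stim_spec)
  cfgs$sim <- unclass(cfgs$sim)
  jsonlite::write_json(unclass(cfgs), file.path(dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$truth)) {
    write_ground_truth(bundle$truth, file.path(dir, "ground_truth.json"))
  }
  invisible(dir)
}
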