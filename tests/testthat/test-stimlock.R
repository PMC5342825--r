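# Stimulus-locked resampling, responder classification, peaks and
# normalization.

test_that("the output grid is spaced exactly at the shift", {
  cfg <- noiseless_cfg(n_cycles = 6)
  sim <- generate_roi_traces(cfg)
  log <- compensate_delay(sim$log)
  fit <- fit_bleach(sim$traces[[1]], "last_25pct_gray", log)
  dff <- compute_dff(sim$traces[[1]], fit)
  avg <- stimulus_locked_average(dff, log, "to_light")
  expect_equal(diff(avg$grid_s), rep(0.00833, length(avg$grid_s) - 1),
               tolerance = 1e-12)
  # ~120 Hz effective rate from a 38.9 Hz acquisition
  expect_equal(1 / avg$shift_s, 120, tolerance = 0.01)
  # window changes smoothing, never the grid
  avg2 <- stimulus_locked_average(dff, log, "to_light", window_s = 0.05)
  expect_equal(avg2$grid_s, avg$grid_s)
})

test_that("a 25 ms window spreads each sample over 3 consecutive bins", {
  # one transition at 0, one sample at a generic offset
  d <- dff_trace("r", c(0.1003, 1), c(1, 0))
  avg <- stimulus_locked_average(d, structure(list(
    spec = stimulus_spec(), delay_applied = TRUE,
    transitions = data.frame(t_s = 0, type = "to_light")),
    class = "stimulus_log"),
    "to_light", pre_s = 0, post_s = 0.3)
  expect_equal(sum(avg$n_per_bin[avg$grid_s < 0.2]), 3)
})

test_that("samples on the grid with a narrow window map one to one", {
  grid <- seq(0, 0.5, by = 0.00833)
  vals <- sin(seq_along(grid))
  d <- dff_trace("r", 2 + grid, vals)
  log <- structure(list(spec = stimulus_spec(), delay_applied = TRUE,
                        transitions = data.frame(t_s = 2,
                                                 type = "to_light")),
                   class = "stimulus_log")
  avg <- stimulus_locked_average(d, log, "to_light", window_s = 0.00833,
                                 shift_s = 0.00833, pre_s = 0,
                                 post_s = 0.5)
  expect_equal(avg$n_per_bin, rep(1L, length(avg$grid_s)))
  expect_equal(avg$mean_dff, vals[seq_along(avg$grid_s)])
})

test_that("the resampler equals a brute-force pooled-window mean", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(100:400, 1)
    times <- sort(runif(n, 0, 20))
    times <- times[c(TRUE, diff(times) > 1e-6)]
    vals <- rnorm(length(times))
    tt <- sort(runif(sample(2:5, 1), 2, 18))
    log <- structure(list(spec = stimulus_spec(), delay_applied = TRUE,
                          transitions = data.frame(t_s = tt,
                                                   type = "to_light")),
                     class = "stimulus_log")
    w <- runif(1, 0.02, 0.1)
    s <- runif(1, 0.005, w)
    avg <- stimulus_locked_average(dff_trace("r", times, vals), log,
                                   "to_light", window_s = w, shift_s = s,
                                   pre_s = 0.3, post_s = 1.2)
    oracle <- brute_force_stimlock(times, vals, tt, w, s, 0.3, 1.2)
    expect_equal(avg$grid_s, oracle$grid_s, tolerance = 1e-12)
    expect_equal(avg$n_per_bin, oracle$n_per_bin)
    expect_equal(avg$mean_dff, oracle$mean_dff, tolerance = 1e-12)
  }
})

test_that("responder classification follows the k-sigma rule", {
  mk_avg <- function(mean_dff, grid) {
    structure(list(grid_s = grid, mean_dff = mean_dff,
                   sem_dff = rep(NA_real_, length(grid)),
                   n_per_bin = rep(5L, length(grid)), window_s = 0.025,
                   shift_s = 0.00833, pre_s = 0.5, post_s = 1,
                   transition_type = "to_light"),
              class = "stim_locked_average")
  }
  grid <- seq(-0.5, 1, by = 0.01)
  base_sd <- 0.02
  set.seed(17)
  baseline <- rnorm(sum(grid < 0), 0, base_sd)
  resp <- rep(0, sum(grid >= 0))
  resp[30] <- 5 * base_sd * 1.5 # comfortably beyond 5 sigma of truth
  trace <- mk_avg(c(baseline, resp), grid)
  expect_true(identify_responder(trace, k_sigma = 3))
  expect_false(identify_responder(mk_avg(rep(0, length(grid)), grid)))
  expect_error(identify_responder(trace, baseline_window = c(-3, -2)),
               "baseline")
})

test_that("flat-noise false positives are consistent with the Gaussian tail", {
  grid <- seq(-1, 1, length.out = 201)
  n_base <- sum(grid < 0)
  n_resp <- sum(grid >= 0)
  set.seed(77)
  hits <- vapply(1:400, function(i) {
    avg <- structure(list(grid_s = grid, mean_dff = rnorm(201),
                          sem_dff = rep(NA_real_, 201),
                          n_per_bin = rep(5L, 201), window_s = 0.025,
                          shift_s = 0.01, pre_s = 1, post_s = 1,
                          transition_type = "to_light"),
                     class = "stim_locked_average")
    identify_responder(avg, k_sigma = 3)
  }, logical(1))
  p_bin <- 2 * pnorm(-3)
  expected <- 1 - (1 - p_bin)^n_resp # independent-bin Gaussian rate
  expect_lt(abs(mean(hits) - expected), 0.1)
})

test_that("peaks take the extreme value in the expected direction", {
  grid <- seq(0, 0.5, by = 0.01)
  vals <- 0.8 * sin(pi * grid / 0.5) - 0.3 * sin(2 * pi * grid / 0.5)
  avg <- structure(list(grid_s = grid, mean_dff = vals,
                        sem_dff = rep(NA_real_, length(grid)),
                        n_per_bin = rep(3L, length(grid)),
                        window_s = 0.025, shift_s = 0.01, pre_s = 0,
                        post_s = 0.5, transition_type = "to_light"),
                   class = "stim_locked_average")
  up <- peak_response(avg, "increase", c(0, 0.5))
  dn <- peak_response(avg, "decrease", c(0, 0.5))
  expect_equal(up$value, max(vals))
  expect_equal(up$time_s, grid[which.max(vals)])
  expect_equal(dn$value, min(vals))
  zero <- avg; zero$mean_dff <- rep(0, length(grid))
  expect_equal(peak_response(zero)$value, 0)
  expect_error(peak_response(avg, response_window_s = c(2, 3)), "window")
})

test_that("smoothing bias at the peak is bounded by the boxcar curvature", {
  rise <- 0.05; decay <- 0.4; m <- 0.4
  fr <- 38.9
  # trials far apart so transient tails do not overlap
  onsets <- seq(2, 50, by = 6)
  t <- seq(0, 55, by = 1 / fr)
  set.seed(8)
  onsets <- onsets + runif(length(onsets), 0, 0.00833)
  y <- rowSums(vapply(onsets, function(o) {
    m * gcamp_kernel(t - o, rise, decay)
  }, numeric(length(t))))
  log <- structure(list(spec = stimulus_spec(), delay_applied = TRUE,
                        transitions = data.frame(t_s = onsets,
                                                 type = "to_light")),
                   class = "stimulus_log")
  avg <- stimulus_locked_average(dff_trace("r", t, y), log, "to_light",
                                 pre_s = 0.1, post_s = 1.0)
  pk <- peak_response(avg, "increase", c(0, 0.5))
  # curvature of the kernel at its peak
  tp <- kernel_peak_time(rise, decay)
  k_max <- exp(-tp / decay) - exp(-tp / rise)
  k2 <- abs((exp(-tp / decay) / decay^2 - exp(-tp / rise) / rise^2) / k_max)
  w <- avg$window_s; s <- avg$shift_s; f <- 0.00833
  bound <- m * k2 * (w^2 / 24 + s^2 / 8 + f^2 / 24) * 2
  expect_lte(pk$value, m + 1e-12)
  expect_gte(pk$value, m - bound)
})

test_that("normalization anchors the control mean at one", {
  peaks <- data.frame(
    roi_id = letters[1:5],
    genotype = c("no_flp_control", "no_flp_control", "experimental",
                 "experimental", "het_control"),
    peak = c(1, 1, 2, 2.4, 1.2))
  norm <- normalize_peaks(peaks)
  expect_equal(norm$normalized_peak[3], 2)
  expect_equal(mean(norm$normalized_peak[norm$genotype == "no_flp_control"]),
               1)

  # with compartments, each gets its own control mean
  peaks$compartment <- c("M5", "M1", "M5", "M1", "M5")
  by_comp <- normalize_peaks(peaks)
  m5_ctrl <- by_comp$normalized_peak[by_comp$genotype == "no_flp_control" &
                                       by_comp$compartment == "M5"]
  expect_equal(mean(m5_ctrl), 1)
  expect_equal(by_comp$normalized_peak[by_comp$roi_id == "d"], 2.4)

  # a compartment without control observations cannot be normalized
  orphan <- peaks[peaks$genotype == "experimental", ]
  expect_error(normalize_peaks(orphan), "empty")
  zero <- data.frame(genotype = c("no_flp_control", "experimental"),
                     peak = c(0, 1))
  expect_error(normalize_peaks(zero), "zero")
})
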