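# Generator contracts: exact signal decomposition, determinism, and
# ground-truth consistency for every synthetic input type.

test_that("noiseless, zero-amplitude traces equal the bleaching envelope", {
  cfg <- noiseless_cfg(base_amplitude = 0)
  sim <- generate_roi_traces(cfg)
  tr <- sim$traces[[1]]
  bl <- sim$truth[[1]]$bleach
  B <- bl$a1 * exp(-tr$times_s / bl$tau1_s) +
    bl$a2 * exp(-tr$times_s / bl$tau2_s) + bl$offset
  expect_identical(tr$F, B)
})

test_that("the same seed reproduces traces bit for bit", {
  cfg <- sim_config(seed = 7, n_rois = 2, compartments = "M5", n_cycles = 4)
  s1 <- generate_roi_traces(cfg)
  s2 <- generate_roi_traces(cfg)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_roi_traces(sim_config(seed = 8, n_rois = 2,
                                       compartments = "M5", n_cycles = 4))
  expect_false(identical(s1$traces[[1]]$F, s3$traces[[1]]$F))
})

test_that("a single noiseless transient peaks at the programmed amplitude", {
  cfg <- noiseless_cfg(n_cycles = 1, base_amplitude = 0.5)
  sim <- generate_roi_traces(cfg)
  tr <- sim$traces[[1]]
  bl <- sim$truth[[1]]$bleach
  B <- bl$a1 * exp(-tr$times_s / bl$tau1_s) +
    bl$a2 * exp(-tr$times_s / bl$tau2_s) + bl$offset
  onset <- sim$truth[[1]]$onsets$t_s[1]
  # analytic oracle: amplitude times the kernel evaluated at the frame grid
  expected <- 0.5 * max(gcamp_kernel(tr$times_s - onset,
                                     cfg$kernel$rise_s, cfg$kernel$decay_s))
  expect_equal(max((tr$F - B) / B), expected, tolerance = 1e-12)
})

test_that("unknown genotype-compartment combinations are rejected", {
  expect_error(sim_config(genotypes = "mystery_genotype"), "effect_map")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(frame_rate = 0), "frame_rate")
})

test_that("movie blobs reproduce the generating trace up to quantization", {
  cfg <- noiseless_cfg(n_cycles = 3, base_amplitude = 0.4)
  mov <- generate_movie(cfg, frame_dim = c(40L, 40L), blob_radius_px = 4,
                        background_level = 10)
  id <- names(mov$traces)[1]
  got <- extract_roi_trace(mov$stack, mov$masks[[id]], mov$background_mask,
                           frame_rate = cfg$frame_rate)
  expect_true(max(abs(got$F - mov$traces[[id]]$F)) <= 0.5)
})

test_that("zero-amplitude movie blobs sit flat at the background level", {
  cfg <- noiseless_cfg(base_amplitude = 0, n_cycles = 2,
                       bleach = list(a1 = 0, tau1_s = 20, a2 = 0,
                                     tau2_s = 200, offset = 0))
  # offset-zero bleach makes the blob trace identically 0
  mov <- generate_movie(cfg, frame_dim = c(32L, 32L), background_level = 50)
  expect_true(all(mov$stack == 50))
  mov2 <- generate_movie(cfg, frame_dim = c(32L, 32L), background_level = 50)
  expect_identical(mov$stack, mov2$stack)
})

test_that("cell clouds plant exactly the requested colocalized fraction", {
  cl <- generate_cell_cloud(20, coloc_fraction = 1, jitter_um = 0,
                            decoys = 0, seed = 2)
  # every A point has an exact copy in B
  expect_equal(nrow(cl$b$points), 20)
  reordered <- cl$b$points[cl$truth$pairs$b_index, ]
  expect_equal(unname(reordered),
               unname(cl$a$points[cl$truth$pairs$a_index, ]))

  empty <- generate_cell_cloud(15, coloc_fraction = 0, decoys = 0, seed = 2)
  expect_equal(nrow(empty$b$points), 0)

  cl2 <- generate_cell_cloud(40, coloc_fraction = 0.9, jitter_um = 1,
                             decoys = 10, seed = 3)
  expect_equal(nrow(cl2$truth$pairs), round(0.9 * 40))
  d <- sqrt(rowSums((cl2$a$points[cl2$truth$pairs$a_index, ] -
                       cl2$b$points[cl2$truth$pairs$b_index, ])^2))
  expect_true(all(d <= 1))
  expect_error(generate_cell_cloud(10, 0.5, jitter_um = -1), "jitter")
  expect_error(generate_cell_cloud(10, 1.5), "coloc_fraction")
})

test_that("Ct tables encode the programmed transcript fraction", {
  ct <- generate_ct_table(0.5, replicate_sd = 0, n_bio = 3, seed = 1)
  expect_equal(delta_delta_ct(ct)$percent, 50)
  ct1 <- generate_ct_table(1, replicate_sd = 0, n_bio = 3, seed = 1)
  expect_equal(delta_delta_ct(ct1)$percent, 100)
  expect_error(generate_ct_table(0), "true_fraction")
  # reference-gene rows share one mean across genotypes (noiseless)
  ref <- ct$ct[ct$gene == "reference"]
  expect_equal(length(unique(ref)), 1L)
})

test_that("noisy Ct tables recover the fraction within Monte-Carlo error", {
  pcts <- vapply(1:20, function(s) {
    delta_delta_ct(generate_ct_table(0.25, replicate_sd = 0.1, n_bio = 5,
                                     seed = s))$percent
  }, numeric(1))
  se <- sd(pcts) / sqrt(length(pcts))
  expect_lt(abs(mean(pcts) - 25), 3 * se + 1e-9)
})

test_that("cross counts follow the enumerated survival probabilities", {
  cs <- cross_spec(c("FlpStop_ND", "Balancer"), c("Null", "Balancer"),
                   scored_class = c("FlpStop_ND", "Null"))
  big <- generate_cross_counts(cs, n = 30000, seed = 4)
  expect_equal(sum(big$count), 30000)
  expect_equal(big$count[big$expected_prob == 0], 0) # lethal class empty
  frac <- big$count / 30000
  expect_true(all(abs(frac - big$expected_prob) < 0.02))
  expect_identical(generate_cross_counts(cs, 300, seed = 9),
                   generate_cross_counts(cs, 300, seed = 9))

  # a lethal scored class yields structural zeros
  lethal <- cross_spec(c("FlpStop_D", "Balancer"), c("Null", "Balancer"),
                       lethal_genotypes = list(c("FlpStop_D", "Null")),
                       scored_class = c("FlpStop_D", "Null"))
  counts <- generate_cross_counts(lethal, n = 500, seed = 5)
  expect_equal(counts$count[counts$genotype == "FlpStop_D/Null"], 0)
})
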