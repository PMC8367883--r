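test_that("kinetics closed forms hit their anchors and asymptotes", {
  dec <- kinetics_model("decay_to_plateau", rate_k_per_s = 0.1,
                        plateau_pct = 8, lag_s = 2)
  expect_equal(ground_truth_percent(dec, 0), 100)       # within the lag
  expect_equal(ground_truth_percent(dec, 2), 100)
  expect_equal(ground_truth_percent(dec, 1e6), 8)       # asymptote
  dec0 <- kinetics_model("decay_to_plateau", rate_k_per_s = 0.1, plateau_pct = 8)
  expect_equal(ground_truth_percent(dec0, 10), 8 + 92 * exp(-1))  # 41.8449
  expect_equal(ground_truth_percent(dec0, 10), 41.844909, tolerance = 1e-6)

  sw <- kinetics_model("swelling", rate_k_per_s = 0.05, swell_amplitude_pct = 25)
  expect_equal(ground_truth_percent(sw, 0), 100)
  expect_equal(ground_truth_percent(sw, 1e6), 125)
  expect_true(all(diff(ground_truth_percent(sw, 0:100)) >= 0))

  bi <- kinetics_model("biphasic", rate_k_per_s = 0.3, plateau_pct = 5,
                       tail_slope_pct_per_s = 0.1)
  v <- ground_truth_percent(bi, seq(0, 300, by = 0.5))
  expect_true(all(diff(v) <= 1e-9))     # monotone non-increasing
  expect_gte(min(v), 5)                 # floored at the plateau
  expect_equal(v[length(v)], 5)
})

test_that("rendering is deterministic and replicates differ only in noise", {
  cfg <- small_sim_config(duration_s = 2, noise_sd = 2, n_replicates = 2L)
  a <- generate_assay(cfg)
  b <- generate_assay(cfg)
  expect_identical(a$replicates[[1]]$frames, b$replicates[[1]]$frames)
  expect_identical(a$background$frames, b$background$frames)
  expect_identical(a$ground_truth, b$ground_truth)
  # distinct noise realizations, shared ground truth
  expect_false(identical(a$replicates[[1]]$frames, a$replicates[[2]]$frames))
})

test_that("the noiseless background phase is exactly flat", {
  cfg <- small_sim_config(duration_s = 1)
  bg <- render_sequence(cfg, "background")
  expect_true(all(vapply(bg$frames,
                         function(f) all(f == cfg$background_intensity),
                         logical(1))))
})

test_that("noiseless end-to-end analysis reproduces the ground truth", {
  cfg <- small_sim_config(duration_s = 20,
                          kinetics = kinetics_model("decay_to_plateau",
                                                    rate_k_per_s = 0.25,
                                                    plateau_pct = 8))
  b <- generate_assay(cfg)
  refs <- measure_references(b$background, b$tablet_only, b$roi)
  p <- build_profile(mgv_series(b$replicates[[1]], b$roi), refs)
  expect_lt(max(abs(p$percent_remaining - b$ground_truth$percent_remaining)),
            0.5)
})

test_that("background MGV noise matches the pixel-averaging prediction", {
  # per-pixel sd sigma averaged over N pixels -> MGV sd sigma/sqrt(N), plus
  # 1/12 quantization variance per pixel from the 8-bit rounding
  cfg <- small_sim_config(duration_s = 30, noise_sd = 2)
  bg <- render_sequence(cfg, "background")
  n_px <- prod(cfg$frame_size_px)
  predicted <- sqrt((cfg$noise_sd^2 + 1 / 12) / n_px)
  observed <- stats::sd(mgv_series(bg, roi_rect(0, 0, 64, 64))$values)
  expect_equal(observed, predicted, tolerance = 0.2)
})

test_that("swollen discs that would leave the frame are rejected", {
  expect_error(
    simulation_config(frame_size_px = c(64L, 64L), tablet_radius_px = 28,
                      kinetics = kinetics_model("swelling", rate_k_per_s = 0.1,
                                                swell_amplitude_pct = 35)),
    "geometry overflow", class = "dida_config_error")
  expect_error(simulation_config(tablet_intensity = 30,
                                 background_intensity = 30),
               class = "dida_config_error")
})

test_that("expected_category mirrors the classifier's reading of the kinetics", {
  swell <- small_sim_config(kinetics = kinetics_model("swelling",
                                                      rate_k_per_s = 0.1,
                                                      swell_amplitude_pct = 25),
                            duration_s = 60)
  expect_identical(expected_category(swell), "swelling")
  fast <- small_sim_config(kinetics = kinetics_model("decay_to_plateau",
                                                     rate_k_per_s = 0.2),
                           duration_s = 60)
  expect_identical(expected_category(fast), "fast")
  part <- small_sim_config(kinetics = kinetics_model("decay_to_plateau",
                                                     rate_k_per_s = 0.2,
                                                     plateau_pct = 15),
                           duration_s = 60)
  expect_identical(expected_category(part), "partial")
})
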