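test_that("flat MGV series map to flat 100% and 0% profiles", {
  refs <- simple_refs()
  full <- refs$mgv_background + refs$mgv_tablet_full
  p100 <- build_profile(mgv_series(const_frames(full), roi_rect(0, 0, 8, 8)),
                        refs)
  expect_true(all(p100$percent_remaining == 100))
  p0 <- build_profile(mgv_series(const_frames(refs$mgv_background),
                                 roi_rect(0, 0, 8, 8)), refs)
  expect_true(all(p0$percent_remaining == 0))
  expect_false(p0$smoothed)
})

test_that("profiles track the simulator ground truth within its noise envelope", {
  cfg <- small_sim_config(duration_s = 15, noise_sd = 2,
                          kinetics = kinetics_model("decay_to_plateau",
                                                    rate_k_per_s = 0.15,
                                                    plateau_pct = 10))
  b <- generate_assay(cfg)
  refs <- measure_references(b$background, b$tablet_only, b$roi)
  p <- build_profile(mgv_series(b$replicates[[1]], b$roi), refs)
  expect_lt(max(abs(p$percent_remaining - b$ground_truth$percent_remaining)), 1)
})

test_that("value_at interpolates linearly and rejects out-of-span times", {
  p <- profile_from_percent(c(100, 90, 80, 70))
  expect_identical(value_at(p, 2), p$percent_remaining[3])  # exact sample hit
  expect_equal(value_at(p, 0.5), 95)
  expect_error(value_at(p, 10), "outside recording span",
               class = "dida_range_error")
  expect_error(value_at(p, -1), "outside", class = "dida_range_error")
})

test_that("timepoint summaries use the sample sd across replicates", {
  reps <- lapply(c(20, 21, 22), function(v)
    profile_from_percent(rep(v, 40)))
  s <- summarize_timepoints(reps, c(10, 30))
  expect_equal(s$mean_percent, c(21, 21))
  expect_equal(s$sd_percent, c(1, 1))
  expect_equal(s$n, c(3L, 3L))

  # k copies of one profile: that profile's values, sd exactly 0
  p <- profile_from_percent(seq(100, 5, length.out = 200))
  for (k in c(1L, 4L)) {
    sk <- summarize_timepoints(rep(list(p), k), c(10, 30, 180))
    expect_equal(sk$mean_percent,
                 vapply(c(10, 30, 180), value_at, numeric(1), profile = p))
    expect_equal(sk$sd_percent, c(0, 0, 0))
  }
})

test_that("a replicate too short for a timepoint is named in the error", {
  long <- profile_from_percent(rep(50, 200))
  short <- build_profile(
    structure(list(times_s = 0:20,
                   values = rep(simple_refs()$mgv_background, 21),
                   roi_ref = "fixture"), class = "dida_mgv_series"),
    simple_refs(), replicate_id = "replicate_2")
  expect_error(summarize_timepoints(list(long, short), c(10, 30, 180)),
               "replicate_2", class = "dida_range_error")
})

test_that("optional smoothing is centered and recorded in metadata", {
  set.seed(5)
  pct <- 50 + rnorm(100)
  p <- profile_from_percent(pct)
  refs <- simple_refs()
  mgv <- structure(list(times_s = 0:99,
                        values = refs$mgv_background +
                          refs$mgv_tablet_full * pct / 100,
                        roi_ref = "fixture"), class = "dida_mgv_series")
  sm <- build_profile(mgv, refs, smoothing_window_s = 5)
  expect_true(sm$smoothed)
  expect_equal(sm$window_s, 5)
  # interior point: plain centered mean over the 5-sample window
  expect_equal(sm$percent_remaining[50], mean(pct[48:52]))
  expect_lt(stats::sd(sm$percent_remaining), stats::sd(p$percent_remaining))
  expect_error(build_profile(mgv, refs, smoothing_window_s = -1),
               class = "dida_config_error")
})

test_that("noise floor estimates background variability in percent units", {
  expect_identical(estimate_noise_floor(rep(0, 50)), 0)
  drift <- seq(0, 2, length.out = 60)
  expect_equal(estimate_noise_floor(drift), stats::sd(drift))
  # seeded pipeline: floor equals the sd of the background % series
  cfg <- small_sim_config(duration_s = 8, noise_sd = 3)
  b <- generate_assay(cfg)
  refs <- measure_references(b$background, b$tablet_only, b$roi)
  bg_pct <- percent_remaining(mgv_series(b$background, b$roi)$values, refs)
  expect_equal(estimate_noise_floor(bg_pct), stats::sd(bg_pct))
  expect_gt(estimate_noise_floor(bg_pct), 0)
})
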