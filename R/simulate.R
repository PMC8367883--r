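# Synthetic assay recordings with known ground truth. The simulator renders
# the optical structure of the assay -- a bright disc-shaped tablet on a
# near-black vessel, imaged from above at a fixed frame rate -- under
# closed-form disintegration kinetics, so every pipeline stage can be
# validated without laboratory recordings.
#
# The optical model is a linear MGV-mass proxy: the ideal (noise-free) ROI
# mean grey value at time t is
#   background + (tablet - background) * R(t) / 100,
# where R(t) is the ground-truth % remaining. Disintegration is rendered as
# disc-area shrinkage (radius proportional to sqrt(R/100), matching the
# shrinking footprint seen in real recordings) and swelling as disc-area
# growth at constant intensity. A small per-frame intensity correction on the
# anti-aliased disc edge makes the ideal ROI-MGV track R(t) exactly, so the
# only end-to-end error sources are sensor noise and 8-bit quantization.

#' Disintegration kinetics model
#'
#' Closed-form ground-truth curves for % tablet remaining, all starting at
#' 100% and held there during an optional lag before medium contact
#' (Delta = t - lag_s below):
#' \describe{
#'   \item{decay_to_plateau}{`R = plateau + (100 - plateau) * exp(-k * Delta)`.
#'     `plateau_pct = 0` is complete disintegration; a positive plateau models
#'     incomplete disintegration where residue remains.}
#'   \item{swelling}{`R = 100 + A * (1 - exp(-k * Delta))` with asymptotic
#'     excess `A = swell_amplitude_pct` over the intact tablet.}
#'   \item{biphasic}{fast exponential phase with a slow linear tail, floored
#'     at the plateau:
#'     `R = max(plateau, plateau + (100 - plateau) * exp(-k * Delta)
#'     - tail_slope * Delta)`.}
#' }
#'
#' @param model One of `"decay_to_plateau"`, `"swelling"`, `"biphasic"`.
#' @param rate_k_per_s First-order rate constant k (1/s), > 0.
#' @param plateau_pct Remaining fraction asymptote (%), in [0, 100).
#' @param swell_amplitude_pct Asymptotic excess over 100% (swelling model).
#' @param lag_s Seconds before medium contact (R = 100 until then).
#' @param tail_slope_pct_per_s Linear tail slope (biphasic model), >= 0.
#' @return A `dida_kinetics` list.
#' @export
kinetics_model <- function(model = c("decay_to_plateau", "swelling", "biphasic"),
                           rate_k_per_s, plateau_pct = 0,
                           swell_amplitude_pct = 0, lag_s = 0,
                           tail_slope_pct_per_s = 0) {
  model <- match.arg(model)
  if (!is_number(rate_k_per_s) || rate_k_per_s <= 0)
    stop_config("rate_k_per_s must be > 0")
  if (plateau_pct < 0 || plateau_pct >= 100)
    stop_config("plateau_pct must lie in [0, 100)")
  if (swell_amplitude_pct < 0) stop_config("swell_amplitude_pct must be >= 0")
  if (lag_s < 0) stop_config("lag_s must be >= 0")
  if (tail_slope_pct_per_s < 0) stop_config("tail_slope_pct_per_s must be >= 0")
  structure(list(model = model, rate_k_per_s = rate_k_per_s,
                 plateau_pct = plateau_pct,
                 swell_amplitude_pct = swell_amplitude_pct,
                 lag_s = lag_s,
                 tail_slope_pct_per_s = tail_slope_pct_per_s),
            class = "dida_kinetics")
}

#' Ground-truth percent remaining
#'
#' Evaluates the kinetics model's closed form at the given times.
#'
#' @param kinetics A [kinetics_model()].
#' @param t_s Time(s) in seconds, >= 0 (vectorized).
#' @return Percent remaining at each time.
#' @export
ground_truth_percent <- function(kinetics, t_s) {
  stopifnot(inherits(kinetics, "dida_kinetics"))
  d <- pmax(t_s - kinetics$lag_s, 0)
  k <- kinetics$rate_k_per_s
  switch(kinetics$model,
    decay_to_plateau = kinetics$plateau_pct +
      (100 - kinetics$plateau_pct) * exp(-k * d),
    swelling = 100 + kinetics$swell_amplitude_pct * (1 - exp(-k * d)),
    biphasic = pmax(kinetics$plateau_pct,
                    kinetics$plateau_pct +
                      (100 - kinetics$plateau_pct) * exp(-k * d) -
                      kinetics$tail_slope_pct_per_s * d))
}

#' Synthetic recording configuration
#'
#' Geometry, optics, noise and kinetics of one simulated assay. Defaults
#' mirror the real setup: a white tablet on a near-black vessel recorded at
#' 10 frames/s for 250 s, with mild sensor noise.
#'
#' @param frame_size_px `c(height, width)` in pixels.
#' @param tablet_center_px `c(row, col)` disc centre (defaults to the frame
#'   centre).
#' @param tablet_radius_px Intact-tablet disc radius in pixels.
#' @param tablet_intensity Disc grey level (must exceed the background).
#' @param background_intensity Vessel grey level.
#' @param noise_sd Per-pixel Gaussian sensor noise sd in grey levels.
#' @param frame_rate_hz Capture rate (default 10).
#' @param duration_s Recording length in seconds (default 250).
#' @param kinetics A [kinetics_model()].
#' @param seed Integer RNG seed; fixed seed gives bit-identical frames.
#' @param n_replicates Number of disintegration replicates (replicate r uses
#'   `seed + r`).
#' @return A `dida_sim_config` list.
#' @export
simulation_config <- function(frame_size_px = c(96L, 96L),
                              tablet_center_px = NULL,
                              tablet_radius_px = 30,
                              tablet_intensity = 220,
                              background_intensity = 20,
                              noise_sd = 2,
                              frame_rate_hz = 10,
                              duration_s = 250,
                              kinetics = kinetics_model("decay_to_plateau",
                                                        rate_k_per_s = 0.1,
                                                        plateau_pct = 8),
                              seed = 1L,
                              n_replicates = 3L) {
  if (is.null(tablet_center_px))
    tablet_center_px <- (frame_size_px + 1) / 2
  if (tablet_intensity <= background_intensity)
    stop_config("tablet_intensity must exceed background_intensity (white-on-black)")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (!is_count(n_replicates)) stop_config("n_replicates must be a positive integer")
  if (!is_number(duration_s) || duration_s <= 0)
    stop_config("duration_s must be positive")
  cfg <- structure(list(frame_size_px = as.numeric(frame_size_px),
                        tablet_center_px = as.numeric(tablet_center_px),
                        tablet_radius_px = as.numeric(tablet_radius_px),
                        tablet_intensity = as.numeric(tablet_intensity),
                        background_intensity = as.numeric(background_intensity),
                        noise_sd = as.numeric(noise_sd),
                        frame_rate_hz = as.numeric(frame_rate_hz),
                        duration_s = as.numeric(duration_s),
                        kinetics = kinetics,
                        seed = as.integer(seed),
                        n_replicates = as.integer(n_replicates)),
                   class = "dida_sim_config")
  check_geometry(cfg)
  cfg
}

# Maximum disc radius reached over the recording (swelling grows the disc).
max_radius <- function(cfg) {
  k <- cfg$kinetics
  rmax_pct <- if (k$model == "swelling") 100 + k$swell_amplitude_pct else 100
  cfg$tablet_radius_px * sqrt(rmax_pct / 100)
}

check_geometry <- function(cfg) {
  r <- max_radius(cfg)
  c0 <- cfg$tablet_center_px
  lim <- c(c0 - r - 0.5, cfg$frame_size_px - c0 - r + 0.5)
  if (any(lim < 0))
    stop_config(sprintf(
      "geometry overflow: disc of radius %.1f px (incl. swelling) does not fit the %dx%d frame",
      r, cfg$frame_size_px[1L], cfg$frame_size_px[2L]))
  invisible(cfg)
}

# Anti-aliased disc coverage: 1 inside, 0 outside, linear ramp across the
# one-pixel edge band. `dist` is the precomputed centre-distance matrix.
disc_coverage <- function(dist, radius) {
  if (radius <= 0) return(array(0, dim(dist)))
  pmin(pmax(radius + 0.5 - dist, 0), 1)
}

#' Render one phase of a synthetic assay
#'
#' The three phases mirror the assay's three companion recordings:
#' `background` (vessel + medium only), `tablet_only` (intact tablet, the
#' 100% reference) and `disintegration` (the test itself, disc area following
#' the kinetics). Per-pixel Gaussian noise is added, then frames are clipped
#' to [0, 255] and quantized to 8 bits -- the canonical intensity scale the
#' analysis pipeline consumes.
#'
#' @param config A [simulation_config()].
#' @param phase `"background"`, `"tablet_only"` or `"disintegration"`.
#' @param seed RNG seed for this rendering (defaults to `config$seed`).
#' @return A [frame_sequence()] of 8-bit quantized frames.
#' @export
render_sequence <- function(config,
                            phase = c("background", "tablet_only", "disintegration"),
                            seed = config$seed) {
  stopifnot(inherits(config, "dida_sim_config"))
  phase <- match.arg(phase)
  check_geometry(config)
  h <- config$frame_size_px[1L]; w <- config$frame_size_px[2L]
  n <- max(1L, round(config$duration_s * config$frame_rate_hz))
  times <- (seq_len(n) - 1) / config$frame_rate_hz
  dist <- sqrt(outer((seq_len(h) - config$tablet_center_px[1L])^2,
                     (seq_len(w) - config$tablet_center_px[2L])^2, `+`))
  bg <- config$background_intensity
  amp <- config$tablet_intensity - bg
  r0 <- config$tablet_radius_px
  cov0 <- disc_coverage(dist, r0)
  area0 <- sum(cov0)

  ideal_signal <- function(i) {
    # coverage array scaled so its total equals area0 * R(t)/100 exactly
    if (phase == "background") return(0)
    if (phase == "tablet_only") return(cov0)
    r_pct <- ground_truth_percent(config$kinetics, times[i])
    r_px <- r0 * sqrt(max(r_pct, 0) / 100)
    cv <- disc_coverage(dist, r_px)
    s <- sum(cv)
    if (s == 0) return(cv)
    cv * (area0 * r_pct / 100 / s)
  }

  frames <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      f <- bg + amp * ideal_signal(i)
      if (length(f) == 1L) f <- matrix(f, h, w)
      if (config$noise_sd > 0)
        f <- f + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
      m <- round(pmin(pmax(f, 0), 255))
      storage.mode(m) <- "integer"
      m
    })
  })
  frame_sequence(frames,
                 frame_rate_hz = config$frame_rate_hz,
                 timestamps_s = times,
                 bit_depth = 8L,
                 source_id = sprintf("sim:%s:seed%d", phase, as.integer(seed)))
}

#' Generate a full synthetic assay bundle
#'
#' Produces the background and intact-tablet reference recordings plus
#' `n_replicates` disintegration recordings (replicate r seeded with
#' `seed + r`, so noise realizations differ while the ground truth is
#' shared), together with the per-frame ground-truth profile and the ROI the
#' geometry implies (the full frame).
#'
#' @param config A [simulation_config()].
#' @return A `dida_assay_bundle`: `background`, `tablet_only`, `replicates`
#'   (list of frame sequences), `ground_truth` (data frame `time_s`,
#'   `percent_remaining`), `roi`, `config`.
#' @export
generate_assay <- function(config) {
  stopifnot(inherits(config, "dida_sim_config"))
  background <- render_sequence(config, "background", seed = config$seed)
  tablet_only <- render_sequence(config, "tablet_only", seed = config$seed)
  replicates <- lapply(seq_len(config$n_replicates), function(r) {
    render_sequence(config, "disintegration", seed = config$seed + r)
  })
  gt <- data.frame(
    time_s = background$timestamps_s,
    percent_remaining = ground_truth_percent(config$kinetics,
                                             background$timestamps_s))
  structure(list(background = background,
                 tablet_only = tablet_only,
                 replicates = replicates,
                 ground_truth = gt,
                 roi = roi_rect(0, 0, config$frame_size_px[2L],
                                config$frame_size_px[1L]),
                 config = config),
            class = "dida_assay_bundle")
}

#' Expected behaviour category of a simulation configuration
#'
#' The category the classifier should assign, derived from the kinetics
#' closed form (not from rendered frames); used as ground truth when scoring
#' classification accuracy.
#'
#' @param config A [simulation_config()].
#' @param thresholds A [dida_thresholds()] list.
#' @return A category string.
#' @export
expected_category <- function(config, thresholds = dida_thresholds()) {
  th <- do.call(dida_thresholds, thresholds)
  k <- config$kinetics
  t_end <- config$duration_s
  if (k$model == "swelling") {
    if (100 + k$swell_amplitude_pct >= th$swelling_threshold_pct)
      return("swelling")
    return("partial")
  }
  if (k$plateau_pct > th$completion_threshold_pct) return("partial")
  tt <- seq(0, t_end, by = 1 / config$frame_rate_hz)
  r <- ground_truth_percent(k, tt)
  below <- which(r <= th$completion_threshold_pct)
  if (length(below) == 0L) return("partial")
  ep <- tt[below[1L]]
  if (ep <= th$instant_limit_s) "instant"
  else if (ep <= th$fast_limit_s) "fast"
  else "prolonged"
}
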