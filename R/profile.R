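# Disintegration profiles: % tablet remaining vs time for one replicate, plus
# timepoint summaries across replicates and the background noise floor.

#' Assay condition labels
#'
#' Metadata describing the run (no physics is computed from these).
#'
#' @param temperature_label_c Medium temperature label in deg C (20-45 when given).
#' @param medium_volume_ml Medium volume in mL (> 0 when given).
#' @param medium_name Free text, e.g. "PBS pH 7".
#' @param formulation_name Free text.
#' @return A `dida_conditions` list.
#' @export
assay_conditions <- function(temperature_label_c = NA_real_,
                             medium_volume_ml = NA_real_,
                             medium_name = "", formulation_name = "") {
  if (!is.na(temperature_label_c) &&
      (temperature_label_c < 20 || temperature_label_c > 45))
    stop_config("temperature label outside the plausible 20-45 degC range")
  if (!is.na(medium_volume_ml) && medium_volume_ml <= 0)
    stop_config("medium volume must be positive")
  structure(list(temperature_label_c = temperature_label_c,
                 medium_volume_ml = medium_volume_ml,
                 medium_name = medium_name,
                 formulation_name = formulation_name),
            class = "dida_conditions")
}

#' Build a disintegration profile from an MGV series
#'
#' Converts each MGV sample to % tablet remaining against the measured
#' references; optionally applies a centered moving-average smoother whose
#' window (in seconds) is recorded in the profile metadata. Smoothing is off
#' by default and all validation runs unsmoothed.
#'
#' @param mgv A `dida_mgv_series`.
#' @param refs A `dida_refs`.
#' @param conditions Optional [assay_conditions()].
#' @param smoothing_window_s Centered moving-average window in seconds, or
#'   `NULL` for no smoothing.
#' @param replicate_id Replicate label.
#' @return A `dida_profile` with `times_s`, `percent_remaining`, `mgv`,
#'   `flags`, `replicate_id`, `conditions`, `smoothed`, `window_s`.
#' @export
build_profile <- function(mgv, refs, conditions = NULL,
                          smoothing_window_s = NULL, replicate_id = "r1") {
  stopifnot(inherits(mgv, "dida_mgv_series"))
  pct <- percent_remaining(mgv$values, refs)
  smoothed <- FALSE
  window_s <- NA_real_
  if (!is.null(smoothing_window_s)) {
    if (!is_number(smoothing_window_s) || smoothing_window_s <= 0)
      stop_config("smoothing window must be a positive number of seconds")
    dt <- mean(diff(mgv$times_s))
    half <- max(0L, floor(smoothing_window_s / dt / 2))
    pct <- moving_average(pct, half)
    smoothed <- TRUE
    window_s <- smoothing_window_s
  }
  flags <- character(length(pct))
  flags[pct < 0] <- "below_zero"
  flags[pct > 100] <- "above_100"
  structure(list(times_s = mgv$times_s,
                 percent_remaining = pct,
                 mgv = mgv$values,
                 flags = flags,
                 replicate_id = replicate_id,
                 conditions = conditions,
                 smoothed = smoothed,
                 window_s = window_s),
            class = "dida_profile")
}

# Centered moving average with window shrinking at the edges.
moving_average <- function(x, half) {
  if (half == 0L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @export
print.dida_profile <- function(x, ...) {
  cat(sprintf("<dida_profile> %s: %d samples over %.1f s, final %.1f%%%s\n",
              x$replicate_id, length(x$times_s),
              x$times_s[length(x$times_s)],
              x$percent_remaining[length(x$percent_remaining)],
              if (x$smoothed) sprintf(" (smoothed %gs)", x$window_s) else ""))
  invisible(x)
}

#' Read a profile at an arbitrary time
#'
#' Linear interpolation between the two bracketing samples; returns the stored
#' sample exactly when `t_s` coincides with a timestamp.
#'
#' @param profile A `dida_profile`.
#' @param t_s Time in seconds, within the recording span.
#' @return Percent remaining at `t_s`.
#' @export
value_at <- function(profile, t_s) {
  stopifnot(inherits(profile, "dida_profile"))
  tmax <- profile$times_s[length(profile$times_s)]
  if (!is_number(t_s) || t_s < profile$times_s[1L] || t_s > tmax)
    stop_range(sprintf(
      "time %.3f s outside recording span [%.3f, %.3f] of replicate '%s'",
      t_s, profile$times_s[1L], tmax, profile$replicate_id))
  hit <- which(profile$times_s == t_s)
  if (length(hit) > 0L) return(profile$percent_remaining[hit[1L]])
  stats::approx(profile$times_s, profile$percent_remaining, xout = t_s)$y
}

#' Summarize replicates at fixed timepoints
#'
#' Sample mean and sample standard deviation (n-1 denominator; 0 when n = 1)
#' of % remaining across replicates at each timepoint. The canonical
#' pharmacopoeial set is 10 s, 30 s and 180 s.
#'
#' @param profiles List of `dida_profile` replicates.
#' @param timepoints_s Numeric vector of timepoints in seconds.
#' @return Data frame with columns `timepoint_s`, `mean_percent`,
#'   `sd_percent`, `n`.
#' @export
summarize_timepoints <- function(profiles, timepoints_s = c(10, 30, 180)) {
  if (inherits(profiles, "dida_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop_input("no replicate profiles supplied")
  rows <- lapply(timepoints_s, function(tp) {
    vals <- vapply(profiles, value_at, numeric(1L), t_s = tp)
    data.frame(timepoint_s = tp,
               mean_percent = mean(vals),
               sd_percent = if (length(vals) > 1L) stats::sd(vals) else 0,
               n = length(vals))
  })
  do.call(rbind, rows)
}

#' Estimate the background noise floor in percent units
#'
#' Standard deviation of a background-only recording pushed through the same
#' normalization pipeline. Profile changes smaller than about three times this
#' floor should not be read as disintegration signal.
#'
#' @param background_profile_values Numeric vector of % remaining values from
#'   a background-only recording.
#' @return One standard deviation, in percentage points.
#' @export
estimate_noise_floor <- function(background_profile_values) {
  v <- as.numeric(background_profile_values)
  if (length(v) < 2L) return(0)
  stats::sd(v)
}
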