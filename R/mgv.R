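# Mean grey values and the 0%/100% normalization scale. The MGV over a fixed
# ROI is the optical proxy for the amount of white tablet material visible;
# the background recording anchors 0% and the intact-tablet recording 100%.

#' Mean grey value of one frame over an ROI
#'
#' Arithmetic mean of the pixel intensities inside the region of interest.
#'
#' @param frame Grayscale matrix (0-255).
#' @param roi A `dida_roi`.
#' @return Mean grey value (grey levels).
#' @export
compute_mgv <- function(frame, roi) {
  mask <- roi_to_mask(roi, dim(frame))
  if (!any(mask)) stop_config("ROI selects no pixels")
  mean(frame[mask])
}

#' MGV time series of a frame sequence
#'
#' One MGV per frame, in frame order, with the sequence's timestamps.
#'
#' @param seq A [frame_sequence()].
#' @param roi A `dida_roi`, held fixed across all frames.
#' @return A `dida_mgv_series`: list with `times_s`, `values`, `roi_ref`.
#' @export
mgv_series <- function(seq, roi) {
  stopifnot(inherits(seq, "dida_frames"))
  mask <- roi_to_mask(roi, frame_dim(seq))
  if (!any(mask)) stop_config("ROI selects no pixels")
  vals <- vapply(seq$frames, function(f) mean(f[mask]), numeric(1L))
  structure(list(times_s = seq$timestamps_s, values = vals,
                 roi_ref = roi_label(roi)),
            class = "dida_mgv_series")
}

#' Measure the assay reference levels
#'
#' Establishes the normalization scale from two companion recordings: the
#' medium-only background (0% anchor and noise floor) and the intact tablet
#' (100% anchor). Both anchors are means over their whole recordings, which
#' suppresses sensor noise relative to single-frame anchors. The intact-tablet
#' reference is background-corrected so both anchors live on one scale.
#'
#' @param background_seq Frame sequence of vessel + medium only.
#' @param tablet_seq Frame sequence of the intact tablet (no medium motion).
#' @param roi The fixed `dida_roi` used for the whole assay.
#' @param contrast_tol Minimum background-corrected intact-tablet MGV (grey
#'   levels) below which the assay is rejected as having no usable contrast.
#' @return A `dida_refs` object with fields `mgv_background`,
#'   `mgv_background_sd`, `mgv_tablet_full`, `n_frames_background`,
#'   `n_frames_reference`.
#' @export
measure_references <- function(background_seq, tablet_seq, roi,
                               contrast_tol = 5) {
  stopifnot(inherits(background_seq, "dida_frames"),
            inherits(tablet_seq, "dida_frames"))
  if (!identical(frame_dim(background_seq), frame_dim(tablet_seq)))
    stop_format("background and tablet recordings have different frame geometry")
  bg <- mgv_series(background_seq, roi)
  tb <- mgv_series(tablet_seq, roi)
  mgv_bg <- mean(bg$values)
  sd_bg <- if (length(bg$values) > 1L) stats::sd(bg$values) else 0
  mgv_full <- mean(tb$values) - mgv_bg
  if (mgv_full <= contrast_tol)
    dida_stop(sprintf(
      "no contrast: intact tablet reads %.3f grey levels above background (tolerance %.3f)",
      mgv_full, contrast_tol), "dida_contrast_error")
  structure(list(mgv_background = mgv_bg,
                 mgv_background_sd = sd_bg,
                 mgv_tablet_full = mgv_full,
                 n_frames_background = length(bg$values),
                 n_frames_reference = length(tb$values)),
            class = "dida_refs")
}

#' Percent tablet remaining for an MGV value
#'
#' `100 * (mgv_t - mgv_background) / mgv_tablet_full`. Values are deliberately
#' not clipped: readings above 100% indicate swelling of the dosage form, and
#' slightly negative readings reflect the sensor noise floor; both carry
#' information and are flagged downstream rather than discarded.
#'
#' @param mgv_t MGV value(s) in grey levels (vectorized).
#' @param refs A `dida_refs` from [measure_references()].
#' @return Percent tablet remaining (same length as `mgv_t`).
#' @export
percent_remaining <- function(mgv_t, refs) {
  stopifnot(inherits(refs, "dida_refs"))
  100 * (mgv_t - refs$mgv_background) / refs$mgv_tablet_full
}
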