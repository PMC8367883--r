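# On-disk form of a synthetic assay bundle: PNG frame stacks per phase, a
# JSON manifest carrying every parameter (including the seed), the implied
# ROI, and the ground-truth profile as CSV. The layout is consumable directly
# by load_frames(), so simulated bundles exercise the same reading path as
# real recordings.

#' Write an assay bundle to disk
#'
#' Creates `background/`, `tablet_only/` and `replicate_<r>/` PNG frame
#' stacks plus `manifest.json`, `roi.json` and `ground_truth.csv` under
#' `dir`.
#'
#' @param bundle A `dida_assay_bundle` from [generate_assay()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assay_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "dida_assay_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  phases <- c(list(background = bundle$background,
                   tablet_only = bundle$tablet_only),
              stats::setNames(bundle$replicates,
                              paste0("replicate_", seq_along(bundle$replicates))))
  for (nm in names(phases)) {
    sub <- file.path(dir, nm)
    dir.create(sub, showWarnings = FALSE)
    fs <- phases[[nm]]$frames
    for (i in seq_along(fs))
      png::writePNG(fs[[i]] / 255, file.path(sub, sprintf("frame_%05d.png", i)))
  }
  cfg <- bundle$config
  manifest <- list(
    format = "dida_assay_bundle",
    frame_rate_hz = cfg$frame_rate_hz,
    duration_s = cfg$duration_s,
    frame_size_px = cfg$frame_size_px,
    tablet_center_px = cfg$tablet_center_px,
    tablet_radius_px = cfg$tablet_radius_px,
    tablet_intensity = cfg$tablet_intensity,
    background_intensity = cfg$background_intensity,
    noise_sd = cfg$noise_sd,
    seed = cfg$seed,
    n_replicates = cfg$n_replicates,
    kinetics = unclass(cfg$kinetics),
    phases = as.list(stats::setNames(names(phases), names(phases)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(x0 = bundle$roi$x0, y0 = bundle$roi$y0,
                            x1 = bundle$roi$x1, y1 = bundle$roi$y1),
                       file.path(dir, "roi.json"), auto_unbox = TRUE)
  utils::write.csv(bundle$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read an assay bundle manifest
#'
#' @param dir Bundle directory written by [write_assay_bundle()].
#' @return The manifest as a list.
#' @export
read_bundle_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path))
    stop_input(sprintf("no manifest.json in '%s': not an assay bundle", dir))
  m <- jsonlite::fromJSON(path)
  if (!identical(m$format, "dida_assay_bundle"))
    stop_format(sprintf("'%s' is not a dida assay bundle manifest", path))
  m
}

#' Reconstruct the kinetics model recorded in a bundle manifest
#'
#' @param manifest List from [read_bundle_manifest()].
#' @return A [kinetics_model()].
#' @export
manifest_kinetics <- function(manifest) {
  k <- manifest$kinetics
  kinetics_model(model = k$model, rate_k_per_s = k$rate_k_per_s,
                 plateau_pct = k$plateau_pct,
                 swell_amplitude_pct = k$swell_amplitude_pct,
                 lag_s = k$lag_s,
                 tail_slope_pct_per_s = k$tail_slope_pct_per_s)
}

#' Write a disintegration profile as CSV
#'
#' Columns `time_s`, `mgv`, `percent_remaining`, `flags`.
#'
#' @param profile A `dida_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "dida_profile"))
  utils::write.csv(data.frame(time_s = profile$times_s,
                              mgv = profile$mgv,
                              percent_remaining = profile$percent_remaining,
                              flags = profile$flags),
                   path, row.names = FALSE)
  invisible(path)
}
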