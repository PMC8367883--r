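# Shared fixtures: small in-code recordings and simulation presets.

# A tiny constant-frame sequence.
const_frames <- function(value, n = 3L, dim = c(8L, 8L), rate = 10) {
  frame_sequence(replicate(n, matrix(value, dim[1L], dim[2L]),
                           simplify = FALSE),
                 frame_rate_hz = rate)
}

# References with background 20 and full-tablet MGV 100 grey levels.
simple_refs <- function(bg = 20, tablet = 120) {
  measure_references(const_frames(bg), const_frames(tablet),
                     roi_rect(0, 0, 8, 8))
}

# A profile straight from a vector of % remaining values (1 Hz sampling),
# routed through MGV space so it exercises the real normalization path.
profile_from_percent <- function(pct, refs = simple_refs(), rate = 1) {
  mgv <- structure(list(
    times_s = (seq_along(pct) - 1) / rate,
    values = refs$mgv_background + refs$mgv_tablet_full * pct / 100,
    roi_ref = "fixture"), class = "dida_mgv_series")
  build_profile(mgv, refs)
}

# Small, fast simulation preset (64 px frame, 20 px disc).
small_sim_config <- function(...) {
  args <- list(frame_size_px = c(64L, 64L), tablet_radius_px = 18,
               duration_s = 10, noise_sd = 0, n_replicates = 1L, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# Write a uniform-intensity PNG frame stack; returns the directory.
write_uniform_stack <- function(values, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  for (i in seq_along(values))
    png::writePNG(matrix(values[i] / 255, 6, 6),
                  file.path(dir, sprintf("f_%04d.png", i)))
  dir
}
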