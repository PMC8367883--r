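# Frame sequences: the raw observable of the assay. Frames are grayscale
# matrices on the canonical 0-255 scale; time base is frame_index / frame_rate
# (0-based, first frame at t = 0 s). Container-embedded timestamps are never
# consulted, so a rerun on the same files is bit-identical.

#' Construct a frame sequence
#'
#' An ordered stack of grayscale frames with timestamps, the input to all MGV
#' computations. Frames must share one geometry and lie on the canonical
#' 0-255 intensity scale.
#'
#' @param frames List of numeric matrices (grayscale, 0-255), all the same
#'   height x width.
#' @param frame_rate_hz Effective capture rate in frames per second.
#' @param timestamps_s Optional numeric vector of per-frame times in seconds,
#'   strictly increasing. Defaults to `(0:(n-1)) / frame_rate_hz`.
#' @param bit_depth Source bit depth (8 or 16); metadata only, frames are
#'   already canonicalized.
#' @param source_id Free-text provenance label.
#' @return A `dida_frames` object.
#' @export
frame_sequence <- function(frames, frame_rate_hz, timestamps_s = NULL,
                           bit_depth = 8L, source_id = "") {
  if (!is.list(frames) || length(frames) == 0L)
    stop_input("empty recording: no frames supplied")
  if (!is_number(frame_rate_hz) || frame_rate_hz <= 0)
    stop_config("frame_rate_hz must be a positive number")
  d <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || !identical(dim(f), d))
      stop_format(sprintf("frame %d does not match geometry %dx%d", i, d[1L], d[2L]))
    r <- range(f)
    if (r[1L] < 0 || r[2L] > 255)
      stop_format(sprintf("frame %d has intensities outside [0, 255]", i))
  }
  n <- length(frames)
  if (is.null(timestamps_s)) timestamps_s <- (seq_len(n) - 1) / frame_rate_hz
  if (length(timestamps_s) != n || any(diff(timestamps_s) <= 0))
    stop_format("timestamps must match frame count and be strictly increasing")
  structure(list(
    frames = frames,
    timestamps_s = as.numeric(timestamps_s),
    frame_rate_hz = as.numeric(frame_rate_hz),
    bit_depth = as.integer(bit_depth),
    source_id = as.character(source_id)
  ), class = "dida_frames")
}

#' @export
length.dida_frames <- function(x) length(x$frames)

#' @export
print.dida_frames <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<dida_frames> %d frames %dx%d px, %.3g fps, %.1f s [%s]\n",
              length(x$frames), d[1L], d[2L], x$frame_rate_hz,
              x$timestamps_s[length(x$timestamps_s)], x$source_id))
  invisible(x)
}

frame_dim <- function(seq) dim(seq$frames[[1L]])

VIDEO_EXTENSIONS <- c("mp4", "avi", "mov", "mkv", "wmv", "webm")

#' Load a frame stack from image files
#'
#' Reads an ordered PNG/TIFF frame stack (a directory, sorted
#' lexicographically, or an explicit file vector in order) and canonicalizes
#' each frame to grayscale 0-255. Video containers are not decoded: extract
#' frames to images first (the assay's acquisition step already does this).
#'
#' @param source Directory containing the frames, or character vector of image
#'   file paths in frame order.
#' @param frame_rate_hz Nominal capture rate of the source recording (Hz).
#' @param decimation Keep every k-th frame (k = 1 keeps all). Timestamps are
#'   derived from the original frame index, so decimation by k yields a
#'   subsequence of the undecimated time base.
#' @return A [frame_sequence()].
#' @export
load_frames <- function(source, frame_rate_hz, decimation = 1L) {
  if (!is.character(source) || length(source) == 0L)
    stop_input("source must be a directory or a character vector of image files")
  if (!is_count(decimation)) stop_config("decimation must be a positive integer")
  if (length(source) == 1L && dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop_input(sprintf("empty recording: no PNG/TIFF frames in '%s'", source))
    src_label <- source
  } else {
    files <- source
    src_label <- dirname(files[1L])
  }
  ext <- tolower(tools::file_ext(files))
  if (any(ext %in% VIDEO_EXTENSIONS))
    stop_input(sprintf(
      "'%s' is a video container; extract frames to PNG/TIFF first",
      files[which(ext %in% VIDEO_EXTENSIONS)[1L]]))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L)
    stop_input(sprintf("cannot read frame file '%s'", missing[1L]))
  keep <- seq(1L, length(files), by = decimation)
  frames <- lapply(files[keep], read_frame_file)
  frame_sequence(frames,
                 frame_rate_hz = frame_rate_hz / decimation,
                 timestamps_s = (keep - 1L) / frame_rate_hz,
                 bit_depth = 8L,
                 source_id = src_label)
}

# Read one PNG/TIFF file to a canonical grayscale matrix. Both readers return
# intensities normalized to [0, 1] regardless of source depth.
read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           stop_format(sprintf("unsupported frame format '.%s' (%s)", ext, path))),
    error = function(e) {
      if (inherits(e, "dida_error")) stop(e)
      stop_input(sprintf("corrupt or unreadable frame file '%s'", path))
    })
  if (length(dim(arr)) == 3L && dim(arr)[3L] == 4L) arr <- arr[, , 1:3]  # drop alpha
  to_grayscale(arr * 255, bit_depth = 8L)
}

#' Canonicalize a frame to grayscale 0-255
#'
#' Three-channel frames are combined with ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114); 16-bit intensities are rescaled by 255/65535.
#' Applying the function to an already canonical frame is a no-op, so
#' canonicalization is idempotent.
#'
#' @param frame Numeric matrix (grayscale) or h x w x 3 array, on the native
#'   scale of `bit_depth`.
#' @param bit_depth Source bit depth, 8 or 16.
#' @return Numeric matrix with values in [0, 255].
#' @export
to_grayscale <- function(frame, bit_depth = 8L) {
  if (!bit_depth %in% c(8L, 16L))
    stop_format("bit_depth must be 8 or 16")
  nd <- length(dim(frame))
  if (nd == 3L) {
    nc <- dim(frame)[3L]
    if (nc == 1L) {
      frame <- frame[, , 1L]
    } else if (nc == 3L) {
      frame <- 0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L]
    } else {
      stop_format(sprintf("unsupported channel count: %d (expected 1 or 3)", nc))
    }
  } else if (nd != 2L && !is.matrix(frame)) {
    stop_format("frame must be a 2-D matrix or a 3-channel array")
  }
  if (bit_depth == 16L) frame <- frame * (255 / 65535)
  frame <- pmin(pmax(frame, 0), 255)
  if (!is.matrix(frame)) frame <- as.matrix(frame)
  frame
}
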