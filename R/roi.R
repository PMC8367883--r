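# Region of interest: the fixed pixel area covering the formulation. One ROI
# is applied unchanged to every frame of an assay.

#' Rectangular region of interest
#'
#' Pixel coordinates are 0-based and half-open, as in the on-disk JSON form
#' `{x0, y0, x1, y1}`: x indexes columns, y indexes rows, and the rectangle
#' covers columns `x0 .. x1-1` and rows `y0 .. y1-1`.
#'
#' @param x0,y0 Top-left corner (inclusive, 0-based).
#' @param x1,y1 Bottom-right corner (exclusive).
#' @return A `dida_roi` object.
#' @export
roi_rect <- function(x0, y0, x1, y1) {
  for (v in list(x0, y0, x1, y1))
    if (!is_number(v) || v < 0 || v != round(v))
      stop_config("ROI corners must be non-negative integers")
  if (x1 <= x0 || y1 <= y0)
    stop_config("ROI rectangle is empty: require x1 > x0 and y1 > y0")
  structure(list(type = "rect",
                 x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "dida_roi")
}

#' Mask region of interest
#'
#' @param mask Logical matrix with the frame's geometry; `TRUE` pixels belong
#'   to the ROI. At least one pixel must be selected.
#' @return A `dida_roi` object.
#' @export
roi_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_config("ROI mask must be a logical matrix")
  if (!any(mask)) stop_config("ROI mask selects no pixels")
  structure(list(type = "mask", mask = mask), class = "dida_roi")
}

#' Read an ROI from JSON
#'
#' Accepts the rectangle form `{"x0":..,"y0":..,"x1":..,"y1":..}` (0-based,
#' half-open pixel coordinates).
#'
#' @param path Path to a JSON file.
#' @return A `dida_roi` object.
#' @export
roi_from_json <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("ROI file '%s' not found", path))
  j <- jsonlite::fromJSON(path)
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(j)))
    stop_format(sprintf("ROI JSON '%s' must contain fields x0, y0, x1, y1", path))
  roi_rect(j$x0, j$y0, j$x1, j$y1)
}

# Materialize the ROI as a logical mask for a given frame geometry.
roi_to_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "dida_roi"))
  if (roi$type == "mask") {
    if (!identical(dim(roi$mask), as.integer(dim)))
      stop_config(sprintf("ROI mask is %dx%d but frames are %dx%d",
                          nrow(roi$mask), ncol(roi$mask), dim[1L], dim[2L]))
    return(roi$mask)
  }
  if (roi$y1 > dim[1L] || roi$x1 > dim[2L])
    stop_config(sprintf("ROI rectangle exceeds the %dx%d frame", dim[1L], dim[2L]))
  m <- matrix(FALSE, dim[1L], dim[2L])
  m[(roi$y0 + 1L):roi$y1, (roi$x0 + 1L):roi$x1] <- TRUE
  m
}

#' Number of pixels an ROI selects in a given frame geometry
#'
#' @param roi A `dida_roi`.
#' @param dim Frame dimensions `c(height, width)`.
#' @return Integer pixel count.
#' @export
roi_pixel_count <- function(roi, dim) sum(roi_to_mask(roi, dim))

roi_label <- function(roi) {
  if (roi$type == "rect")
    sprintf("rect[%d,%d,%d,%d]", roi$x0, roi$y0, roi$x1, roi$y1)
  else sprintf("mask[%dpx]", sum(roi$mask))
}
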