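#' Normalized trench-profile frame geometry
#'
#' The analysis frame is a fixed window on the profile wall: 60 cm deep by
#' 60 cm wide at 25.6 pixels per cm (256 dots per 10 cm), i.e. 1536 x 1536
#' pixels. Row 0 is the soil surface and depth increases with the row
#' index; horizontal position is measured as distance from the hill
#' column (the planting position, by default the image center).
#'
#' @param resolution_px_per_cm Pixels per centimetre (default 25.6).
#' @param width_cm,depth_cm Physical extent of the frame in cm.
#' @param hill_column_px 0-based column index of the hill (planting
#'   position). Defaults to the central column, `width_px / 2`.
#' @return A `frame_spec` object with derived pixel dimensions
#'   `width_px` and `depth_px`.
#' @examples
#' fr <- frame_spec()
#' fr$depth_px  # 1536
#' @export
frame_spec <- function(resolution_px_per_cm = 25.6, width_cm = 60,
                       depth_cm = 60, hill_column_px = NULL) {
  stopifnot(resolution_px_per_cm > 0, width_cm > 0, depth_cm > 0)
  wpx <- resolution_px_per_cm * width_cm
  dpx <- resolution_px_per_cm * depth_cm
  if (abs(wpx - round(wpx)) > 1e-8 || abs(dpx - round(dpx)) > 1e-8)
    stop("resolution x extent must give a whole number of pixels")
  wpx <- as.integer(round(wpx)); dpx <- as.integer(round(dpx))
  if (is.null(hill_column_px)) hill_column_px <- wpx %/% 2L
  hill_column_px <- as.integer(hill_column_px)
  if (hill_column_px < 0L || hill_column_px >= wpx)
    stop("hill_column_px must lie inside the frame (0-based)")
  structure(list(resolution_px_per_cm = resolution_px_per_cm,
                 width_cm = width_cm, depth_cm = depth_cm,
                 width_px = wpx, depth_px = dpx,
                 hill_column_px = hill_column_px),
            class = "frame_spec")
}

#' Per-image normalization annotation
#'
#' Describes how a raw field photograph maps into the normalized frame:
#' a counterclockwise rotation correction, the raw scale read off the
#' in-image scale bar, and the crop origin (the ground-surface /
#' left-edge corner of the frame window, in 0-based pixel coordinates of
#' the rotated raw image). Images are normalized manually in the field
#' workflow, so the annotation is supplied per image (see
#' [read_annotations()]) rather than detected automatically.
#'
#' @param scale_px_per_cm Raw image resolution in px/cm (from the scale
#'   bar); must be positive.
#' @param rotation_deg Counterclockwise rotation (degrees) that levels
#'   the soil surface.
#' @param crop_row,crop_col 0-based pixel coordinates, in the rotated
#'   raw image, of the top-left corner of the frame window.
#' @param hill_col_raw Optional 0-based hill column in the rotated raw
#'   image; only used for bookkeeping.
#' @return A `frame_annotation` object.
#' @export
frame_annotation <- function(scale_px_per_cm, rotation_deg = 0,
                             crop_row = 0, crop_col = 0, hill_col_raw = NA) {
  if (!is.numeric(scale_px_per_cm) || scale_px_per_cm <= 0)
    stop("scale_px_per_cm must be a positive number")
  structure(list(scale_px_per_cm = scale_px_per_cm,
                 rotation_deg = rotation_deg,
                 crop_row = crop_row, crop_col = crop_col,
                 hill_col_raw = hill_col_raw),
            class = "frame_annotation")
}

#' Construct a trench image in the normalized frame
#'
#' @param pixels Numeric array `depth_px x width_px x 3` with values in
#'   \[0, 1\].
#' @param frame A [frame_spec()].
#' @return A `trench_image` object.
#' @export
trench_image <- function(pixels, frame = frame_spec()) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stop("expected 3 channels")
  if (d[1] != frame$depth_px || d[2] != frame$width_px)
    stop(sprintf("pixels are %dx%d but the frame is %dx%d",
                 d[1], d[2], frame$depth_px, frame$width_px))
  structure(list(pixels = pixels, frame = frame), class = "trench_image")
}

#' Construct a binary root mask in the normalized frame
#'
#' @param pixels Integer matrix of 0/1 with the frame's dimensions.
#' @param frame A [frame_spec()].
#' @return A `root_mask` object.
#' @export
root_mask <- function(pixels, frame = frame_spec()) {
  if (!is.matrix(pixels)) stop("mask must be a single-channel matrix")
  if (!all(pixels %in% c(0L, 1L))) stop("mask must be binary (0/1)")
  if (nrow(pixels) != frame$depth_px || ncol(pixels) != frame$width_px)
    stop("mask dimensions do not match the frame")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, frame = frame), class = "root_mask")
}

# Accept either a wrapped object or a bare raster.
as_pixels <- function(x) {
  if (inherits(x, "trench_image") || inherits(x, "root_mask")) x$pixels else x
}

#' @export
print.frame_spec <- function(x, ...) {
  cat(sprintf("<frame_spec> %g x %g cm at %g px/cm (%d x %d px), hill column %d\n",
              x$depth_cm, x$width_cm, x$resolution_px_per_cm,
              x$depth_px, x$width_px, x$hill_column_px))
  invisible(x)
}

#' @export
print.trench_image <- function(x, ...) {
  cat(sprintf("<trench_image> %d x %d px RGB\n",
              dim(x$pixels)[1], dim(x$pixels)[2]))
  invisible(x)
}

#' @export
print.root_mask <- function(x, ...) {
  cat(sprintf("<root_mask> %d x %d px, %d root pixels\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}
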