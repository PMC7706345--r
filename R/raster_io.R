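#' Read a trench-profile photograph
#'
#' Reads an 8-bit RGB PNG or TIFF into a numeric array with values in
#' \[0, 1\]. Single-channel or RGBA files are rejected: the pipeline
#' expects plain 3-channel photographs.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array `H x W x 3`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = ,
               tiff = tiff::readTIFF(path),
               stop("unsupported image format: .", ext))
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("expected 3 channels, got ",
         if (length(dim(px)) == 2L) 1L else dim(px)[3])
  px
}

#' Write an RGB raster as an 8-bit PNG
#'
#' @param pixels `H x W x 3` array in \[0, 1\] or a [trench_image()].
#' @param path Output path (`.png`).
#' @export
write_image <- function(pixels, path) {
  px <- as_pixels(pixels)
  if (length(dim(px)) != 3L || dim(px)[3] != 3L) stop("expected 3 channels")
  png::writePNG(px, path)
  invisible(path)
}

#' Map a raw photograph into the normalized frame
#'
#' Applies the manual normalization recorded in the per-image
#' annotation: the raster is rotated counterclockwise about its centre,
#' rescaled from the raw scale-bar resolution to the frame resolution,
#' and trimmed to the frame window (60 cm depth x 60 cm width at the
#' defaults). The three steps are composed into a single inverse
#' coordinate map, so each output pixel is sampled once: output pixel
#' `(r, c)` (0-based) reads the rotated raw image at
#' `crop + (r, c) / s` where `s = frame resolution / raw resolution`.
#' Photographs are resampled bilinearly; masks use nearest-neighbour so
#' labels stay binary.
#'
#' @param raw Raw raster: `H x W x 3` array (kind `"image"`) or a binary
#'   matrix (kind `"mask"`).
#' @param ann A [frame_annotation()].
#' @param frame A [frame_spec()].
#' @param kind `"image"` or `"mask"`.
#' @return A [trench_image()] or [root_mask()] in the normalized frame.
#' @export
normalize_frame <- function(raw, ann, frame = frame_spec(),
                            kind = c("image", "mask")) {
  kind <- match.arg(kind)
  stopifnot(inherits(ann, "frame_annotation"))
  if (ann$scale_px_per_cm <= 0) stop("non-positive scale")
  raw <- as_pixels(raw)
  is_mask <- kind == "mask"
  if (is_mask) {
    if (!is.matrix(raw)) stop("mask must be a single-channel matrix")
    storage.mode(raw) <- "double"
  } else if (length(dim(raw)) != 3L || dim(raw)[3] != 3L) {
    stop("expected 3 channels")
  }
  H <- dim(raw)[1]; W <- dim(raw)[2]
  s <- frame$resolution_px_per_cm / ann$scale_px_per_cm
  th <- ann$rotation_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  # src = centre + Rinv %*% (p - centre),  p = crop + out / s
  A <- matrix(c(ct / s, -st / s, st / s, ct / s), 2, 2)
  t0 <- c(cr + ct * (ann$crop_row - cr) + st * (ann$crop_col - cc),
          cc - st * (ann$crop_row - cr) + ct * (ann$crop_col - cc))
  out <- resample_affine_cpp(raw, frame$depth_px, frame$width_px, A, t0,
                             bilinear = !is_mask, fill = 0,
                             error_outside = TRUE)
  if (is_mask) {
    out <- matrix(as.integer(out > 0.5), frame$depth_px, frame$width_px)
    root_mask(out, frame)
  } else {
    trench_image(out, frame)
  }
}

#' Write / read binary root masks as 8-bit PNG
#'
#' Masks are stored as single-channel 8-bit PNGs with values 0 and 255,
#' matching the export convention of manual tracing tools. Reading maps
#' gray levels above 127 to 1, so round-trips are bit-exact.
#'
#' @param mask Binary matrix of 0/1 or a [root_mask()].
#' @param path Path to a `.png` file.
#' @return `read_mask()` returns an integer 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  px <- as_pixels(mask)
  if (!is.matrix(px)) stop("mask must be a single-channel matrix")
  if (!all(px %in% c(0L, 1L))) stop("mask must be binary (0/1)")
  png::writePNG(matrix(as.numeric(px), nrow(px), ncol(px)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) stop("expected a single-channel mask PNG")
  matrix(as.integer(px > 127 / 255), nrow(px), ncol(px))
}

#' Read a sidecar CSV of per-image frame annotations
#'
#' Expected columns: `image`, `rotation_deg`, `scale_px_per_cm`,
#' `crop_row`, `crop_col`, `hill_col`.
#'
#' @param path CSV path.
#' @return A data.frame with one row per image and a list-column free
#'   layout; use [frame_annotation()] on each row.
#' @export
read_annotations <- function(path) {
  need <- c("image", "rotation_deg", "scale_px_per_cm",
            "crop_row", "crop_col", "hill_col")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation CSV lacks columns: ", paste(missing, collapse = ", "))
  df
}
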