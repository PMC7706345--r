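#' Fold a root mask in half about the hill column
#'
#' Horizontal root distance is measured from the hill (the planting
#' position), so the mask is folded about the hill column before
#' skeletonization: columns at equal distance left and right of the
#' hill are combined by logical OR. The output keeps binary mask
#' semantics -- an overlap of left and right roots counts once, since
#' the folded object is still an image that is subsequently thinned.
#'
#' @param mask Binary matrix or [root_mask()].
#' @param hill_col 0-based hill column; defaults to the mask frame's
#'   hill column (or the central column for a bare matrix).
#' @return Binary matrix with `max(left, right) + 1` columns; column
#'   `d + 1` holds distance-`d` pixels.
#' @export
fold_half <- function(mask, hill_col = NULL) {
  fr <- if (inherits(mask, "root_mask")) mask$frame else NULL
  px <- as_pixels(mask)
  if (!all(px %in% c(0L, 1L))) stop("mask must be binary (0/1)")
  W <- ncol(px)
  if (is.null(hill_col))
    hill_col <- if (!is.null(fr)) fr$hill_column_px else W %/% 2L
  if (hill_col < 0L || hill_col >= W) stop("hill column outside raster")
  h1 <- hill_col + 1L  # 1-based
  dmax <- max(hill_col, W - 1L - hill_col)
  out <- matrix(0L, nrow(px), dmax + 1L)
  for (d in 0:dmax) {
    v <- rep(0L, nrow(px))
    if (h1 + d <= W) v <- v | px[, h1 + d]
    if (d > 0L && h1 - d >= 1L) v <- v | px[, h1 - d]
    out[, d + 1L] <- as.integer(v)
  }
  out
}

#' Skeletonize a binary mask to 1-px-wide centerlines
#'
#' Morphological thinning (Zhang-Suen) reduces each root stroke to its
#' medial axis, so the pixel count approximates curve length and is
#' insensitive to the stroke width used during manual tracing. Already
#' thin curves pass through unchanged.
#'
#' @param mask Binary matrix or [root_mask()].
#' @return Integer 0/1 matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  px <- as_pixels(mask)
  if (!all(px %in% c(0L, 1L))) stop("mask must be binary (0/1)")
  storage.mode(px) <- "integer"
  thin_zhang_suen_cpp(px)
}

#' Root length represented by a skeleton
#'
#' Each skeleton pixel stands for one pixel length of root: at the
#' default 25.6 px/cm (256 dots per 10 cm) one pixel is 10/256 cm,
#' approximately 0.39 mm.
#'
#' @param skeleton Binary skeleton matrix.
#' @param px_per_cm Frame resolution (default 25.6).
#' @return Root length in cm.
#' @export
root_length_cm <- function(skeleton, px_per_cm = 25.6) {
  sum(as_pixels(skeleton)) / px_per_cm
}

#' Cumulative root-length profile along one axis
#'
#' Counts skeleton pixels per 1-px bin along the depth (rows) or
#' hill-distance (columns, after folding) axis, cumulated and
#' normalized to end at 1.
#'
#' @param skeleton Binary skeleton matrix (non-empty).
#' @param axis `"depth"` or `"width"`.
#' @param px_per_cm Frame resolution (default 25.6).
#' @return A `cumulative_profile`: list with `axis`, `bin_cm`,
#'   `px_per_cm` and the non-decreasing `cumulative` vector.
#' @export
cumulative_profile <- function(skeleton, axis = c("depth", "width"),
                               px_per_cm = 25.6) {
  axis <- match.arg(axis)
  px <- as_pixels(skeleton)
  total <- sum(px)
  if (total == 0) stop("no roots detected")
  counts <- if (axis == "depth") rowSums(px) else colSums(px)
  structure(list(axis = axis, bin_cm = 1 / px_per_cm,
                 px_per_cm = px_per_cm,
                 cumulative = cumsum(counts) / total),
            class = "cumulative_profile")
}

#' Distance at which a cumulative profile reaches a quantile
#'
#' Returns the smallest distance where the cumulative root fraction
#' reaches `q`, interpolating linearly inside the crossing bin. With
#' `q = 0.5` on a depth profile this is Depth50; on a width profile,
#' Width50. A bin is 1 px = 0.39 mm at the default resolution, so the
#' interpolation choice is below measurement noise.
#'
#' @param profile A [cumulative_profile()].
#' @param q Quantile in (0, 1); default 0.5.
#' @return Distance in cm.
#' @export
quantile_distance <- function(profile, q = 0.5) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  cum <- profile$cumulative
  k <- match(TRUE, cum >= q)
  if (is.na(k)) k <- length(cum)  # guard against rounding at the tail
  prev <- if (k > 1L) cum[k - 1L] else 0
  frac <- if (cum[k] > prev) (q - prev) / (cum[k] - prev) else 1
  ((k - 1L) + frac) / profile$px_per_cm
}

#' Root distribution parameters of one mask
#'
#' The full measurement pipeline for one image: fold the mask about the
#' hill, thin it to a skeleton, and summarize the skeleton as
#' * `depth50_cm` -- the depth from the soil surface enclosing 50% of
#'   total root length,
#' * `width50_cm` -- the distance from the hill enclosing 50% of total
#'   root length,
#' * `total_root_length_cm` -- skeleton pixel count converted to cm.
#'
#' An empty mask is an error ("no roots detected"), not a zero
#' phenotype: a failed segmentation should be re-traced, not recorded
#' as a rootless plant.
#'
#' @param mask A [root_mask()], or a binary matrix plus `hill_col` and
#'   `px_per_cm`.
#' @param hill_col 0-based hill column (default: frame hill or centre).
#' @param px_per_cm Frame resolution (default: frame resolution or 25.6).
#' @return A `root_distribution_params` list.
#' @export
phenotype_image <- function(mask, hill_col = NULL, px_per_cm = NULL) {
  fr <- if (inherits(mask, "root_mask")) mask$frame else NULL
  if (is.null(px_per_cm))
    px_per_cm <- if (!is.null(fr)) fr$resolution_px_per_cm else 25.6
  px <- as_pixels(mask)
  if (sum(px) == 0) stop("no roots detected")
  folded <- fold_half(mask, hill_col)
  sk <- skeletonize_mask(folded)
  if (sum(sk) == 0) stop("no roots detected")
  depth <- cumulative_profile(sk, "depth", px_per_cm)
  width <- cumulative_profile(sk, "width", px_per_cm)
  structure(list(depth50_cm = quantile_distance(depth, 0.5),
                 width50_cm = quantile_distance(width, 0.5),
                 total_root_length_cm = root_length_cm(sk, px_per_cm)),
            class = "root_distribution_params")
}

#' @export
print.root_distribution_params <- function(x, ...) {
  cat(sprintf("Depth50 %.2f cm, Width50 %.2f cm, root length %.1f cm\n",
              x$depth50_cm, x$width50_cm, x$total_root_length_cm))
  invisible(x)
}
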