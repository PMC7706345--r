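#' Augmentation configuration
#'
#' Training tiles are perturbed geometrically (horizontal flip, rotation
#' angle, scale) and photometrically (intensity, gamma, chroma) to make
#' the model robust to field conditions: camera tilt, distance jitter,
#' sunlight and soil-colour variation. Geometric transforms are applied
#' identically to the image and its mask; photometric transforms touch
#' the image only. Ranges are uniform draws; each transform uses one
#' draw per pair, applied in the fixed order flip, rotate, scale,
#' intensity, gamma, chroma.
#'
#' @param rotation_deg_range Rotation range in degrees (counterclockwise).
#' @param scale_range Isotropic scale factor range.
#' @param flip_horizontal Draw a horizontal flip with probability 1/2.
#' @param intensity_range Multiplicative brightness range.
#' @param gamma_range Gamma (power-law) exponent range; must be positive.
#' @param chroma_range Saturation multiplier range (1 leaves colour
#'   untouched, 0 collapses to gray).
#' @param seed Base seed for [make_epoch()] streams.
#' @return An `augment_config` object.
#' @export
augment_config <- function(rotation_deg_range = c(-15, 15),
                           scale_range = c(0.9, 1.1),
                           flip_horizontal = TRUE,
                           intensity_range = c(0.8, 1.2),
                           gamma_range = c(0.7, 1.4),
                           chroma_range = c(0.8, 1.2),
                           seed = 1L) {
  for (r in list(rotation_deg_range, scale_range, intensity_range,
                 gamma_range, chroma_range)) {
    if (length(r) != 2L || r[1] > r[2]) stop("ranges must be (lo, hi) with lo <= hi")
  }
  if (scale_range[1] <= 0 || gamma_range[1] <= 0)
    stop("scale and gamma must be strictly positive")
  structure(list(rotation_deg_range = rotation_deg_range,
                 scale_range = scale_range,
                 flip_horizontal = isTRUE(flip_horizontal),
                 intensity_range = intensity_range,
                 gamma_range = gamma_range,
                 chroma_range = chroma_range,
                 seed = as.integer(seed)),
            class = "augment_config")
}

draw_augment <- function(cfg) {
  list(flip = cfg$flip_horizontal && stats::runif(1) < 0.5,
       rot = stats::runif(1, cfg$rotation_deg_range[1], cfg$rotation_deg_range[2]),
       scale = stats::runif(1, cfg$scale_range[1], cfg$scale_range[2]),
       intensity = stats::runif(1, cfg$intensity_range[1], cfg$intensity_range[2]),
       gamma = stats::runif(1, cfg$gamma_range[1], cfg$gamma_range[2]),
       chroma = stats::runif(1, cfg$chroma_range[1], cfg$chroma_range[2]))
}

#' Apply one paired augmentation draw
#'
#' The geometric part (flip, rotation and scale about the tile centre,
#' composed into a single resampling pass) is shared between image and
#' mask; the mask is resampled nearest-neighbour so it stays binary.
#' Regions swept in from outside the tile are filled with 0. Photometric
#' adjustments operate on the image in \[0, 1\] space and are clipped
#' back to \[0, 1\].
#'
#' @param image `H x W x 3` tile in \[0, 1\].
#' @param mask Binary `H x W` matrix.
#' @param cfg An [augment_config()].
#' @param draws Optional fixed transform draws (as produced internally);
#'   when `NULL`, one draw per transform is taken from the current RNG
#'   stream.
#' @return List with augmented `image` and `mask`.
#' @export
augment_pair <- function(image, mask, cfg = augment_config(), draws = NULL) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stop("image and mask shapes differ")
  if (is.null(draws)) draws <- draw_augment(cfg)
  H <- dim(image)[1]; W <- dim(image)[2]

  identity_geom <- !draws$flip && draws$rot == 0 && draws$scale == 1
  if (!identity_geom) {
    th <- draws$rot * pi / 180
    ct <- cos(th); st <- sin(th)
    s <- draws$scale
    cr <- (H - 1) / 2; cc <- (W - 1) / 2
    # inverse map: undo scale, undo rotation (both about the centre),
    # then undo the flip
    A1 <- matrix(c(ct / s, -st / s, st / s, ct / s), 2, 2)
    t1 <- c(cr, cc) - A1 %*% c(cr, cc)
    if (draws$flip) {
      A <- A1 * matrix(c(1, -1, 1, -1), 2, 2)
      t0 <- c(t1[1], (W - 1) - t1[2])
    } else {
      A <- A1; t0 <- c(t1[1], t1[2])
    }
    image <- resample_affine_cpp(image, H, W, A, t0, bilinear = TRUE,
                                 fill = 0, error_outside = FALSE)
    m <- resample_affine_cpp(matrix(as.numeric(mask), H, W), H, W, A, t0,
                             bilinear = FALSE, fill = 0, error_outside = FALSE)
    mask <- matrix(as.integer(m > 0.5), H, W)
  } else {
    mask <- matrix(as.integer(mask > 0.5), H, W)
  }

  img <- image * draws$intensity
  img[img < 0] <- 0; img[img > 1] <- 1
  img <- img ^ draws$gamma
  if (draws$chroma != 1) {
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    for (ch in 1:3) img[, , ch] <- gray + (img[, , ch] - gray) * draws$chroma
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  list(image = img, mask = mask)
}

#' Generate one deterministic epoch of augmented pairs
#'
#' Yields exactly one augmented copy of every training pair. The stream
#' is a pure function of `(cfg$seed, epoch_index)`: the same pair of
#' values reproduces the epoch bit-for-bit, and different epochs see
#' different draws.
#'
#' @param pairs Non-empty list of `list(image =, mask =)` tiles.
#' @param cfg An [augment_config()].
#' @param epoch_index Epoch counter (1-based).
#' @return List of augmented pairs, same length and order as `pairs`.
#' @export
make_epoch <- function(pairs, cfg = augment_config(), epoch_index = 1L) {
  if (length(pairs) == 0L) stop("empty training set")
  seed_e <- (as.numeric(cfg$seed) + 100003 * as.numeric(epoch_index)) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed_e))
  lapply(pairs, function(p) augment_pair(p$image, p$mask, cfg))
}
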