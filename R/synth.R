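#' Synthetic trench-image configuration
#'
#' The generator emulates a normalized trench-profile photograph: a
#' brown-textured soil background with a vertical illumination gradient
#' and per-image contrast jitter (standing in for sunlight and soil
#' colour variation), on which lighter root curves fan downward and
#' outward from the hill at the top centre. Each root places exactly
#' one centerline pixel per row, so the depth distribution of
#' centerline pixels is analytically controlled: with the
#' truncated-exponential law, terminal depths are drawn as
#' `min(Exp(rate), depth_cm)`, which makes the marginal depth density
#' of centerline pixels exactly the truncated exponential with that
#' rate.
#'
#' The ground-truth mask is the centerline dilated to `label_width_px`
#' (default 4 px, the manual pencil-tool convention, about 1.56 mm at
#' 25.6 px/cm), with no anti-aliasing. Rendered root strokes use an
#' independent per-root width from `root_width_px_range`, so labels are
#' deliberately width-mismatched with appearance, as in manual tracing.
#'
#' @param n_roots Number of root curves per image.
#' @param root_width_px_range Rendered stroke width range in px.
#' @param depth_law Either
#'   `list(kind = "truncated_exponential", rate_per_cm = 0.1)` or
#'   `list(kind = "fixed_path", depth_cm = 20)` (one straight vertical
#'   root per curve).
#' @param lateral_drift Controls the angular spread of the fan: the
#'   outermost roots take slope (pixels sideways per pixel down) about
#'   `min(0.8, 2 * lateral_drift)`, and each root's slope scales with
#'   its crown emergence distance so the fan never crosses itself,
#'   not even after folding about the hill.
#' @param soil_palette `"topsoil"` (dark loam) or `"subsoil"`
#'   (red-brown), or a list with `base` (RGB in \[0,1\]) and `noise`.
#' @param illumination_gradient Relative top-to-bottom brightness drop.
#' @param label_width_px Truth-mask pencil width in px (default 4).
#' @param seed Seed; the same configuration is bit-reproducible.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_roots = 40L,
                         root_width_px_range = c(2L, 6L),
                         depth_law = list(kind = "truncated_exponential",
                                          rate_per_cm = 0.1),
                         lateral_drift = 0.4,
                         soil_palette = "topsoil",
                         illumination_gradient = 0.25,
                         label_width_px = 4L,
                         seed = 1L) {
  if (n_roots < 1L) stop("n_roots must be >= 1")
  if (root_width_px_range[1] < 1L) stop("root widths must be >= 1")
  if (label_width_px < 1L) stop("label_width_px must be >= 1")
  if (identical(depth_law$kind, "truncated_exponential") &&
      depth_law$rate_per_cm <= 0) stop("rate_per_cm must be positive")
  if (is.character(soil_palette)) {
    soil_palette <- switch(soil_palette,
      topsoil = list(base = c(0.33, 0.25, 0.18), noise = 0.10),
      subsoil = list(base = c(0.45, 0.30, 0.20), noise = 0.08),
      stop("unknown soil palette: ", soil_palette))
  }
  structure(list(n_roots = as.integer(n_roots),
                 root_width_px_range = as.integer(root_width_px_range),
                 depth_law = depth_law,
                 lateral_drift = lateral_drift,
                 soil_palette = soil_palette,
                 illumination_gradient = illumination_gradient,
                 label_width_px = as.integer(label_width_px),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Draw the root centerlines. Each root places exactly one pixel per
# image row (sideways movement rides on diagonal steps), so a root
# reaching depth D contributes one centerline pixel at every depth in
# [0, D] and the marginal depth density of centerline pixels follows
# the terminal-depth survival function exactly. Roots start within the
# crown (up to 2 cm either side of the hill) and follow ordered
# outward rays -- sorted start columns paired with sorted lateral
# slopes -- plus a small bounded wiggle, so the fan spreads from the
# hill without curves crossing each other.
draw_centerlines <- function(cfg, frame) {
  H <- frame$depth_px; W <- frame$width_px
  res <- frame$resolution_px_per_cm
  hill1 <- frame$hill_column_px + 1L
  crown_px <- max(1, round(2 * res))  # 2 cm half-width
  center <- matrix(0L, H, W)
  law <- cfg$depth_law
  n <- cfg$n_roots
  if (identical(law$kind, "fixed_path")) {
    d_cm <- if (is.null(law$depth_cm)) 20 else law$depth_cm
    n_px <- min(H, max(1L, as.integer(round(d_cm * res))))
    center[seq_len(n_px), hill1] <- 1L
    return(list(center = center, rows = seq_len(n_px),
                cols = rep(hill1, n_px),
                root_rows = list(seq_len(n_px)),
                root_cols = list(rep(hill1, n_px))))
  }
  if (!identical(law$kind, "truncated_exponential"))
    stop("unknown depth law: ", law$kind)
  smax <- min(0.8, 2 * cfg$lateral_drift)
  # Crown emergence points: evenly spaced distances from the hill with
  # random sides and a little jitter. Outward slope grows with the
  # emergence distance, so the fan does not cross itself -- not even
  # after the measurement fold maps both sides onto hill distance.
  gap <- crown_px / n
  mags <- seq(gap / 2, crown_px, length.out = n) +
    stats::runif(n, -gap / 4, gap / 4)
  signs <- sample(c(-1, 1), n, replace = TRUE)
  slope_jit <- stats::runif(n, 0.9, 1.1)
  d_cm <- pmin(stats::rexp(n, rate = law$rate_per_cm), frame$depth_cm)
  period <- stats::runif(n, 3 * res, 8 * res)
  phase <- stats::runif(n, 0, 2 * pi)
  rows_l <- vector("list", n); cols_l <- vector("list", n)
  for (i in seq_len(n)) {
    n_px <- min(H, max(1L, as.integer(round(d_cm[i] * res))))
    slope <- smax * (mags[i] / crown_px) * slope_jit[i]
    # keep the whole path inside the frame rather than clamping it
    # into an artificial vertical line on the border
    room <- (W %/% 2) - crown_px - 8
    if (slope * n_px > room) slope <- room / n_px
    r <- seq_len(n_px)
    col <- hill1 + signs[i] * round(mags[i] + slope * (r - 1) +
                                      0.6 * sin(2 * pi * (r - 1) / period[i] + phase[i]))
    col <- pmin(pmax(col, 1L), W)
    center[cbind(r, col)] <- 1L
    rows_l[[i]] <- r; cols_l[[i]] <- col
  }
  list(center = center, rows = unlist(rows_l), cols = unlist(cols_l),
       root_rows = rows_l, root_cols = cols_l)
}

#' Generate one synthetic trench image with ground truth
#'
#' @param cfg A [synth_config()].
#' @param frame A [frame_spec()]; use a coarser resolution (e.g.
#'   6.4 px/cm, 384 x 384 px) for desk-scale work.
#' @param render If `FALSE`, skip soil/root rendering and return
#'   `image = NULL` (fast path when only the ground truth is needed,
#'   e.g. for distribution studies with thousands of roots).
#' @return List with `image` ([trench_image()]), `mask`
#'   ([root_mask()], the centerline dilated to the label width),
#'   `centerline` (exact 1-px truth raster) and `truth`
#'   (`root_distribution_params` computed from the exact centerline
#'   paths, with multiplicity where curves cross -- the oracle route,
#'   bypassing segmentation and thinning).
#' @export
generate_sample <- function(cfg = synth_config(), frame = frame_spec(),
                            render = TRUE) {
  set.seed(cfg$seed)
  H <- frame$depth_px; W <- frame$width_px
  res <- frame$resolution_px_per_cm

  cl <- draw_centerlines(cfg, frame)
  center <- cl$center

  # truth parameters from the exact centerline paths: per-pixel depth
  # and hill-distance counts (with multiplicity, so two curves crossing
  # one pixel both contribute), pushed through the measurement
  # pipeline's own cumulative-quantile math
  hill1 <- frame$hill_column_px + 1L
  d_counts <- tabulate(cl$rows, nbins = H)
  w_counts <- tabulate(abs(cl$cols - hill1) + 1L, nbins = W)
  total <- length(cl$rows)
  mkprof <- function(counts, axis)
    structure(list(axis = axis, bin_cm = 1 / res, px_per_cm = res,
                   cumulative = cumsum(counts) / total),
              class = "cumulative_profile")
  truth <- structure(
    list(depth50_cm = quantile_distance(mkprof(d_counts, "depth"), 0.5),
         width50_cm = quantile_distance(mkprof(w_counts, "width"), 0.5),
         total_root_length_cm = total / res),
    class = "root_distribution_params")

  mask <- dilate_square_cpp(center, cfg$label_width_px)

  if (!render) {
    return(list(image = NULL, mask = root_mask(mask, frame),
                centerline = center, truth = truth))
  }

  # soil background: correlated low-frequency noise + fine grain
  pal <- cfg$soil_palette
  coarse_h <- max(4L, H %/% 24L); coarse_w <- max(4L, W %/% 24L)
  coarse <- matrix(stats::rnorm(coarse_h * coarse_w), coarse_h, coarse_w)
  A <- matrix(c((coarse_h - 1) / (H - 1), 0, 0, (coarse_w - 1) / (W - 1)), 2, 2)
  lowfreq <- resample_affine_cpp(coarse, H, W, A, c(0, 0), bilinear = TRUE,
                                 fill = 0, error_outside = FALSE)
  grain <- matrix(stats::rnorm(H * W, sd = 0.02), H, W)
  illum <- 1 + cfg$illumination_gradient * (0.5 - (seq_len(H) - 1) / (H - 1))
  contrast <- stats::runif(1, 0.85, 1.25)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    base <- pal$base[ch] * (1 + pal$noise * lowfreq) + grain
    img[, , ch] <- base * illum * contrast
  }

  # render each root as a lighter, desaturated stroke of its own width
  root_base <- c(0.78, 0.72, 0.60)
  widths <- cfg$root_width_px_range
  for (i in seq_along(cl$root_rows)) {
    w <- sample(widths[1]:widths[2], 1L)
    lo <- -((w - 1L) %/% 2L); hi <- w %/% 2L
    offs <- expand.grid(dr = lo:hi, dc = lo:hi)
    rr <- outer(cl$root_rows[[i]], offs$dr, `+`)
    cc <- outer(cl$root_cols[[i]], offs$dc, `+`)
    keep <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    idx <- unique((cc[keep] - 1L) * H + rr[keep])
    shade <- stats::runif(1, 0.85, 1.1)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- root_base[ch] * shade +
        stats::rnorm(length(idx), sd = 0.03)
      img[, , ch] <- plane
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  # quantize to 8 bits so in-memory and PNG round-trip values agree
  img <- round(img * 255) / 255

  list(image = trench_image(img, frame),
       mask = root_mask(mask, frame),
       centerline = center,
       truth = truth)
}

#' Generate a reproducible synthetic dataset on disk
#'
#' Writes `images/img_###.png`, `masks/img_###.png` and `truth.csv`
#' (per-image truth parameters and split assignment) under `out_dir`.
#' Per-image seeds and, under the truncated-exponential law, per-image
#' rates are derived deterministically from `cfg$seed`, so a re-run
#' reproduces every file byte-for-byte. Drawing the rate per image from
#' `rate_range_per_cm` emulates the accession-to-accession diversity of
#' root depth distributions.
#'
#' @param cfg A [synth_config()]; when `cfg$depth_law` carries a
#'   `rate_range_per_cm = c(lo, hi)`, each image draws its own rate
#'   uniformly from that range.
#' @param n_images Total number of images (>= 2).
#' @param split Train/validation sizes, either counts summing to
#'   `n_images` or fractions summing to 1.
#' @param out_dir Output directory (created).
#' @param frame A [frame_spec()].
#' @return Invisibly, the truth data.frame.
#' @export
generate_dataset <- function(cfg = synth_config(), n_images,
                             split = c(train = 5/6, val = 1/6),
                             out_dir, frame = frame_spec()) {
  if (n_images < 2L) stop("n_images must be >= 2")
  if (abs(sum(split) - 1) < 1e-9) split <- round(split * n_images)
  if (sum(split) != n_images || any(split < 0))
    stop("invalid split: must be counts summing to n_images or fractions summing to 1")
  n_train <- split[[1]]
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- NULL
  for (i in seq_len(n_images)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer((as.numeric(cfg$seed) * 10007 + i) %% 2147483647)
    if (identical(cfg$depth_law$kind, "truncated_exponential") &&
        !is.null(cfg$depth_law$rate_range_per_cm)) {
      rr <- cfg$depth_law$rate_range_per_cm
      set.seed(cfg_i$seed + 1L)
      cfg_i$depth_law$rate_per_cm <- stats::runif(1, rr[1], rr[2])
      cfg_i$depth_law$rate_range_per_cm <- NULL
    }
    smp <- generate_sample(cfg_i, frame)
    id <- sprintf("img_%03d", i)
    write_image(smp$image, file.path(out_dir, "images", paste0(id, ".png")))
    write_mask(smp$mask, file.path(out_dir, "masks", paste0(id, ".png")))
    rows <- rbind(rows, data.frame(
      image = id,
      split = if (i <= n_train) "train" else "val",
      depth50_cm = smp$truth$depth50_cm,
      width50_cm = smp$truth$width50_cm,
      total_root_length_cm = smp$truth$total_root_length_cm,
      rate_per_cm = if (identical(cfg_i$depth_law$kind, "truncated_exponential"))
        cfg_i$depth_law$rate_per_cm else NA_real_,
      seed = cfg_i$seed,
      stringsAsFactors = FALSE))
  }
  utils::write.csv(rows, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(rows)
}

#' Closed-form median of the truncated exponential depth law
#'
#' For a depth density proportional to `exp(-rate * d)` on
#' `[0, depth_cm]`, the depth enclosing fraction `q` of the mass is
#' `-log(1 - q * (1 - exp(-rate * depth_cm))) / rate`. With `q = 0.5`
#' this is the analytic Depth50 of a synthetic image.
#'
#' @param rate_per_cm Exponential rate (1/cm).
#' @param depth_cm Truncation depth (default 60).
#' @param q Mass fraction (default 0.5).
#' @return Depth in cm.
#' @export
truncated_exp_quantile <- function(rate_per_cm, depth_cm = 60, q = 0.5) {
  -log(1 - q * (1 - exp(-rate_per_cm * depth_cm))) / rate_per_cm
}
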