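# Shared fixtures: small frames and hand-built rasters.

# Desk-scale frame: 60 x 60 cm at 6.4 px/cm = 384 x 384 px, which
# still divides into a 6 x 6 grid of 64-px tiles.
desk_frame <- function() frame_spec(resolution_px_per_cm = 6.4)

# Full-resolution frame (1536 x 1536).
full_frame <- function() frame_spec()

random_rgb <- function(h, w, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

random_mask <- function(h, w, p = 0.1, seed = 1) {
  set.seed(seed)
  matrix(rbinom(h * w, 1L, p), h, w)
}

# A handful of disjoint synthetic root curves (vertical bars) that
# never come within `sep` pixels of each other, all on one side of a
# hill at column 0 so folding cannot overlay them; used for
# dilation-invariance checks.
disjoint_roots_mask <- function(h = 256, w = 256, sep = 12) {
  m <- matrix(0L, h, w)
  cols <- seq(20, w - 20, by = sep + 8)
  depths <- round(seq(0.3, 0.95, length.out = length(cols)) * h)
  for (i in seq_along(cols)) m[seq_len(depths[i]), cols[i]] <- 1L
  m
}

# Brute-force affine resampler used as the independent oracle for
# normalize_frame: maps each output pixel through the same geometry
# definition with explicit loops.
oracle_resample <- function(raw, ann, frame, bilinear = TRUE) {
  H <- dim(raw)[1]; W <- dim(raw)[2]
  C <- if (length(dim(raw)) == 3) dim(raw)[3] else 1
  s <- frame$resolution_px_per_cm / ann$scale_px_per_cm
  th <- ann$rotation_deg * pi / 180
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  out <- array(0, c(frame$depth_px, frame$width_px, C))
  for (r in 0:(frame$depth_px - 1)) {
    for (c in 0:(frame$width_px - 1)) {
      pr <- ann$crop_row + r / s; pc <- ann$crop_col + c / s
      sr <- cr + cos(th) * (pr - cr) + sin(th) * (pc - cc)
      sc <- cc - sin(th) * (pr - cr) + cos(th) * (pc - cc)
      for (ch in seq_len(C)) {
        plane <- if (C == 1) raw else raw[, , ch]
        if (bilinear) {
          r0 <- floor(sr); c0 <- floor(sc)
          fr <- sr - r0; fc <- sc - c0
          r1 <- min(r0 + 1, H - 1); c1 <- min(c0 + 1, W - 1)
          v <- (1 - fr) * (1 - fc) * plane[r0 + 1, c0 + 1] +
            fr * (1 - fc) * plane[r1 + 1, c0 + 1] +
            (1 - fr) * fc * plane[r0 + 1, c1 + 1] +
            fr * fc * plane[r1 + 1, c1 + 1]
        } else {
          v <- plane[min(max(round(sr), 0), H - 1) + 1,
                     min(max(round(sc), 0), W - 1) + 1]
        }
        out[r + 1, c + 1, ch] <- v
      }
    }
  }
  if (C == 1) out[, , 1] else out
}
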