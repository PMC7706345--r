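test_that("image round-trips through PNG are bit-exact and contracts hold", {
  px <- round(random_rgb(48, 40, seed = 3) * 255) / 255
  f <- withr::local_tempfile(fileext = ".png")
  write_image(px, f)
  back <- read_image(f)
  expect_identical(dim(back), c(48L, 40L, 3L))
  expect_equal(back, px)
  write_image(back, f)
  expect_equal(read_image(f), back)

  g <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(100), 10, 10), g)
  expect_error(read_image(g), "expected 3 channels")
  expect_error(read_image("no-such-file.png"), "not found")
})

test_that("mask round-trips are bit-exact and non-binary input raises", {
  m <- random_mask(30, 30, p = 0.2, seed = 5)
  f <- withr::local_tempfile(fileext = ".png")
  write_mask(m, f)
  expect_identical(read_mask(f), m)

  z <- matrix(0L, 8, 8)
  write_mask(z, f)
  expect_identical(read_mask(f), z)
  expect_true(all(png::readPNG(f) == 0))

  bad <- m; bad[1, 1] <- 7L
  expect_error(write_mask(bad, f), "binary")
})

test_that("normalize_frame with identity annotation is an exact crop", {
  fr <- frame_spec(resolution_px_per_cm = 1, width_cm = 24, depth_cm = 24)
  raw <- random_rgb(40, 40, seed = 7)
  ann <- frame_annotation(scale_px_per_cm = 1)
  out <- normalize_frame(raw, ann, fr)
  expect_s3_class(out, "trench_image")
  expect_equal(out$pixels, raw[1:24, 1:24, ])

  # idempotence: normalizing the already-normalized image changes nothing
  again <- normalize_frame(out$pixels, ann, fr)
  expect_equal(again$pixels, out$pixels)

  # crop offset
  ann2 <- frame_annotation(scale_px_per_cm = 1, crop_row = 10, crop_col = 4)
  expect_equal(normalize_frame(raw, ann2, fr)$pixels, raw[11:34, 5:28, ])
})

test_that("normalize_frame scaling matches the brute-force oracle resampler", {
  fr <- frame_spec(resolution_px_per_cm = 1, width_cm = 24, depth_cm = 24)
  raw <- random_rgb(64, 64, seed = 11)
  # raw is 2x too fine: 2 px/cm against a 1 px/cm frame
  ann <- frame_annotation(scale_px_per_cm = 2, crop_row = 3, crop_col = 5)
  got <- normalize_frame(raw, ann, fr)$pixels
  expect_equal(got, oracle_resample(raw, ann, fr), tolerance = 1e-12)

  # arbitrary rotation + scale against the same oracle
  ann3 <- frame_annotation(scale_px_per_cm = 1.5, rotation_deg = 7,
                           crop_row = 12, crop_col = 14)
  got3 <- normalize_frame(raw, ann3, fr)$pixels
  expect_equal(got3, oracle_resample(raw, ann3, fr), tolerance = 1e-12)
})

test_that("rotation moves a marked pixel to its analytic position", {
  fr <- frame_spec(resolution_px_per_cm = 1, width_cm = 31, depth_cm = 31)
  raw <- array(0, c(31, 31, 3))
  # pixel east of the centre (0-based (15, 25)) must land north of the
  # centre under a 90-degree counterclockwise rotation
  raw[16, 26, ] <- 1
  ann <- frame_annotation(scale_px_per_cm = 1, rotation_deg = 90)
  out <- normalize_frame(raw, ann, fr)$pixels
  expect_equal(out[6, 16, 1], 1)
  expect_equal(sum(out), 3)
})

test_that("masks are resampled nearest-neighbour and stay binary", {
  fr <- frame_spec(resolution_px_per_cm = 1, width_cm = 16, depth_cm = 16)
  raw <- random_mask(40, 40, p = 0.4, seed = 13)
  ann <- frame_annotation(scale_px_per_cm = 2, rotation_deg = 3,
                          crop_row = 4, crop_col = 4)
  out <- normalize_frame(raw, ann, fr, kind = "mask")
  expect_s3_class(out, "root_mask")
  expect_true(all(out$pixels %in% c(0L, 1L)))
})

test_that("out-of-bounds crop windows and bad scales are rejected", {
  fr <- frame_spec(resolution_px_per_cm = 1, width_cm = 24, depth_cm = 24)
  raw <- random_rgb(30, 30)
  expect_error(
    normalize_frame(raw, frame_annotation(scale_px_per_cm = 1, crop_row = 20), fr),
    "outside")
  expect_error(frame_annotation(scale_px_per_cm = -1), "positive")
})

test_that("annotation sidecar CSV is read and validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("image,rotation_deg,scale_px_per_cm,crop_row,crop_col,hill_col",
               "a.png,1.5,25.6,10,20,768"), f)
  df <- read_annotations(f)
  expect_equal(df$scale_px_per_cm, 25.6)
  writeLines("image,rotation_deg", f)
  expect_error(read_annotations(f), "lacks columns")
})

test_that("frame_spec derives pixel geometry and validates the hill column", {
  fr <- frame_spec()
  expect_equal(fr$width_px, 1536L)
  expect_equal(fr$depth_px, 1536L)
  expect_equal(fr$hill_column_px, 768L)
  expect_error(frame_spec(hill_column_px = 2000), "inside the frame")
  expect_error(frame_spec(resolution_px_per_cm = 25.61), "whole number")
})
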