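test_that("fold_half combines mirror columns by OR", {
  m <- matrix(0L, 10, 21)  # hill at 0-based column 10
  m[3, 1] <- 1L            # 10 px left of the hill
  f <- fold_half(m, hill_col = 10L)
  expect_equal(ncol(f), 11L)
  expect_equal(f[3, 11], 1L)
  expect_equal(sum(f), 1L)

  # pixels at the same distance on both sides collapse to one (OR)
  m2 <- matrix(0L, 10, 21)
  m2[5, 1] <- 1L; m2[5, 21] <- 1L
  f2 <- fold_half(m2, hill_col = 10L)
  expect_equal(f2[5, 11], 1L)
  expect_equal(sum(f2), 1L)

  # symmetric mask folds onto either half
  m3 <- matrix(0L, 10, 21)
  m3[2:8, 7] <- 1L; m3[2:8, 15] <- 1L
  f3 <- fold_half(m3, hill_col = 10L)
  expect_equal(f3[2:8, 5], rep(1L, 7))
  expect_equal(sum(f3), 7L)

  expect_error(fold_half(m, hill_col = 30L), "hill column")
})

test_that("fold, mirror-expand, fold is idempotent", {
  m <- random_mask(20, 41, p = 0.15, seed = 3)
  f1 <- fold_half(m, hill_col = 20L)
  # mirror-expand back to the full width, then fold again
  expanded <- cbind(f1[, (ncol(f1)):2], f1)
  f2 <- fold_half(expanded, hill_col = ncol(f1) - 1L)
  expect_identical(f2, f1)
})

test_that("thinning reduces a wide bar to a ~1-px line of its length", {
  # hand-verified 20-px bar first: 4 px wide, ends erode by up to half
  # the stroke width on each side
  m <- matrix(0L, 12, 28); m[5:8, 5:24] <- 1L
  sk <- skeletonize_mask(m)
  expect_true(abs(sum(sk) - 20) <= 4)
  expect_equal(length(unique(which(sk == 1L, arr.ind = TRUE)[, 1])), 1L)

  m2 <- matrix(0L, 12, 264); m2[5:8, 5:260] <- 1L
  sk2 <- skeletonize_mask(m2)
  expect_true(abs(sum(sk2) - 256) <= 4)

  expect_equal(sum(skeletonize_mask(matrix(0L, 10, 10))), 0)

  # already-thin curves are fixed points
  thin <- matrix(0L, 30, 30)
  for (i in 1:20) thin[i, 5 + (i %/% 3)] <- 1L
  expect_identical(skeletonize_mask(thin), thin)
  expect_error(skeletonize_mask(matrix(2L, 3, 3)), "binary")
})

test_that("skeleton pixel count converts to physical root length", {
  sk <- matrix(0L, 10, 300); sk[5, 1:256] <- 1L
  expect_equal(root_length_cm(sk, 25.6), 10)
  one <- matrix(0L, 5, 5); one[2, 2] <- 1L
  expect_equal(root_length_cm(one, 25.6), 0.0390625)  # ~0.39 mm
  expect_equal(root_length_cm(matrix(0L, 5, 5)), 0)
})

test_that("cumulative profiles behave as step/linear functions", {
  sk <- matrix(0L, 8, 8); sk[1, ] <- 1L
  prof <- cumulative_profile(sk, "depth", px_per_cm = 1)
  expect_equal(prof$cumulative[1], 1)

  unif <- matrix(1L, 1536, 2)
  p <- cumulative_profile(unif, "depth", px_per_cm = 25.6)
  expect_equal(p$cumulative[768], 0.5)
  expect_equal(quantile_distance(p, 0.5), 30, tolerance = 1e-6)

  two <- matrix(0L, 1536, 4)
  two[257, ] <- 1L; two[1281, ] <- 1L
  p2 <- cumulative_profile(two, "depth", px_per_cm = 25.6)
  expect_equal(quantile_distance(p2, 0.5), 257 / 25.6, tolerance = 0.05)

  expect_error(cumulative_profile(matrix(0L, 4, 4)), "no roots")
  expect_error(quantile_distance(p, 1.5), "lie in")
})

test_that("point masses and the truncated-exponential law are located exactly", {
  # all mass at 10 cm depth
  sk <- matrix(0L, 1536, 3); sk[257, ] <- 1L
  p <- cumulative_profile(sk, "depth", 25.6)
  expect_equal(quantile_distance(p, 0.5), 10, tolerance = 0.05)

  # skeleton pixels sampled from a truncated exponential (rate 0.1/cm,
  # truncation 60 cm): the 50% depth must match the closed-form median
  set.seed(42)
  rate <- 0.1; trunc_cm <- 60; n <- 20000
  u <- runif(n)
  d_cm <- -log(1 - u * (1 - exp(-rate * trunc_cm))) / rate  # inverse CDF
  rows <- pmin(1536L, pmax(1L, as.integer(floor(d_cm * 25.6)) + 1L))
  counts <- tabulate(rows, nbins = 1536L)
  # build a raster with those per-row counts
  width <- max(counts) + 1L
  sk2 <- matrix(0L, 1536, width)
  for (r in which(counts > 0)) sk2[r, seq_len(counts[r])] <- 1L
  p2 <- cumulative_profile(sk2, "depth", 25.6)
  analytic <- -log(1 - 0.5 * (1 - exp(-rate * trunc_cm))) / rate
  expect_equal(quantile_distance(p2, 0.5), analytic, tolerance = 0.2 / analytic)
})

test_that("phenotype_image recovers line geometries", {
  fr <- full_frame()
  # one vertical root from the surface to 20 cm under the hill
  m <- matrix(0L, fr$depth_px, fr$width_px)
  m[1:512, 769] <- 1L
  ph <- phenotype_image(m, hill_col = 768L, px_per_cm = 25.6)
  expect_equal(ph$depth50_cm, 10, tolerance = 0.1)
  expect_lt(ph$width50_cm, 0.2)
  expect_equal(ph$total_root_length_cm, 20, tolerance = 0.2)

  # one horizontal root at 5 cm depth spanning 0-20 cm from the hill
  m2 <- matrix(0L, fr$depth_px, fr$width_px)
  m2[129, 769:1280] <- 1L
  ph2 <- phenotype_image(m2, hill_col = 768L, px_per_cm = 25.6)
  expect_equal(ph2$depth50_cm, 5, tolerance = 0.1)
  expect_equal(ph2$width50_cm, 10, tolerance = 0.1)

  expect_error(phenotype_image(matrix(0L, 16, 16)), "no roots")
})

test_that("Depth50/Width50 are invariant to label dilation up to 4 px", {
  m <- disjoint_roots_mask(256, 256)
  base <- phenotype_image(m, hill_col = 0L, px_per_cm = 6.4)
  for (w in 2:4) {
    dil <- trenchroot:::dilate_square_cpp(m, w)
    ph <- phenotype_image(dil, hill_col = 0L, px_per_cm = 6.4)
    expect_equal(ph$depth50_cm, base$depth50_cm, tolerance = 0.12)
    expect_equal(ph$width50_cm, base$width50_cm, tolerance = 0.12)
  }
})

test_that("Depth50 is monotone and scale-free in row counts", {
  sk <- matrix(0L, 100, 10)
  set.seed(8)
  sk[cbind(sample(100, 40, TRUE), sample(10, 40, TRUE))] <- 1L
  p <- cumulative_profile(sk, "depth", 1)
  d0 <- quantile_distance(p, 0.5)

  # moving one pixel deeper never decreases Depth50
  idx <- which(sk == 1L, arr.ind = TRUE)
  shallow <- idx[which.min(idx[, 1]), ]
  sk2 <- sk
  sk2[shallow[1], shallow[2]] <- 0L
  free <- which(sk2[100, ] == 0L)[1]
  sk2[100, free] <- 1L
  expect_gte(quantile_distance(cumulative_profile(sk2, "depth", 1), 0.5), d0)

  # doubling every row's pixel count leaves the profile unchanged
  dbl <- cbind(sk, sk)
  expect_equal(quantile_distance(cumulative_profile(dbl, "depth", 1), 0.5), d0)
})
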