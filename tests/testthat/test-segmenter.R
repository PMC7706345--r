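tiny_cfg <- function() model_config(levels = 2L, base_channels = 4L,
                                    input_px = 32L)

test_that("network output matches input size with sigmoid range", {
  cfg <- model_config(test_scale = TRUE)  # levels 3, base 8, 64 px
  m <- build_model(cfg, seed = 1)
  x <- random_rgb(64, 64, seed = 1)
  p <- predict_tiles(m, list(x))[[1]]
  expect_identical(dim(p), c(64L, 64L))
  expect_true(all(p > 0 & p < 1))

  # levels = 3 on a 64-px tile is the documented test-scale contract;
  # an input size not divisible by 2^levels must be rejected
  expect_error(model_config(levels = 5L, input_px = 48L), "divisible")
})

test_that("prediction is deterministic and invariant to tile order", {
  m <- build_model(model_config(test_scale = TRUE), seed = 2)
  img <- random_rgb(192, 192, seed = 3)
  p1 <- predict_image(m, img)
  p2 <- predict_image(m, img)
  expect_identical(dim(p1), c(192L, 192L))
  expect_identical(p1, p2)

  # disjoint tiling: each tile is processed independently, so shifting
  # the image by exactly one tile stride shifts the output identically
  shifted <- img[, c(65:192, 1:64), ]
  ps <- predict_image(m, shifted)
  expect_equal(ps[, 1:128], p1[, 65:192], tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(31)
  lv <- 1L; bs <- 2L
  params <- trenchroot:::unet_init_cpp(lv, bs, 3L)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- matrix(rbinom(64, 1, 0.3), 8, 8); storage.mode(y) <- "double"
  for (loss in c("bce", "dice")) {
    res <- trenchroot:::unet_grad_cpp(params, list(x), list(y), lv, bs, 3L,
                                      loss, 0.1)
    eps <- 1e-6
    set.seed(7)
    for (gi in sample(seq_along(params), 4)) {
      g <- params[[gi]]
      nm <- if (g$type == "conv") "W" else "gamma"
      ii <- sample(length(g[[nm]]), 1)
      p2 <- params
      p2[[gi]][[nm]][ii] <- g[[nm]][ii] + eps
      lp <- trenchroot:::unet_grad_cpp(p2, list(x), list(y), lv, bs, 3L,
                                       loss, 0.1)$loss
      p2[[gi]][[nm]][ii] <- g[[nm]][ii] - eps
      lm <- trenchroot:::unet_grad_cpp(p2, list(x), list(y), lv, bs, 3L,
                                       loss, 0.1)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- res$grads[[gi]][[nm]][ii]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("training records history and reduces the loss on a learnable task", {
  # trivially learnable: the mask is a threshold of the red channel
  set.seed(17)
  pairs <- lapply(1:8, function(i) {
    img <- random_rgb(32, 32, seed = 100 + i)
    list(image = img, mask = matrix(as.integer(img[, , 1] > 0.7), 32, 32))
  })
  m <- build_model(tiny_cfg(), seed = 5)
  tcfg <- train_config(epochs = 20L, seed = 5)
  m <- train_model(m, pairs, tcfg)
  expect_equal(nrow(m$history), 20L)
  expect_true(all(is.finite(m$history$loss)))
  expect_lt(m$history$loss[20], m$history$loss[1])
  expect_gt(m$history$dice[20], m$history$dice[1])
})

test_that("training smoke contract: two epochs on four pairs", {
  pairs <- lapply(1:4, function(i)
    list(image = random_rgb(32, 32, seed = i),
         mask = random_mask(32, 32, p = 0.1, seed = i)))
  m <- train_model(build_model(tiny_cfg(), seed = 1), pairs,
                   train_config(epochs = 2L, seed = 1))
  expect_equal(m$history$epoch, 1:2)
  expect_true(all(is.finite(m$history$loss)))
  expect_error(train_model(build_model(tiny_cfg()), list(),
                           train_config(epochs = 1L)), "empty")
  bad <- list(list(image = random_rgb(32, 32), mask = matrix(2L, 32, 32)))
  expect_error(train_model(build_model(tiny_cfg()), bad,
                           train_config(epochs = 1L)), "binary")
})

test_that("checkpoints reload to bit-identical predictions", {
  m <- build_model(model_config(test_scale = TRUE), seed = 9)
  m$train_config <- train_config(epochs = 1L)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, f)
  m2 <- load_model(f)
  x <- random_rgb(64, 64, seed = 4)
  expect_identical(predict_tiles(m, list(x))[[1]],
                   predict_tiles(m2, list(x))[[1]])
})

test_that("binarize applies a strict threshold and validates inputs", {
  expect_identical(binarize(matrix(0.9, 3, 3), 0.5), matrix(1L, 3, 3))
  # ties go to background: strict inequality
  expect_identical(binarize(matrix(0.5, 3, 3), 0.5), matrix(0L, 3, 3))
  expect_error(binarize(matrix(0.5, 2, 2), 1.2), "threshold")
  expect_error(binarize(matrix(1.5, 2, 2), 0.5), "probabilities")
})

test_that("Dice coefficient matches its definition and is symmetric", {
  a <- matrix(0L, 4, 4); a[1, 1:2] <- 1L
  b <- matrix(0L, 4, 4); b[1, 2:3] <- 1L
  expect_equal(dice_coefficient(a, a), 1)
  disj <- matrix(0L, 4, 4); disj[4, 4] <- 1L
  expect_equal(dice_coefficient(a, disj), 0)
  # |T| = 2, |P| = 2, overlap 1: 2*1/(2+2)
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(b, a), 0.5)
  expect_equal(dice_coefficient(matrix(0L, 2, 2), matrix(0L, 2, 2)), 1)
  expect_error(dice_coefficient(a, matrix(0L, 2, 2)), "differ")
})

test_that("a zeroed network predicts the constant sigmoid of its bias", {
  m <- build_model(tiny_cfg(), seed = 3)
  m$params <- lapply(m$params, function(g) {
    if (identical(g$type, "conv")) { g$W[] <- 0; g$b[] <- 0 } else {
      g$gamma[] <- 0; g$beta[] <- 0
    }
    g
  })
  p <- predict_tiles(m, list(random_rgb(32, 32, seed = 8)))[[1]]
  expect_true(all(p == 0.5))
})
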