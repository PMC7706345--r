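#' Network architecture configuration
#'
#' The segmentation model is a U-shaped fully convolutional network:
#' a contracting path and an expansive path joined by skip connections.
#' Three choices depart from the classic design: 3x3 convolutions are
#' zero-padded so tiles keep their size end to end, batch normalization
#' follows every convolution and every down/up-sampling step, and the
#' output is a single sigmoid channel (the only class is "root").
#'
#' The default is 4 resolution levels starting at 64 channels on
#' 256-px tiles. `test_scale = TRUE` gives a desk-scale preset
#' (3 levels, 8 base channels, 64-px tiles) used throughout the test
#' battery, where synthetic imagery is generated at a correspondingly
#' coarser frame resolution.
#'
#' @param levels Encoder/decoder depth (number of 2x poolings).
#' @param base_channels Channels at the top level; doubled per level.
#' @param input_px Tile edge in pixels; must be divisible by `2^levels`.
#' @param in_channels Number of image channels (3 for RGB).
#' @param test_scale If `TRUE`, return the desk-scale preset.
#' @return A `model_config` object.
#' @export
model_config <- function(levels = 4L, base_channels = 64L, input_px = 256L,
                         in_channels = 3L, test_scale = FALSE) {
  if (test_scale) {
    levels <- 3L; base_channels <- 8L; input_px <- 64L
  }
  levels <- as.integer(levels); base_channels <- as.integer(base_channels)
  input_px <- as.integer(input_px); in_channels <- as.integer(in_channels)
  if (input_px %% (2L^levels) != 0L)
    stop(sprintf("input_px (%d) must be divisible by 2^levels (%d)",
                 input_px, 2L^levels))
  structure(list(levels = levels, base_channels = base_channels,
                 input_px = input_px, in_channels = in_channels,
                 batch_norm = TRUE, padding = "zero", out_channels = 1L),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate
#' 0.001 for 500 epochs, iterating every training pair once per epoch.
#' The loss is selectable between binary cross-entropy (default) and
#' soft Dice; the Dice coefficient is always tracked as a metric.
#'
#' @param epochs Number of epochs (each pair seen once per epoch).
#' @param learning_rate Adam step size.
#' @param batch_size Tiles per gradient step.
#' @param loss `"bce"` or `"dice"`.
#' @param threshold Probability cut for [binarize()], in (0, 1).
#' @param seed Seed controlling initialization, shuffling and
#'   augmentation draws.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 500L, learning_rate = 0.001,
                         batch_size = 4L, loss = c("bce", "dice"),
                         threshold = 0.5, seed = 1L) {
  loss <- match.arg(loss)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = "adam", batch_size = as.integer(batch_size),
                 loss = loss, threshold = threshold, seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained network
#'
#' Weights use He initialization from the seeded R random stream, so a
#' given `(cfg, seed)` always produces the same model.
#'
#' @param cfg A [model_config()].
#' @param seed Initialization seed.
#' @return A `unet_model` object.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  set.seed(seed)
  params <- unet_init_cpp(cfg$levels, cfg$base_channels, cfg$in_channels)
  structure(list(params = params, model_config = cfg,
                 train_config = NULL, history = NULL, trained = FALSE),
            class = "unet_model")
}

adam_init <- function(params) {
  lapply(params, function(g) {
    nm <- if (identical(g$type, "conv")) c("W", "b") else c("gamma", "beta")
    st <- lapply(nm, function(n) list(m = g[[n]] * 0, v = g[[n]] * 0))
    names(st) <- nm
    st
  })
}

adam_update <- function(params, grads, state, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
  for (i in seq_along(params)) {
    g <- params[[i]]
    nm <- if (identical(g$type, "conv")) c("W", "b") else c("gamma", "beta")
    for (n in nm) {
      gr <- grads[[i]][[n]]
      st <- state[[i]][[n]]
      st$m <- beta1 * st$m + (1 - beta1) * gr
      st$v <- beta2 * st$v + (1 - beta2) * gr^2
      params[[i]][[n]] <- g[[n]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[i]][[n]] <- st
    }
    if (identical(g$type, "bn")) {
      params[[i]]$running_mean <- grads[[i]]$running_mean
      params[[i]]$running_var <- grads[[i]]$running_var
    }
  }
  list(params = params, state = state)
}

#' Train the segmentation network
#'
#' Iterates every training pair once per epoch in a shuffled order,
#' optionally re-augmenting the pairs each epoch, and records the mean
#' loss and the aggregate (micro) training Dice per epoch. Fully
#' deterministic for a fixed `tcfg$seed`.
#'
#' @param model An untrained or previously trained `unet_model`.
#' @param pairs List of `list(image =, mask =)` training tiles; images
#'   are `input_px x input_px x 3` arrays in \[0, 1\], masks binary
#'   matrices.
#' @param tcfg A [train_config()].
#' @param acfg Optional [augment_config()]; `NULL` trains on the raw
#'   pairs.
#' @param verbose Print a line every `verbose` epochs (0 = silent).
#' @return The trained `unet_model` with a `history` data.frame
#'   (`epoch`, `loss`, `dice`).
#' @export
train_model <- function(model, pairs, tcfg = train_config(), acfg = NULL,
                        verbose = 0L) {
  if (length(pairs) < 1L) stop("empty training set")
  for (p in pairs) {
    if (!all(p$mask %in% c(0L, 1L))) stop("masks must be binary (0/1)")
  }
  cfg <- model$model_config
  set.seed(tcfg$seed)
  state <- adam_init(model$params)
  params <- model$params
  n <- length(pairs)
  hist <- data.frame(epoch = integer(0), loss = numeric(0), dice = numeric(0))
  step <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    ep_pairs <- if (is.null(acfg)) pairs else make_epoch(pairs, acfg, epoch)
    ord <- sample.int(n)
    loss_sum <- 0; nb <- 0L
    inter <- 0; tsum <- 0; psum <- 0
    b0 <- 1L
    while (b0 <= n) {
      idx <- ord[b0:min(b0 + tcfg$batch_size - 1L, n)]
      xs <- lapply(ep_pairs[idx], `[[`, "image")
      ys <- lapply(ep_pairs[idx], function(p) {
        m <- p$mask; storage.mode(m) <- "double"; m
      })
      res <- unet_grad_cpp(params, xs, ys, cfg$levels, cfg$base_channels,
                           cfg$in_channels, tcfg$loss, 0.1)
      step <- step + 1L
      upd <- adam_update(params, res$grads, state, tcfg$learning_rate, step)
      params <- upd$params; state <- upd$state
      loss_sum <- loss_sum + res$loss; nb <- nb + 1L
      for (j in seq_along(idx)) {
        pb <- res$probs[[j]] > tcfg$threshold
        yb <- ys[[j]] > 0.5
        inter <- inter + sum(pb & yb)
        tsum <- tsum + sum(yb); psum <- psum + sum(pb)
      }
      b0 <- b0 + tcfg$batch_size
    }
    dice <- if (tsum + psum == 0) 1 else 2 * inter / (tsum + psum)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = loss_sum / nb,
                                   dice = dice))
    if (verbose > 0L && epoch %% verbose == 0L)
      message(sprintf("epoch %d: loss %.4f, train dice %.3f",
                      epoch, loss_sum / nb, dice))
  }
  model$params <- params
  model$train_config <- tcfg
  model$history <- hist
  model$trained <- TRUE
  model
}

#' Predict root probabilities for a list of tiles
#'
#' @param model A `unet_model`.
#' @param tiles List of `input_px x input_px x 3` arrays.
#' @param chunk Tiles per forward batch (memory control).
#' @return List of probability matrices in \[0, 1\].
#' @export
predict_tiles <- function(model, tiles, chunk = 8L) {
  cfg <- model$model_config
  out <- vector("list", length(tiles))
  b0 <- 1L
  while (b0 <= length(tiles)) {
    idx <- b0:min(b0 + chunk - 1L, length(tiles))
    out[idx] <- unet_predict_cpp(model$params, tiles[idx],
                                 cfg$levels, cfg$base_channels, cfg$in_channels)
    b0 <- b0 + chunk
  }
  out
}

#' Predict a root probability map for a whole trench image
#'
#' The image is split into disjoint tiles, each tile is passed through
#' the network, and the per-tile probability maps are reassembled in
#' the original order. There is no overlap or seam blending.
#'
#' @param model A `unet_model`.
#' @param image A [trench_image()] or `H x W x 3` array; dimensions
#'   must be divisible by the model tile size.
#' @return Probability matrix of the image's spatial size.
#' @export
predict_image <- function(model, image) {
  px <- as_pixels(image)
  grid <- split_tiles(px, model$model_config$input_px)
  probs <- predict_tiles(model, grid$tiles)
  assemble_tiles(probs, grid$grid)
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is root iff its probability strictly exceeds the threshold.
#'
#' @param prob Matrix with values in \[0, 1\].
#' @param threshold Cut point in (0, 1); default 0.5.
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (min(prob) < 0 || max(prob) > 1) stop("probabilities must lie in [0, 1]")
  matrix(as.integer(prob > threshold), nrow(prob), ncol(prob))
}

#' Dice coefficient between two binary masks
#'
#' `2 |T intersect P| / (|T| + |P|)`, where `T` is the manual (truth)
#' segmentation and `P` the prediction. Defined as 1 when both masks
#' are empty. Symmetric in its arguments.
#'
#' @param truth,pred Binary matrices of identical shape (or
#'   [root_mask()] objects).
#' @return A number in \[0, 1\].
#' @export
dice_coefficient <- function(truth, pred) {
  t <- as_pixels(truth); p <- as_pixels(pred)
  if (!identical(dim(t), dim(p))) stop("mask shapes differ")
  if (!all(t %in% c(0L, 1L)) || !all(p %in% c(0L, 1L)))
    stop("masks must be binary (0/1)")
  st <- sum(t); sp <- sum(p)
  if (st + sp == 0) return(1)
  2 * sum(t == 1L & p == 1L) / (st + sp)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single serialized archive holding the weights,
#' both configurations, the training history and a format version.
#' Reloading yields bit-identical predictions.
#'
#' @param model A `unet_model`.
#' @param path Checkpoint path.
#' @return `load_model()` returns the `unet_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  obj <- unclass(model)
  obj$format_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version)) stop("not a model checkpoint: ", path)
  obj$format_version <- NULL
  structure(obj, class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cfg <- x$model_config
  cat(sprintf("<unet_model> levels %d, base %d, tile %d px, %s\n",
              cfg$levels, cfg$base_channels, cfg$input_px,
              if (x$trained) sprintf("trained %d epochs", nrow(x$history))
              else "untrained"))
  invisible(x)
}
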