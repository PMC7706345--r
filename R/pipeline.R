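#' Assemble and validate a pipeline configuration
#'
#' A pipeline configuration bundles the frame geometry, the synthetic
#' generator, augmentation, model and training settings, plus an output
#' directory and a master seed. It can be built from a YAML file (see
#' the `config` block layout in the package vignette) or from an R
#' list. Unknown keys anywhere in the configuration are rejected before
#' any stage runs.
#'
#' @param x Path to a YAML file, or a named list.
#' @return A `pipeline_config` object with elements `frame`, `synth`,
#'   `augment`, `model`, `train`, `n_images`, `split`, `out_dir`,
#'   `seed`.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  known <- c("frame", "synth", "augment", "model", "train",
             "n_images", "split", "out_dir", "seed")
  extra <- setdiff(names(x), known)
  if (length(extra)) stop("unknown configuration keys: ",
                          paste(extra, collapse = ", "))
  build <- function(block, ctor) {
    args <- if (is.null(x[[block]])) list() else x[[block]]
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad)) stop("unknown keys in '", block, "' block: ",
                          paste(bad, collapse = ", "))
    do.call(ctor, args)
  }
  seed <- if (is.null(x$seed)) 1L else as.integer(x$seed)
  cfg <- list(
    frame = build("frame", frame_spec),
    synth = build("synth", synth_config),
    augment = build("augment", augment_config),
    model = build("model", model_config),
    train = build("train", train_config),
    n_images = if (is.null(x$n_images)) 12L else as.integer(x$n_images),
    split = if (is.null(x$split)) c(train = 5/6, val = 1/6) else unlist(x$split),
    out_dir = if (is.null(x$out_dir)) "trenchroot_run" else x$out_dir,
    seed = seed)
  cfg$synth$seed <- seed
  cfg$augment$seed <- seed
  cfg$train$seed <- seed
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

write_csv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_stamped <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the pipeline end to end (or a subset of stages)
#'
#' Stages, in dependency order:
#' * `synth` -- write a synthetic dataset (images, masks, truth table).
#' * `train` -- tile the training images and train the network; writes
#'   `model.ckpt`.
#' * `predict` -- segment the validation images with the checkpoint;
#'   writes predicted masks.
#' * `phenotype` -- measure Depth50 / Width50 / root length on the
#'   predicted validation masks; writes `phenotype.csv`.
#' * `stats` -- Pearson validation of predicted vs truth parameters;
#'   writes `validation.csv`.
#'
#' Each emitted CSV carries the configuration hash as a comment line.
#' Re-running with the same configuration and seed reproduces the
#' artifacts exactly.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Ordered subset of
#'   `c("synth", "train", "predict", "phenotype", "stats")`.
#' @param verbose Log one line per stage.
#' @return Invisibly, a list of artifact paths and (when computed) the
#'   validation statistics.
#' @export
run_pipeline <- function(cfg, stages = c("synth", "train", "predict",
                                         "phenotype", "stats"),
                         verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  hash <- config_hash(cfg)
  out <- cfg$out_dir
  data_dir <- file.path(out, "data")
  ckpt <- file.path(out, "model.ckpt")
  pred_dir <- file.path(out, "pred")
  res <- list(out_dir = out, config_hash = hash)
  say <- function(...) if (verbose) message(sprintf("[%s] %s",
                                                    format(Sys.time(), "%H:%M:%S"),
                                                    sprintf(...)))

  truth_path <- file.path(data_dir, "truth.csv")

  if ("synth" %in% stages) {
    say("synth: %d images -> %s (seed %d)", cfg$n_images, data_dir, cfg$seed)
    generate_dataset(cfg$synth, cfg$n_images, cfg$split, data_dir, cfg$frame)
    res$data_dir <- data_dir
  }

  if ("train" %in% stages) {
    if (!file.exists(truth_path))
      stop("missing artifact: ", truth_path, " (run the 'synth' stage first)")
    truth <- read_csv_stamped(truth_path)
    tr_ids <- truth$image[truth$split == "train"]
    say("train: %d images -> %d tiles", length(tr_ids),
        length(tr_ids) * (cfg$frame$depth_px %/% cfg$model$input_px)^2)
    pairs <- list()
    for (id in tr_ids) {
      img <- read_image(file.path(data_dir, "images", paste0(id, ".png")))
      msk <- read_mask(file.path(data_dir, "masks", paste0(id, ".png")))
      ig <- split_tiles(img, cfg$model$input_px)
      mg <- split_tiles(msk, cfg$model$input_px)
      for (k in seq_along(ig$tiles))
        pairs[[length(pairs) + 1L]] <- list(image = ig$tiles[[k]],
                                            mask = mg$tiles[[k]])
    }
    model <- build_model(cfg$model, seed = cfg$seed)
    model <- train_model(model, pairs, cfg$train, cfg$augment)
    save_model(model, ckpt)
    say("train: done, final loss %.4f, train dice %.3f",
        utils::tail(model$history$loss, 1), utils::tail(model$history$dice, 1))
    res$checkpoint <- ckpt
  }

  if ("predict" %in% stages) {
    if (!file.exists(ckpt))
      stop("missing artifact: ", ckpt, " (run the 'train' stage first)")
    if (!file.exists(truth_path)) stop("missing artifact: ", truth_path)
    model <- load_model(ckpt)
    truth <- read_csv_stamped(truth_path)
    val_ids <- truth$image[truth$split == "val"]
    dir.create(pred_dir, recursive = TRUE, showWarnings = FALSE)
    say("predict: %d validation images", length(val_ids))
    for (id in val_ids) {
      img <- read_image(file.path(data_dir, "images", paste0(id, ".png")))
      prob <- predict_image(model, img)
      mask <- binarize(prob, model$train_config$threshold)
      write_mask(mask, file.path(pred_dir, paste0(id, ".png")))
    }
    res$pred_dir <- pred_dir
  }

  if ("phenotype" %in% stages) {
    if (!dir.exists(pred_dir))
      stop("missing artifact: ", pred_dir, " (run the 'predict' stage first)")
    ids <- sub("\\.png$", "", list.files(pred_dir, pattern = "\\.png$"))
    say("phenotype: %d masks", length(ids))
    rows <- NULL
    for (id in ids) {
      m <- read_mask(file.path(pred_dir, paste0(id, ".png")))
      ph <- phenotype_image(m, hill_col = cfg$frame$hill_column_px,
                            px_per_cm = cfg$frame$resolution_px_per_cm)
      rows <- rbind(rows, data.frame(image = id,
                                     depth50_cm = ph$depth50_cm,
                                     width50_cm = ph$width50_cm,
                                     root_length_cm = ph$total_root_length_cm))
    }
    write_csv_stamped(rows, file.path(out, "phenotype.csv"), hash)
    res$phenotype_csv <- file.path(out, "phenotype.csv")
  }

  if ("stats" %in% stages) {
    ph_path <- file.path(out, "phenotype.csv")
    if (!file.exists(ph_path))
      stop("missing artifact: ", ph_path, " (run the 'phenotype' stage first)")
    if (!file.exists(truth_path)) stop("missing artifact: ", truth_path)
    ph <- read_csv_stamped(ph_path)
    truth <- read_csv_stamped(truth_path)
    merged <- merge(ph, truth, by = "image", suffixes = c("_pred", "_truth"))
    val <- data.frame(
      parameter = c("depth50_cm", "width50_cm"),
      pearson_r = c(pearson(merged$depth50_cm_truth, merged$depth50_cm_pred),
                    pearson(merged$width50_cm_truth, merged$width50_cm_pred)),
      n = nrow(merged))
    write_csv_stamped(val, file.path(out, "validation.csv"), hash)
    say("stats: Depth50 r = %.3f, Width50 r = %.3f over %d images",
        val$pearson_r[1], val$pearson_r[2], val$n[1])
    res$validation <- val
  }

  invisible(res)
}
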