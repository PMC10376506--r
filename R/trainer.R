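# Training protocol: Adam with a stepped learning-rate schedule, fixed
# batch size and epoch count, and the dataset-split protocol (fixed test
# set; training groups of several sizes, several groups per size).

#' Training configuration
#'
#' Defaults reproduce the wing-model protocol: Adam at base learning rate
#' 1e-4, dropped to 1e-5 and 1e-6 at epochs 40 and 55, batch size 8,
#' 80 epochs. Epochs are 0-based: "epoch 40" is the first epoch run at the
#' new rate.
#'
#' @param base_lr base learning rate.
#' @param lr_drops named numeric vector: names are drop epochs, values the
#'   rate from that epoch onward; epochs must be strictly increasing and
#'   below `max_epochs`.
#' @param batch_size samples per optimization step.
#' @param max_epochs total epochs.
#' @param seed RNG seed for shuffling.
#' @param beta1,beta2,eps Adam moment parameters (conventional defaults).
#' @return a `train_config`.
#' @export
train_config <- function(base_lr = 1e-4,
                         lr_drops = c("40" = 1e-5, "55" = 1e-6),
                         batch_size = 8, max_epochs = 80, seed = 1,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(batch_size >= 1, max_epochs >= 1)
  if (length(lr_drops)) {
    de <- as.integer(names(lr_drops))
    if (any(is.na(de)) || is.unsorted(de, strictly = TRUE) ||
        any(de >= max_epochs) || any(de < 0)) {
      stop("lr_drops epochs must be strictly increasing and < max_epochs")
    }
  }
  structure(list(base_lr = base_lr, lr_drops = lr_drops,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = seed,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

#' Desk-scale training configuration for the tiny model
#'
#' Same schedule shape (drops at epochs 40 and 55, each by 10x) but a 1e-2
#' base rate: the tiny variant trains from random initialization on small
#' synthetic images, where the full-scale fine-tuning rate of 1e-4 moves the
#' freshly initialized weights far too little within 80 epochs.
#' @param ... overrides passed to [train_config()].
#' @export
tiny_train_config <- function(...) {
  train_config(base_lr = 1e-2, lr_drops = c("40" = 1e-3, "55" = 1e-4), ...)
}

#' Learning rate at an epoch
#'
#' Piecewise-constant: `base_lr` before the first drop epoch, then each drop
#' value from its epoch onward.
#' @param epoch 0-based epoch index in `[0, max_epochs)`.
#' @param config a [train_config()].
#' @return the learning rate.
#' @export
lr_at <- function(epoch, config) {
  if (epoch < 0 || epoch >= config$max_epochs) {
    stop("epoch out of range [0, ", config$max_epochs, ")")
  }
  lr <- config$base_lr
  if (length(config$lr_drops)) {
    de <- as.integer(names(config$lr_drops))
    past <- which(de <= epoch)
    if (length(past)) lr <- config$lr_drops[[max(past)]]
  }
  lr
}

#' Split a dataset into a test set and training groups
#'
#' Draws the test ids first, then, for every size in `group_sizes`,
#' `groups_per_size` training groups from the remaining pool. Groups of the
#' same size are independent draws (without replacement within a group) and
#' may overlap each other, but never the test set. Deterministic given
#' `seed`.
#'
#' @param index a `wing_dataset`.
#' @param n_test test-set size (default 80).
#' @param group_sizes training-set sizes (default `c(1, 3, 5, 10, 50, 100)`).
#' @param groups_per_size groups per size (default 10).
#' @param seed RNG seed.
#' @return a `split_plan`: list with `test_ids`, `groups` (nested list
#'   `groups[[as.character(size)]][[g]]`), `group_sizes`, `groups_per_size`,
#'   `seed`.
#' @export
make_splits <- function(index, n_test = 80,
                        group_sizes = c(1, 3, 5, 10, 50, 100),
                        groups_per_size = 10, seed = 1) {
  ids <- vapply(index$annotations, function(a) a$image_id, integer(1))
  need <- n_test + max(group_sizes)
  if (length(ids) < need) {
    stop("dataset too small: ", length(ids), " records, need at least ", need)
  }
  set.seed(seed)
  test_ids <- sort(sample(ids, n_test))
  pool <- setdiff(ids, test_ids)
  groups <- list()
  for (gs in group_sizes) {
    groups[[as.character(gs)]] <- lapply(seq_len(groups_per_size),
                                         function(g) sort(sample(pool, gs)))
  }
  structure(list(test_ids = test_ids, groups = groups,
                 group_sizes = group_sizes,
                 groups_per_size = groups_per_size, seed = seed),
            class = "split_plan")
}

new_adam <- function() {
  opt <- new.env(parent = emptyenv())
  opt$m <- list()
  opt$v <- list()
  opt$t <- 0L
  opt
}

adam_step <- function(opt, params, lr, config) {
  opt$t <- opt$t + 1L
  b1 <- config$beta1; b2 <- config$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    m <- opt$m[[nm]]
    v <- opt$v[[nm]]
    if (is.null(m)) { m <- 0 * g; v <- 0 * g }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    p$value <- p$value - lr * (m / c1) / (sqrt(v / c2) + config$eps)
  }
  invisible(opt)
}

zero_grads <- function(model) {
  for (p in model$params) p$grad <- NULL
  invisible(NULL)
}

# Build the (input, target) pair for one annotation.
prepare_sample <- function(ann, image, codec, in_channels,
                           reference_pair = c(1L, 18L)) {
  window <- crop_window(ann$bbox, codec)
  x <- crop_resize(image, window, codec$input_size)
  if (length(dim(x)) == 2 || is.null(dim(x))) {
    x <- array(x, c(codec$input_size, 1))
  }
  if (dim(x)[3] != in_channels) {
    if (dim(x)[3] == 1 && in_channels == 3) {
      x <- array(rep(x, 3), c(codec$input_size, 3))
    } else if (dim(x)[3] == 3 && in_channels == 1) {
      x <- array(rowMeans(matrix(x, ncol = 3)), c(codec$input_size, 1))
    } else {
      stop("cannot match image channels (", dim(x)[3], ") to model input (",
           in_channels, ")")
    }
  }
  pts <- keypoint_matrix(ann$keypoints)
  target <- encode_heatmaps(pts, window, codec)
  list(x = x, target = target$values, window = window, points = pts)
}

# Read images for a set of annotations, either from `images` (a list keyed
# by as.character(image_id)) or from files relative to the dataset root.
fetch_image <- function(ann, index, images = NULL, image_root = NULL) {
  key <- as.character(ann$image_id)
  if (!is.null(images) && !is.null(images[[key]])) return(images[[key]])
  root <- image_root %||%
    (if (!is.na(index$source_path)) dirname(index$source_path) else ".")
  path <- file.path(root, ann$file_name)
  if (!file.exists(path)) stop("cannot read image file: ", path)
  read_wing_image(path)
}

#' Read a wing image (PNG or TIFF), grayscale or RGB
#' @param path image file.
#' @return `(H, W)` matrix or `(H, W, 3)` array with values in `[0, 1]`.
#' @export
read_wing_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF images")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  if (length(dim(img)) == 3 && dim(img)[3] == 2) img <- img[, , 1]
  img
}

#' Train a model on a group of annotated images
#'
#' Runs `max_epochs` epochs of MSE heatmap-regression with Adam under the
#' stepped learning-rate schedule. Only the parameters of groups marked
#' trainable by the applied [transfer_strategy()] are updated; frozen groups
#' (including their normalization statistics) are untouched. Deterministic
#' given the config seed.
#'
#' @param model a `wm_model` (modified in place).
#' @param index a `wing_dataset`.
#' @param ids image ids of the training group.
#' @param config a [train_config()].
#' @param strategy a [transfer_strategy()] (default `TA`, everything
#'   trainable).
#' @param codec a [codec_config()] matching the model input size.
#' @param images optional named list of in-memory images keyed by
#'   `as.character(image_id)`.
#' @param image_root directory for image paths (default: dataset source dir).
#' @param verbose print per-epoch losses.
#' @return list with `model` and `manifest` (seed, strategy, schedule,
#'   per-epoch loss curve, final loss).
#' @export
train <- function(model, index, ids, config = train_config(),
                  strategy = transfer_strategy("TA"),
                  codec = codec_config(), images = NULL, image_root = NULL,
                  verbose = FALSE) {
  stopifnot(length(ids) >= 1)
  if (!all(codec$input_size == model$config$input_size) ||
      !all(codec$heatmap_size == model$config$input_size %/% 4L)) {
    stop("codec input/heatmap sizes must match the model ",
         "(input_size, input_size/4)")
  }
  apply_strategy(model, strategy)
  anns <- Filter(function(a) a$image_id %in% ids, index$annotations)
  if (length(anns) != length(ids)) {
    stop("some training ids are not in the dataset")
  }
  prepared <- lapply(anns, function(a) {
    img <- fetch_image(a, index, images, image_root)
    prepare_sample(a, img, codec, model$config$in_channels)
  })
  names(prepared) <- vapply(anns, function(a) as.character(a$image_id),
                            character(1))

  params <- trainable_params(model)
  opt <- new_adam()
  set.seed(config$seed)
  n <- length(prepared)
  losses <- numeric(config$max_epochs)
  for (epoch in 0:(config$max_epochs - 1)) {
    lr <- lr_at(epoch, config)
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1, n)]
      B <- length(take)
      xb <- array(0, c(model$config$input_size, model$config$in_channels, B))
      tb <- array(0, c(codec$heatmap_size, model$config$num_landmarks, B))
      for (i in seq_len(B)) {
        xb[, , , i] <- prepared[[take[i]]]$x
        tb[, , , i] <- prepared[[take[i]]]$target
      }
      ag_set_recording(TRUE)
      out <- model_forward(model, xb, training = TRUE)
      loss <- op_mse(out, tb)
      lv <- loss$value
      if (!is.finite(lv)) {
        ag_set_recording(FALSE)
        stop(sprintf("non-finite loss at epoch %d (lr %g): %g; aborting",
                     epoch, lr, lv))
      }
      ag_backward(loss)
      ag_set_recording(FALSE)
      adam_step(opt, params, lr, config)
      zero_grads(model)
      ep_loss <- ep_loss + lv
      nb <- nb + 1L
    }
    losses[epoch + 1] <- ep_loss / nb
    if (verbose) {
      message(sprintf("epoch %3d lr %.1e loss %.6g", epoch, lr,
                      losses[epoch + 1]))
    }
  }
  manifest <- list(seed = config$seed, strategy = strategy$name,
                   strategy_mask = strategy$mask,
                   base_lr = config$base_lr, lr_drops = config$lr_drops,
                   batch_size = config$batch_size,
                   max_epochs = config$max_epochs,
                   n_train = n, losses = losses,
                   final_loss = losses[config$max_epochs])
  list(model = model, manifest = manifest)
}
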