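#' Backbone configuration
#'
#' Describes the four-stage multi-resolution network. Branch `b`
#' (0-indexed, high to low resolution) carries `base_width * 2^b` channels at
#' `input/4 / 2^b` resolution. Stage 1 is a single high-resolution branch of
#' bottleneck units; stages 2-4 add one lower branch each and consist of
#' modules of `blocks_per_module` basic units per branch followed by one
#' fusion, so `num_modules` equals the per-stage fusion counts.
#'
#' @param base_width channels of the highest-resolution branch (18 for the
#'   w18 variant used on wing images; 8 for the tiny test variant).
#' @param input_size `c(height, width)` of the network input crop; both must
#'   be divisible by 32.
#' @param in_channels image channels (3 for RGB, 1 for grayscale).
#' @param num_landmarks channels of the heatmap head output.
#' @param stage1_blocks number of bottleneck units in stage 1.
#' @param blocks_per_module basic units per branch per module in stages 2-4.
#' @param num_modules modules (= fusions) per stage for stages 2-4.
#' @param stem_width channels of the two strided stem convolutions.
#' @param bottleneck_expansion channel expansion of the final 1x1 convolution
#'   in a bottleneck unit.
#' @param init_seed RNG seed for weight initialization.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(base_width = 18,
                            input_size = c(256, 256),
                            in_channels = 3,
                            num_landmarks = 36,
                            stage1_blocks = 4,
                            blocks_per_module = 4,
                            num_modules = c(1, 4, 3),
                            stem_width = 2 * base_width,
                            bottleneck_expansion = 4,
                            init_seed = 42) {
  stopifnot(length(input_size) == 2, length(num_modules) == 3,
            base_width >= 1, stage1_blocks >= 1, blocks_per_module >= 1)
  if (any(input_size %% 32 != 0)) {
    stop("input_size dimensions must be divisible by 32, got ",
         paste(input_size, collapse = "x"))
  }
  structure(list(base_width = base_width, input_size = as.integer(input_size),
                 in_channels = in_channels, num_landmarks = num_landmarks,
                 stage1_blocks = stage1_blocks,
                 blocks_per_module = blocks_per_module,
                 num_modules = as.integer(num_modules),
                 stem_width = stem_width,
                 bottleneck_expansion = bottleneck_expansion,
                 init_seed = init_seed),
            class = "backbone_config")
}

#' Configuration used for the 36-landmark wing model
#'
#' The w18 variant: 256x256 input, 64x64x36 heatmap output, 4 bottlenecks in
#' stage 1 and fusion counts (1, 4, 3) in stages 2-4.
#' @param ... overrides passed to [backbone_config()].
#' @export
hwlfc_config <- function(...) backbone_config(...)

#' Tiny desk-scale configuration
#'
#' A reduced variant (base width 8, 64x64 grayscale input, fewer blocks) that
#' trains end-to-end on a CPU in minutes while preserving every structural
#' element of the full network. Default fixture for tests and the synthetic
#' transfer experiments.
#' @param num_landmarks landmark count.
#' @param in_channels image channels.
#' @param ... further overrides passed to [backbone_config()].
#' @export
tiny_config <- function(num_landmarks = 36, in_channels = 1, ...) {
  backbone_config(base_width = 8, input_size = c(64, 64),
                  in_channels = in_channels, num_landmarks = num_landmarks,
                  stage1_blocks = 2, blocks_per_module = 2,
                  num_modules = c(1, 1, 1), stem_width = 16, ...)
}

#' Build the landmark-detection network
#'
#' Assembles stem (two strided 3x3 convolutions to 1/4 resolution), stage 1
#' (bottleneck units), transitions creating one new half-resolution,
#' double-channel branch per stage, stages 2-4 (basic units + fusion
#' modules), a representation head (bilinear upsampling of the three
#' low-resolution branches to the high-resolution grid followed by channel
#' concatenation), and a 1x1 heatmap head with one output channel per
#' landmark. Every parameter belongs to exactly one of the groups
#' `stem, stage1, stage2, stage3, stage4, head`.
#'
#' @param config a [backbone_config()].
#' @return an object of class `wm_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "backbone_config"))
  M <- new_model_registry()
  class(M) <- c("wm_model", "wm_registry")
  M$config <- config
  M$trainable_mask <- c(stem = TRUE, stage1 = TRUE, stage2 = TRUE,
                        stage3 = TRUE, stage4 = TRUE, head = TRUE)

  set.seed(config$init_seed)
  bw <- config$base_width
  sw <- config$stem_width
  exp4 <- config$bottleneck_expansion
  ch <- bw * 2^(0:3)  # per-branch channels

  M$stem <- list(
    c1 = conv_bn(M, "stem.c1", "stem", config$in_channels, sw, 3, stride = 2),
    c2 = conv_bn(M, "stem.c2", "stem", sw, sw, 3, stride = 2))

  s1out <- sw * exp4
  M$stage1 <- lapply(seq_len(config$stage1_blocks), function(i) {
    new_bottleneck(M, paste0("stage1.b", i), "stage1",
                   cin = if (i == 1) sw else s1out, mid = sw,
                   expansion = exp4)
  })

  # Transition into stage k+1: existing branches pass through a
  # channel-matching 3x3 conv only where counts change; the new lowest
  # branch is a strided 3x3 conv from the lowest existing branch.
  M$transitions <- list(
    list(match1 = conv_bn(M, "stage2.t.b1", "stage2", s1out, ch[1], 3),
         new = conv_bn(M, "stage2.t.b2", "stage2", s1out, ch[2], 3, stride = 2)),
    list(new = conv_bn(M, "stage3.t.b3", "stage3", ch[2], ch[3], 3, stride = 2)),
    list(new = conv_bn(M, "stage4.t.b4", "stage4", ch[3], ch[4], 3, stride = 2))
  )

  make_stage <- function(stage_idx, nbranches, nmodules) {
    grp <- paste0("stage", stage_idx)
    lapply(seq_len(nmodules), function(m) {
      blocks <- lapply(seq_len(nbranches), function(b) {
        lapply(seq_len(config$blocks_per_module), function(k) {
          new_basic(M, sprintf("%s.m%d.br%d.b%d", grp, m, b, k), grp, ch[b])
        })
      })
      fus <- new_fusion(M, sprintf("%s.m%d.fuse", grp, m), grp,
                        ch[seq_len(nbranches)])
      list(blocks = blocks, fusion = fus)
    })
  }
  M$stage2 <- make_stage(2, 2, config$num_modules[1])
  M$stage3 <- make_stage(3, 3, config$num_modules[2])
  M$stage4 <- make_stage(4, 4, config$num_modules[3])

  # near-zero head init: standard for heatmap regression heads, so initial
  # predictions are ~0 rather than random-scale (also the scheme used when
  # re-initializing the head after loading a pretrained backbone)
  M$head <- new_conv(M, "head.final", "head", sum(ch), config$num_landmarks,
                     1, bias = TRUE)
  M$head$w$value[] <- stats::rnorm(length(M$head$w$value), 0, 0.001)
  M
}

forward_stage <- function(modules, xs, training) {
  for (mod in modules) {
    xs <- lapply(seq_along(xs), function(b) {
      x <- xs[[b]]
      for (blk in mod$blocks[[b]]) x <- forward_basic(blk, x, training)
      x
    })
    xs <- forward_fusion(mod$fusion, xs, training)
  }
  xs
}

#' Forward pass
#'
#' @param model a `wm_model`.
#' @param x input array `(H, W, channels, N)` matching the configured input
#'   size, or `(H, W, channels)` for a single image.
#' @param training logical; batch-norm uses batch statistics (and updates
#'   running statistics) when `TRUE` and the layer's group is not frozen.
#' @return an `ag_tensor` whose value is the heatmap batch
#'   `(H/4, W/4, num_landmarks, N)`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2] ||
      d[3] != cfg$in_channels) {
    stop(sprintf("input shape (%d,%d,%d) does not match config (%d,%d,%d)",
                 d[1], d[2], d[3], cfg$input_size[1], cfg$input_size[2],
                 cfg$in_channels))
  }
  xt <- ag_tensor(x)
  y <- forward_conv_bn(model$stem$c1, xt, training)
  y <- forward_conv_bn(model$stem$c2, y, training)
  for (blk in model$stage1) y <- forward_bottleneck(blk, y, training)

  tr <- model$transitions
  xs <- list(forward_conv_bn(tr[[1]]$match1, y, training),
             forward_conv_bn(tr[[1]]$new, y, training))
  xs <- forward_stage(model$stage2, xs, training)
  xs <- c(xs, list(forward_conv_bn(tr[[2]]$new, xs[[2]], training)))
  xs <- forward_stage(model$stage3, xs, training)
  xs <- c(xs, list(forward_conv_bn(tr[[3]]$new, xs[[3]], training)))
  xs <- forward_stage(model$stage4, xs, training)

  # representation head: upsample low branches to the high-resolution grid
  hd <- dim(xs[[1]]$value)
  up <- c(xs[1], lapply(xs[-1], op_upsample_bilinear, h_out = hd[1],
                        w_out = hd[2]))
  rep_feat <- op_concat_channels(up)
  forward_conv(model$head, rep_feat)
}

#' Run inference and return plain heatmap arrays
#'
#' @inheritParams model_forward
#' @return numeric array `(H/4, W/4, num_landmarks, N)`.
#' @export
predict_heatmaps <- function(model, x) {
  old <- ag_set_recording(FALSE)
  on.exit(ag_set_recording(old))
  model_forward(model, x, training = FALSE)$value
}

#' Structural summary of a built model
#'
#' @param model a `wm_model`.
#' @return list with `stage1_bottlenecks`, `fusion_counts` (stages 2-4),
#'   `branch_channels`, and per-group parameter counts.
#' @export
model_summary <- function(model) {
  cfg <- model$config
  n_param <- vapply(model$params, function(p) length(p$value), numeric(1))
  list(
    stage1_bottlenecks = length(model$stage1),
    fusion_counts = c(length(model$stage2), length(model$stage3),
                      length(model$stage4)),
    branch_channels = cfg$base_width * 2^(0:3),
    params_per_group = tapply(n_param, model$group_of[names(n_param)], sum)
  )
}

## ---- checkpoint state ------------------------------------------------

#' Extract the model state as a flat named map of arrays
#'
#' Includes trainable parameters and batch-norm running statistics, each
#' tagged with its parameter group, plus a metadata block (configuration and
#' landmark count).
#' @param model a `wm_model`.
#' @return list with `arrays`, `groups`, `meta`.
#' @export
model_state <- function(model) {
  arrays <- lapply(model$params, function(p) p$value)
  groups <- model$group_of
  for (nm in names(model$bn_layers)) {
    ly <- model$bn_layers[[nm]]
    arrays[[paste0(nm, ".running_mean")]] <- ly$rmu
    arrays[[paste0(nm, ".running_var")]] <- ly$rvar
    groups[paste0(nm, ".running_mean")] <- ly$group
    groups[paste0(nm, ".running_var")] <- ly$group
  }
  list(arrays = arrays, groups = groups,
       meta = list(config = model$config,
                   num_landmarks = model$config$num_landmarks))
}

set_model_state <- function(model, state) {
  for (nm in names(state$arrays)) {
    v <- state$arrays[[nm]]
    if (endsWith(nm, ".running_mean") || endsWith(nm, ".running_var")) {
      base <- sub("\\.running_(mean|var)$", "", nm)
      ly <- model$bn_layers[[base]]
      if (is.null(ly)) stop("unknown batch-norm layer in state: ", base)
      if (endsWith(nm, "mean")) ly$rmu <- v else ly$rvar <- v
    } else {
      p <- model$params[[nm]]
      if (is.null(p)) stop("unknown parameter in state: ", nm)
      if (!identical(dim2(p$value), dim2(v))) {
        stop("shape mismatch for ", nm)
      }
      p$value <- v
    }
  }
  invisible(model)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Save / load a model checkpoint
#'
#' Checkpoints are the flat state map of [model_state()] serialized with
#' `saveRDS`. A checkpoint lacking head entries is accepted by
#' [load_pretrained()].
#' @param model a `wm_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model_state(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
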