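# Layer constructors and forwards for the multi-resolution backbone.
# Every constructor registers its parameters in the model registry under a
# group-qualified name so that checkpointing and stage freezing can address
# them ({stem, stage1..stage4, head}).

reg_param <- function(M, name, tensor, group) {
  M$params[[name]] <- tensor
  M$group_of[name] <- group
  tensor
}

new_conv <- function(M, name, group, cin, cout, k, stride = 1,
                     pad = k %/% 2, bias = FALSE) {
  fanin <- k * k * cin
  w <- ag_tensor(matrix(stats::rnorm(fanin * cout, 0, sqrt(2 / fanin)),
                        fanin, cout), param = TRUE)
  reg_param(M, paste0(name, ".w"), w, group)
  b <- NULL
  if (bias) {
    b <- ag_tensor(numeric(cout), param = TRUE)
    reg_param(M, paste0(name, ".b"), b, group)
  }
  list(type = "conv", w = w, b = b, k = k, cin = cin, cout = cout,
       stride = stride, pad = pad)
}

forward_conv <- function(ly, x) {
  op_conv2d(x, ly$w, ly$b, ly$k, ly$cout, ly$stride, ly$pad)
}

new_bn <- function(M, name, group, C) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "bn"
  ly$gamma <- ag_tensor(rep(1, C), param = TRUE)
  ly$beta <- ag_tensor(numeric(C), param = TRUE)
  ly$rmu <- numeric(C)
  ly$rvar <- rep(1, C)
  ly$momentum <- 0.1
  ly$eps <- 1e-5
  ly$frozen <- FALSE
  ly$name <- name
  ly$group <- group
  reg_param(M, paste0(name, ".gamma"), ly$gamma, group)
  reg_param(M, paste0(name, ".beta"), ly$beta, group)
  M$bn_layers[[name]] <- ly
  ly
}

forward_bn <- function(ly, x, training) op_batchnorm(x, ly, training)

conv_bn <- function(M, name, group, cin, cout, k, stride = 1) {
  list(conv = new_conv(M, paste0(name, ".conv"), group, cin, cout, k, stride),
       bn = new_bn(M, paste0(name, ".bn"), group, cout))
}

forward_conv_bn <- function(ly, x, training, relu = TRUE) {
  y <- forward_bn(ly$bn, forward_conv(ly$conv, x), training)
  if (relu) op_relu(y) else y
}

# Bottleneck residual unit: 1x1 reduce, 3x3, 1x1 expand (x4), with a 1x1
# projection on the shortcut when channel counts differ.
new_bottleneck <- function(M, prefix, group, cin, mid, expansion = 4) {
  cout <- mid * expansion
  blk <- list(
    type = "bottleneck", cin = cin, cout = cout,
    c1 = conv_bn(M, paste0(prefix, ".c1"), group, cin, mid, 1),
    c2 = conv_bn(M, paste0(prefix, ".c2"), group, mid, mid, 3),
    c3 = conv_bn(M, paste0(prefix, ".c3"), group, mid, cout, 1)
  )
  if (cin != cout) {
    blk$proj <- conv_bn(M, paste0(prefix, ".proj"), group, cin, cout, 1)
  }
  blk
}

forward_bottleneck <- function(blk, x, training) {
  y <- forward_conv_bn(blk$c1, x, training)
  y <- forward_conv_bn(blk$c2, y, training)
  y <- forward_conv_bn(blk$c3, y, training, relu = FALSE)
  res <- if (is.null(blk$proj)) x else
    forward_conv_bn(blk$proj, x, training, relu = FALSE)
  op_relu(op_add(y, res))
}

# Basic residual unit: two 3x3 convolutions, constant channel count.
new_basic <- function(M, prefix, group, C) {
  list(type = "basic", cin = C, cout = C,
       c1 = conv_bn(M, paste0(prefix, ".c1"), group, C, C, 3),
       c2 = conv_bn(M, paste0(prefix, ".c2"), group, C, C, 3))
}

forward_basic <- function(blk, x, training) {
  y <- forward_conv_bn(blk$c1, x, training)
  y <- forward_conv_bn(blk$c2, y, training, relu = FALSE)
  op_relu(op_add(y, x))
}

#' Construct a multi-resolution fusion unit
#'
#' Exchanges information across parallel branches: every output branch is
#' the sum of all input branches resampled to its resolution. Higher-to-lower
#' paths use chains of strided 3x3 convolutions; lower-to-higher paths use a
#' 1x1 channel-matching convolution followed by bilinear upsampling.
#'
#' @param M model registry (as created by [build_model()]); a bare registry
#'   can be made with `new_model_registry()` for standalone use.
#' @param prefix parameter name prefix.
#' @param group parameter group label.
#' @param channels integer vector of per-branch channel counts, high to low
#'   resolution.
#' @return a fusion unit for [forward_fusion()].
#' @export
new_fusion <- function(M, prefix, group, channels) {
  nb <- length(channels)
  paths <- vector("list", nb)
  for (i in seq_len(nb)) {
    paths[[i]] <- vector("list", nb)
    for (j in seq_len(nb)) {
      if (j == i) next
      nm <- paste0(prefix, ".f", i, "_", j)
      if (j > i) {
        # lower resolution -> upsample
        paths[[i]][[j]] <- list(kind = "up", factor = 2^(j - i),
                                cb = conv_bn(M, nm, group, channels[j],
                                             channels[i], 1))
      } else {
        # higher resolution -> chain of strided convs
        steps <- i - j
        chain <- vector("list", steps)
        cfrom <- channels[j]
        for (s in seq_len(steps)) {
          cto <- if (s == steps) channels[i] else channels[j]
          chain[[s]] <- conv_bn(M, paste0(nm, ".d", s), group, cfrom, cto, 3,
                                stride = 2)
          cfrom <- cto
        }
        paths[[i]][[j]] <- list(kind = "down", chain = chain)
      }
    }
  }
  list(type = "fusion", channels = channels, paths = paths)
}

#' Forward pass of a fusion unit
#'
#' @param fus fusion unit from [new_fusion()].
#' @param xs list of branch tensors (high to low resolution), `ag_tensor`s
#'   or plain arrays.
#' @param training logical, batch-norm mode.
#' @return list of fused branch tensors, shapes unchanged.
#' @export
forward_fusion <- function(fus, xs, training = FALSE) {
  xs <- lapply(xs, function(x) if (inherits(x, "ag_tensor")) x else ag_tensor(x))
  nb <- length(xs)
  stopifnot(nb == length(fus$channels))
  if (nb == 1L) return(xs)
  out <- vector("list", nb)
  for (i in seq_len(nb)) {
    di <- dim(xs[[i]]$value)
    acc <- xs[[i]]
    for (j in seq_len(nb)) {
      if (j == i) next
      p <- fus$paths[[i]][[j]]
      if (p$kind == "up") {
        y <- forward_conv_bn(p$cb, xs[[j]], training, relu = FALSE)
        y <- op_upsample_bilinear(y, di[1], di[2])
      } else {
        y <- xs[[j]]
        for (s in seq_along(p$chain)) {
          y <- forward_conv_bn(p$chain[[s]], y, training,
                               relu = s < length(p$chain))
        }
      }
      acc <- op_add(acc, y)
    }
    out[[i]] <- op_relu(acc)
  }
  out
}

#' Create a bare model registry
#'
#' Holds named parameters, their group labels, and batch-norm layer state.
#' Used internally by [build_model()]; exposed for constructing standalone
#' units (e.g. a fusion module) in isolation.
#' @return an environment of class `wm_registry`.
#' @export
new_model_registry <- function() {
  M <- new.env(parent = emptyenv())
  M$params <- list()
  M$group_of <- character(0)
  M$bn_layers <- list()
  class(M) <- "wm_registry"
  M
}
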