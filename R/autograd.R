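# Minimal reverse-mode autodiff over dense arrays, layout (H, W, C, N).
# Ops append output nodes to a tape while recording; backward walks the tape
# in reverse creation order (which is a topological order) and accumulates
# gradients into parent tensors.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$n <- 0L
.ag$recording <- FALSE
.ag$interp_cache <- new.env(parent = emptyenv())

#' Create an autodiff tensor
#'
#' Wraps a numeric array (or matrix/vector) in a mutable node usable by the
#' network layers. Parameters (`param = TRUE`) keep their accumulated
#' gradient after a backward pass; intermediate nodes are freed as the tape
#' unwinds.
#'
#' @param value numeric array.
#' @param param logical; is this a trainable parameter?
#' @return an object of class `ag_tensor`.
#' @keywords internal
ag_tensor <- function(value, param = FALSE) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$param <- param
  t$bw <- NULL
  t$rec <- FALSE
  class(t) <- "ag_tensor"
  t
}

ag_reset_tape <- function() {
  .ag$tape <- vector("list", 512L)
  .ag$n <- 0L
}

ag_set_recording <- function(on) {
  old <- .ag$recording
  .ag$recording <- isTRUE(on)
  if (isTRUE(on)) ag_reset_tape()
  invisible(old)
}

ag_push <- function(t) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) length(.ag$tape) <- 2L * n
  t$rec <- TRUE
  .ag$tape[[n]] <- t
  .ag$n <- n
  invisible(t)
}

ag_needs_grad <- function(t) isTRUE(t$param) || isTRUE(t$rec)

ag_accum <- function(t, g) {
  if (!ag_needs_grad(t)) return(invisible(NULL))
  t$grad <- if (is.null(t$grad)) g else t$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(inherits(loss, "ag_tensor"))
  loss$grad <- 1
  if (.ag$n > 0L) {
    for (i in seq(.ag$n, 1L)) {
      nd <- .ag$tape[[i]]
      if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
      nd$grad <- NULL
      nd$bw <- NULL
      nd$rec <- FALSE
      .ag$tape[i] <- list(NULL)
    }
  }
  .ag$n <- 0L
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- ops -------------------------------------------------------------

op_conv2d <- function(x, w, b, k, cout, stride, pad) {
  xd <- dim(x$value)
  y <- cpp_conv2d_fwd(x$value, xd, w$value, k, k, cout, stride, pad,
                      if (is.null(b)) NULL else as.numeric(b$value))
  out <- ag_tensor(y)
  if (.ag$recording) {
    xv <- x$value
    out$bw <- function(g) {
      need_dx <- ag_needs_grad(x)
      r <- cpp_conv2d_bwd(xv, xd, w$value, k, k, cout, stride, pad, g,
                          need_dx, !is.null(b))
      ag_accum(w, r$dw)
      if (!is.null(b)) ag_accum(b, as.numeric(r$db))
      if (need_dx) ag_accum(x, r$dx)
    }
    ag_push(out)
  }
  out
}

# Batch normalization over (H, W, N) per channel. `layer` is the bn layer
# environment holding gamma/beta tensors, running statistics, and flags.
op_batchnorm <- function(x, layer, training) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- H * W * N
  # channel-first layout (C, m) so per-channel vectors broadcast by column
  # recycling without rep() allocations
  xt <- matrix(aperm(x$value, c(3, 1, 2, 4)), nrow = C)
  use_batch <- isTRUE(training) && !isTRUE(layer$frozen)
  if (use_batch) {
    mu <- .rowMeans(xt, C, m)
    v <- .rowMeans(xt * xt, C, m) - mu^2
    v[v < 0] <- 0
    mom <- layer$momentum
    layer$rmu <- (1 - mom) * layer$rmu + mom * mu
    layer$rvar <- (1 - mom) * layer$rvar + mom * v
  } else {
    mu <- layer$rmu
    v <- layer$rvar
  }
  istd <- 1 / sqrt(v + layer$eps)
  gam <- as.numeric(layer$gamma$value)
  bet <- as.numeric(layer$beta$value)
  xhat <- (xt - mu) * istd
  yt <- xhat * gam + bet
  y <- aperm(array(yt, c(C, H, W, N)), c(2, 3, 1, 4))
  out <- ag_tensor(y)
  if (.ag$recording) {
    out$bw <- function(g) {
      gm <- matrix(aperm(g, c(3, 1, 2, 4)), nrow = C)
      ag_accum(layer$gamma, .rowSums(gm * xhat, C, m))
      ag_accum(layer$beta, .rowSums(gm, C, m))
      if (ag_needs_grad(x)) {
        dxhat <- gm * gam
        if (use_batch) {
          mdx <- .rowMeans(dxhat, C, m)
          mdxx <- .rowMeans(dxhat * xhat, C, m)
          dxt <- istd * (dxhat - mdx - xhat * mdxx)
        } else {
          dxt <- dxhat * istd
        }
        dx <- aperm(array(dxt, c(C, H, W, N)), c(2, 3, 1, 4))
        ag_accum(x, dx)
      }
    }
    ag_push(out)
  }
  out
}

op_relu <- function(x) {
  y <- x$value
  y[y < 0] <- 0
  out <- ag_tensor(y)
  if (.ag$recording) {
    mask <- x$value > 0
    out$bw <- function(g) {
      if (ag_needs_grad(x)) ag_accum(x, g * mask)
    }
    ag_push(out)
  }
  out
}

op_add <- function(a, b) {
  out <- ag_tensor(a$value + b$value)
  if (.ag$recording) {
    out$bw <- function(g) {
      ag_accum(a, g)
      ag_accum(b, g)
    }
    ag_push(out)
  }
  out
}

#' Linear interpolation matrix between two 1-D grids
#'
#' Rows map output sample positions (half-pixel convention, edges clamped)
#' to weighted pairs of input samples. Used for bilinear feature upsampling
#' and image crop-resizing.
#' @keywords internal
interp_matrix <- function(n_out, n_in) {
  key <- paste0(n_out, "_", n_in)
  hit <- .ag$interp_cache[[key]]
  if (!is.null(hit)) return(hit)
  M <- matrix(0, n_out, n_in)
  if (n_out == n_in) {
    diag(M) <- 1
  } else {
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    lo <- floor(pos)
    w <- pos - lo
    for (i in seq_len(n_out)) {
      l <- lo[i]; h <- l + 1
      wl <- 1 - w[i]; wh <- w[i]
      if (l < 0) { l <- 0; wl <- 1; h <- 0; wh <- 0 }
      if (h > n_in - 1) { h <- n_in - 1; if (l > n_in - 1) l <- n_in - 1 }
      M[i, l + 1] <- M[i, l + 1] + wl
      M[i, h + 1] <- M[i, h + 1] + wh
    }
  }
  .ag$interp_cache[[key]] <- M
  M
}

# Apply separable row/column interpolation matrices to (H, W, C, N).
resample_hw <- function(x, Lh, Lw) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Ho <- nrow(Lh); Wo <- nrow(Lw)
  a <- Lh %*% matrix(x, nrow = H)            # (Ho, W*C*N)
  a <- array(a, c(Ho, W, C, N))
  a <- aperm(a, c(2, 1, 3, 4))               # (W, Ho, C, N)
  b <- Lw %*% matrix(a, nrow = W)            # (Wo, Ho*C*N)
  b <- array(b, c(Wo, Ho, C, N))
  aperm(b, c(2, 1, 3, 4))                    # (Ho, Wo, C, N)
}

op_upsample_bilinear <- function(x, h_out, w_out) {
  d <- dim(x$value)
  Lh <- interp_matrix(h_out, d[1])
  Lw <- interp_matrix(w_out, d[2])
  out <- ag_tensor(resample_hw(x$value, Lh, Lw))
  if (.ag$recording) {
    out$bw <- function(g) {
      if (ag_needs_grad(x)) ag_accum(x, resample_hw(g, t(Lh), t(Lw)))
    }
    ag_push(out)
  }
  out
}

op_concat_channels <- function(xs) {
  d1 <- dim(xs[[1]]$value)
  H <- d1[1]; W <- d1[2]; N <- d1[4]
  cs <- vapply(xs, function(t) dim(t$value)[3], integer(1))
  y <- array(0, c(H, W, sum(cs), N))
  at <- 0L
  for (i in seq_along(xs)) {
    y[, , at + seq_len(cs[i]), ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  out <- ag_tensor(y)
  if (.ag$recording) {
    out$bw <- function(g) {
      at <- 0L
      for (i in seq_along(xs)) {
        if (ag_needs_grad(xs[[i]])) {
          ag_accum(xs[[i]], g[, , at + seq_len(cs[i]), , drop = FALSE])
        }
        at <- at + cs[i]
      }
    }
    ag_push(out)
  }
  out
}

op_mse <- function(pred, target) {
  diff <- pred$value - target
  out <- ag_tensor(mean(diff^2))
  if (.ag$recording) {
    out$bw <- function(g) {
      if (ag_needs_grad(pred)) ag_accum(pred, g * 2 * diff / length(diff))
    }
    ag_push(out)
  }
  out
}
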