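# Gaussian heatmap codec: landmark coordinates <-> per-landmark score maps
# on a bbox-derived crop, plus the MSE training loss.

#' Heatmap codec configuration
#'
#' @param input_size `c(height, width)` of the network input crop, pixels.
#' @param heatmap_size `c(H, W)` of the target/predicted heatmaps; input
#'   dimensions must be integer multiples of the heatmap dimensions (default
#'   256x256 over 64x64, the 4x stride of the high-resolution branch).
#' @param sigma Gaussian standard deviation in heatmap pixels.
#' @param refine sub-pixel decoding refinement: `"gaussian"` (default; fits
#'   a parabola to the log-scores around the peak, exact for clean Gaussian
#'   targets), `"quarter"` (0.25-pixel shift toward the larger neighbor), or
#'   `"none"` (plain argmax).
#' @param pad_frac bbox padding fraction when deriving the crop window.
#' @return a `codec_config`.
#' @export
codec_config <- function(input_size = c(256, 256), heatmap_size = c(64, 64),
                         sigma = 2, refine = c("gaussian", "quarter", "none"),
                         pad_frac = 0.25) {
  refine <- match.arg(refine)
  stopifnot(sigma > 0, length(input_size) == 2, length(heatmap_size) == 2)
  if (any(input_size %% heatmap_size != 0)) {
    stop("input_size must be integer multiples of heatmap_size")
  }
  structure(list(input_size = as.integer(input_size),
                 heatmap_size = as.integer(heatmap_size), sigma = sigma,
                 refine = refine, pad_frac = pad_frac),
            class = "codec_config")
}

#' Derive the crop window from a bounding box
#'
#' Pads the bbox by `pad_frac` on each side, then expands the shorter side
#' to the input aspect ratio, keeping the center. The window may extend
#' beyond the image; sampling clamps to the edge.
#'
#' @param bbox `c(x_min, y_min, w, h)` in image pixels.
#' @param config a [codec_config()].
#' @return list `(x0, y0, w, h)` in image pixels.
#' @export
crop_window <- function(bbox, config) {
  if (bbox[3] <= 0 || bbox[4] <= 0) stop("bbox has non-positive size")
  cx <- bbox[1] + bbox[3] / 2
  cy <- bbox[2] + bbox[4] / 2
  w <- bbox[3] * (1 + 2 * config$pad_frac)
  h <- bbox[4] * (1 + 2 * config$pad_frac)
  aspect <- config$input_size[2] / config$input_size[1]  # w / h
  if (w / h < aspect) w <- h * aspect else h <- w / aspect
  list(x0 = cx - w / 2, y0 = cy - h / 2, w = w, h = h)
}

# Continuous mapping image <-> heatmap grid (half-pixel convention: heatmap
# cell u has its center at image x = x0 + (u + 0.5) * w / W).
image_to_grid <- function(x, y, window, grid_hw) {
  list(u = (x - window$x0) * grid_hw[2] / window$w - 0.5,
       v = (y - window$y0) * grid_hw[1] / window$h - 0.5)
}

grid_to_image <- function(u, v, window, grid_hw) {
  list(x = window$x0 + (u + 0.5) * window$w / grid_hw[2],
       y = window$y0 + (v + 0.5) * window$h / grid_hw[1])
}

#' Encode landmarks as Gaussian target heatmaps
#'
#' Channel c holds `exp(-((u-u_c)^2 + (v-v_c)^2) / (2 sigma^2))` on the
#' heatmap grid, rescaled so that the maximum over the grid is exactly 1 (at
#' the cell nearest the landmark). A landmark whose grid position falls
#' outside the heatmap yields an all-zero channel with a warning.
#'
#' @param landmarks a `landmark_set` or K x 2 matrix, image-pixel coords.
#' @param window crop window from [crop_window()] (or a bbox vector, from
#'   which the window is derived).
#' @param config a [codec_config()].
#' @return a `heatmap_stack`: list with `values` array `(H, W, K)`, `window`,
#'   and `scale` (image pixels per heatmap pixel, `c(sx, sy)`).
#' @export
encode_heatmaps <- function(landmarks, window, config) {
  pts <- if (inherits(landmarks, "landmark_set")) landmarks$points
         else as.matrix(landmarks)
  if (is.numeric(window) && length(window) == 4) {
    window <- crop_window(window, config)
  }
  H <- config$heatmap_size[1]; W <- config$heatmap_size[2]
  K <- nrow(pts)
  g <- image_to_grid(pts[, 1], pts[, 2], window, c(H, W))
  vals <- array(0, c(H, W, K))
  us <- 0:(W - 1); vs <- 0:(H - 1)
  s2 <- 2 * config$sigma^2
  n_out <- 0L
  for (k in seq_len(K)) {
    uc <- g$u[k]; vc <- g$v[k]
    if (uc < -0.5 || uc > W - 0.5 || vc < -0.5 || vc > H - 0.5) {
      n_out <- n_out + 1L
      next
    }
    ch <- exp(-(outer((vs - vc)^2, (us - uc)^2, "+")) / s2)
    vals[, , k] <- ch / max(ch)
  }
  if (n_out > 0) {
    warning(n_out, " landmark(s) outside the crop; channel(s) left zero")
  }
  structure(list(values = vals, window = window,
                 scale = c(window$w / W, window$h / H)),
            class = "heatmap_stack")
}

#' Decode heatmaps back to image coordinates
#'
#' Per channel: the maximum cell (ties broken by the first cell in row-major
#' order), optionally refined to sub-pixel precision, mapped back to image
#' pixels through the crop window. An all-zero (or non-finite) channel is
#' flagged undecodable and reported at the crop center.
#'
#' @param stack a `heatmap_stack` (predicted values allowed), or an
#'   `(H, W, K)` array plus an explicit `window`.
#' @param config a [codec_config()].
#' @param window crop window, required if `stack` is a bare array.
#' @return list with `points` (K x 2 image-pixel matrix) and `undecodable`
#'   (logical K).
#' @export
decode_heatmaps <- function(stack, config, window = NULL) {
  if (inherits(stack, "heatmap_stack")) {
    vals <- stack$values
    window <- stack$window
  } else {
    vals <- stack
    if (is.null(window)) stop("window required when decoding a bare array")
    if (is.numeric(window) && length(window) == 4) {
      window <- crop_window(window, config)
    }
  }
  d <- dim(vals)
  H <- d[1]; W <- d[2]; K <- d[3]
  pts <- matrix(NA_real_, K, 2)
  undec <- logical(K)
  for (k in seq_len(K)) {
    ch <- vals[, , k]
    if (!all(is.finite(ch)) || max(ch) <= 0) {
      undec[k] <- TRUE
      pts[k, ] <- c(window$x0 + window$w / 2, window$y0 + window$h / 2)
      next
    }
    # row-major tie-break: scan rows top to bottom, columns left to right
    idx <- which.max(t(ch))
    v0 <- (idx - 1) %/% W
    u0 <- (idx - 1) %% W
    off <- c(0, 0)
    if (config$refine != "none") {
      off <- c(refine_axis(ch, v0, u0, axis = "u", W = W, H = H,
                           mode = config$refine),
               refine_axis(ch, v0, u0, axis = "v", W = W, H = H,
                           mode = config$refine))
    }
    xy <- grid_to_image(u0 + off[1], v0 + off[2], window, c(H, W))
    pts[k, ] <- c(xy$x, xy$y)
  }
  list(points = pts, undecodable = undec)
}

# Sub-pixel offset along one axis at the peak cell (0-based v0, u0).
refine_axis <- function(ch, v0, u0, axis, W, H, mode) {
  if (axis == "u") {
    if (u0 == 0 || u0 == W - 1) return(0)
    lo <- ch[v0 + 1, u0]; mid <- ch[v0 + 1, u0 + 1]; hi <- ch[v0 + 1, u0 + 2]
  } else {
    if (v0 == 0 || v0 == H - 1) return(0)
    lo <- ch[v0, u0 + 1]; mid <- ch[v0 + 1, u0 + 1]; hi <- ch[v0 + 2, u0 + 1]
  }
  if (mode == "quarter") {
    if (hi > lo) return(0.25)
    if (lo > hi) return(-0.25)
    return(0)
  }
  # parabolic fit to log scores; exact for Gaussian-shaped channels
  eps <- 1e-12
  if (lo <= 0 || hi <= 0 || mid <= 0) {
    if (hi > lo) return(0.25) else if (lo > hi) return(-0.25) else return(0)
  }
  a <- log(lo + eps); b <- log(mid + eps); cc <- log(hi + eps)
  den <- a - 2 * b + cc
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  off <- 0.5 * (a - cc) / den
  max(-0.5, min(0.5, off))
}

#' Mean squared error between heatmap stacks
#'
#' Mean over all elements of squared differences; zero iff identical.
#' @param predicted,target `heatmap_stack`s or numeric arrays of identical
#'   shape.
#' @return non-negative scalar.
#' @export
mse_loss <- function(predicted, target) {
  a <- if (inherits(predicted, "heatmap_stack")) predicted$values else predicted
  b <- if (inherits(target, "heatmap_stack")) target$values else target
  if (!identical(dim(a), dim(b))) {
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  mean((a - b)^2)
}

#' Crop and resize an image region to the network input size
#'
#' Bilinear sampling of the window region (half-pixel convention, edges
#' clamped for windows extending beyond the image).
#'
#' @param image `(H, W)` matrix or `(H, W, 3)` array, values in `[0, 1]`.
#' @param window crop window from [crop_window()].
#' @param out_size `c(height, width)` of the output.
#' @return array of size `out_size` (same channel count as input).
#' @export
crop_resize <- function(image, window, out_size) {
  dm <- dim(image)
  H <- dm[1]; W <- dm[2]
  src_y <- window$y0 + (seq_len(out_size[1]) - 0.5) * window$h / out_size[1] - 0.5
  src_x <- window$x0 + (seq_len(out_size[2]) - 0.5) * window$w / out_size[2] - 0.5
  Lh <- sample_matrix(src_y, H)
  Lw <- sample_matrix(src_x, W)
  if (length(dm) == 2) {
    Lh %*% image %*% t(Lw)
  } else {
    out <- array(0, c(out_size, dm[3]))
    for (c in seq_len(dm[3])) out[, , c] <- Lh %*% image[, , c] %*% t(Lw)
    out
  }
}

# Interpolation matrix for arbitrary (clamped) source positions.
sample_matrix <- function(pos, n_in) {
  pos <- pmin(pmax(pos, 0), n_in - 1)
  lo <- floor(pos)
  hi <- pmin(lo + 1, n_in - 1)
  w <- pos - lo
  M <- matrix(0, length(pos), n_in)
  for (i in seq_along(pos)) {
    M[i, lo[i] + 1] <- M[i, lo[i] + 1] + (1 - w[i])
    M[i, hi[i] + 1] <- M[i, hi[i] + 1] + w[i]
  }
  M
}
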