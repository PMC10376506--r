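# Normalized mean error (NME) evaluation: per-sample, per-landmark, and
# group-aggregated summaries, plus prediction overlay rendering.

#' Normalized mean error between two landmark sets
#'
#' `NME = (1/K) * sum_i ||p_i - p_hat_i|| / d`, where `d` is the
#' specimen-specific reference distance (here, landmark 1 to landmark 18 of
#' the ground truth). Per-landmark normalized errors are returned alongside
#' the mean.
#'
#' @param predicted,truth K x 2 matrices or `landmark_set`s.
#' @param d reference distance in pixels (> 0).
#' @return list with `mean` and `per_landmark` (length K).
#' @export
nme <- function(predicted, truth, d) {
  p <- if (inherits(predicted, "landmark_set")) predicted$points
       else as.matrix(predicted)
  q <- if (inherits(truth, "landmark_set")) truth$points else as.matrix(truth)
  if (!identical(dim(p), dim(q))) {
    stop("landmark count mismatch: ", nrow(p), " vs ", nrow(q))
  }
  if (!is.finite(d) || d <= 0) stop("reference distance d must be > 0")
  per <- sqrt(rowSums((p - q)^2)) / d
  list(mean = mean(per), per_landmark = per)
}

#' Evaluate a model on a test set
#'
#' For each test annotation the ground-truth reference distance `d` is
#' computed from its own reference landmark pair; predictions come either
#' from the model (crop, forward, decode) or from a supplied `predict_fn`.
#' Samples with a degenerate (zero) reference distance are excluded with a
#' warning. Undecodable landmarks contribute their crop-center fallback
#' position rather than being dropped.
#'
#' @param model a `wm_model` (ignored when `predict_fn` is given).
#' @param index a `wing_dataset` of test annotations.
#' @param codec a [codec_config()] matching the model.
#' @param ids optional subset of image ids to evaluate (default: all).
#' @param predict_fn optional `function(image, annotation)` returning a
#'   K x 2 matrix of predicted image coordinates.
#' @param reference_pair 1-based index pair for `d` (default `c(1, 18)`).
#' @param images optional in-memory image list keyed by id.
#' @param image_root image directory (default: dataset source dir).
#' @param metadata list stored in the report (strategy, group size, ...).
#' @return an `nme_report`: `per_landmark_nme` (K), `mean_nme`,
#'   `per_sample_nme`, `reference_distances`, `n_excluded`, `metadata`.
#' @export
evaluate_model <- function(model, index, codec = codec_config(), ids = NULL,
                           predict_fn = NULL, reference_pair = c(1L, 18L),
                           images = NULL, image_root = NULL,
                           metadata = list()) {
  anns <- index$annotations
  if (!is.null(ids)) {
    anns <- Filter(function(a) a$image_id %in% ids, anns)
  }
  stopifnot(length(anns) >= 1)
  K <- anns[[1]]$num_keypoints
  per_sample <- numeric(0)
  dists <- numeric(0)
  per_lm <- matrix(0, 0, K)
  n_excluded <- 0L
  for (ann in anns) {
    truth <- annotation_landmarks(ann, reference_pair)
    d <- tryCatch(reference_distance(truth), error = function(e) NA_real_)
    if (is.na(d)) {
      n_excluded <- n_excluded + 1L
      warning("sample ", ann$image_id,
              " excluded: degenerate reference distance")
      next
    }
    img <- if (is.null(predict_fn)) {
      fetch_image(ann, index, images, image_root)
    } else {
      tryCatch(fetch_image(ann, index, images, image_root),
               error = function(e) NULL)
    }
    if (is.null(predict_fn)) {
      ps <- prepare_sample(ann, img, codec, model$config$in_channels)
      hm <- predict_heatmaps(model, array(ps$x, c(dim(ps$x), 1)))
      dec <- decode_heatmaps(hm[, , , 1], codec, window = ps$window)
      pred <- dec$points
    } else {
      pred <- predict_fn(img, ann)
    }
    r <- nme(pred, truth$points, d)
    per_sample <- c(per_sample, r$mean)
    dists <- c(dists, d)
    per_lm <- rbind(per_lm, r$per_landmark)
  }
  if (!length(per_sample)) stop("no evaluable samples")
  structure(list(per_landmark_nme = colMeans(per_lm),
                 mean_nme = mean(per_sample),
                 per_sample_nme = per_sample,
                 reference_distances = dists,
                 n_excluded = n_excluded,
                 metadata = metadata),
            class = "nme_report")
}

#' @export
print.nme_report <- function(x, ...) {
  cat(sprintf("nme_report: %d samples, mean NME %.4f (per-landmark %.4f-%.4f)\n",
              length(x$per_sample_nme), x$mean_nme,
              min(x$per_landmark_nme), max(x$per_landmark_nme)))
  invisible(x)
}

#' Aggregate NME reports across training groups
#'
#' Per (strategy, group size): mean and sample (n-1 denominator) standard
#' deviation of the reports' mean NMEs, as plotted in training-set-size
#' sweeps. Reports must carry `metadata$strategy` and `metadata$group_size`.
#'
#' @param reports list of `nme_report`s.
#' @return data.frame with columns `strategy`, `group_size`, `n_groups`,
#'   `mean_nme`, `sd_nme`; per-landmark means are attached as the
#'   `"per_landmark"` attribute (one row per table row).
#' @export
aggregate_groups <- function(reports) {
  if (!length(reports)) stop("no reports to aggregate")
  strat <- vapply(reports, function(r) r$metadata$strategy %||% "?",
                  character(1))
  gsize <- vapply(reports, function(r) as.numeric(r$metadata$group_size %||% NA),
                  numeric(1))
  means <- vapply(reports, function(r) r$mean_nme, numeric(1))
  key <- paste(strat, gsize)
  uk <- unique(key[order(strat, gsize)])
  K <- length(reports[[1]]$per_landmark_nme)
  rows <- lapply(uk, function(k) {
    sel <- key == k
    data.frame(strategy = strat[sel][1], group_size = gsize[sel][1],
               n_groups = sum(sel), mean_nme = mean(means[sel]),
               sd_nme = if (sum(sel) > 1) stats::sd(means[sel]) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  plm <- t(vapply(uk, function(k) {
    sel <- which(key == k)
    colMeans(do.call(rbind, lapply(reports[sel],
                                   function(r) r$per_landmark_nme)))
  }, numeric(K)))
  attr(out, "per_landmark") <- plm
  out
}

#' Render an overlay of annotated and predicted landmarks
#'
#' Writes a PNG with ground-truth landmarks in red and predictions in blue,
#' each labeled with its 1-based landmark index.
#'
#' @param image `(H, W)` matrix or `(H, W, 3)` array in `[0, 1]`.
#' @param truth,predicted K x 2 matrices or `landmark_set`s.
#' @param path output PNG path.
#' @param radius marker radius in pixels.
#' @return the path, invisibly.
#' @export
render_overlay <- function(image, truth, predicted, path, radius = 3) {
  tp <- if (inherits(truth, "landmark_set")) truth$points else as.matrix(truth)
  pp <- if (inherits(predicted, "landmark_set")) predicted$points
        else as.matrix(predicted)
  if (!nrow(tp) || !nrow(pp)) stop("empty landmark set")
  dm <- dim(image)
  H <- dm[1]; W <- dm[2]
  rgb <- if (length(dm) == 3) image else array(rep(image, 3), c(H, W, 3))
  rgb <- draw_markers(rgb, tp, c(1, 0, 0), radius)
  rgb <- draw_markers(rgb, pp, c(0, 0.2, 1), radius)
  png::writePNG(rgb, path)
  invisible(path)
}

draw_markers <- function(rgb, pts, col, radius) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  for (k in seq_len(nrow(pts))) {
    cx <- pts[k, 1]; cy <- pts[k, 2]
    rs <- max(1, floor(cy - radius)):min(H, ceiling(cy + radius) + 1)
    cs <- max(1, floor(cx - radius)):min(W, ceiling(cx + radius) + 1)
    for (r in rs) for (cc in cs) {
      if ((cc - 0.5 - cx)^2 + (r - 0.5 - cy)^2 <= radius^2) {
        rgb[r, cc, ] <- col
      }
    }
    rgb <- draw_number(rgb, k, cx + radius + 1, cy - radius - 6, col)
  }
  rgb
}

# 3x5 bitmap digits for index labels.
.digit_font <- list(
  "0" = c(7,5,5,5,7), "1" = c(2,6,2,2,7), "2" = c(7,1,7,4,7),
  "3" = c(7,1,7,1,7), "4" = c(5,5,7,1,1), "5" = c(7,4,7,1,7),
  "6" = c(7,4,7,5,7), "7" = c(7,1,2,2,2), "8" = c(7,5,7,5,7),
  "9" = c(7,5,7,1,7))

draw_number <- function(rgb, num, x, y, col) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  digits <- strsplit(as.character(num), "")[[1]]
  for (di in seq_along(digits)) {
    rows <- .digit_font[[digits[di]]]
    for (r in 1:5) for (cc in 1:3) {
      if (bitwAnd(rows[r], bitwShiftL(1L, 3L - cc)) != 0) {
        rr <- round(y) + r
        ccx <- round(x) + (di - 1) * 4 + cc
        if (rr >= 1 && rr <= H && ccx >= 1 && ccx <= W) rgb[rr, ccx, ] <- col
      }
    }
  }
  rgb
}
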