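test_that("nme matches closed forms and a brute-force loop oracle", {
  set.seed(8)
  truth <- matrix(runif(72, 0, 100), 36, 2)
  expect_equal(nme(truth, truth, d = 50)$mean, 0)

  # K = 1 offset by exactly d along one axis
  expect_equal(nme(rbind(c(10 + 25, 5)), rbind(c(10, 5)), d = 25)$mean, 1)

  for (i in 1:200) {
    K <- sample(2:40, 1)
    p <- matrix(rnorm(2 * K, 0, 30), K, 2)
    q <- matrix(rnorm(2 * K, 0, 30), K, 2)
    d <- runif(1, 1, 100)
    acc <- 0
    per <- numeric(K)
    for (k in 1:K) {
      per[k] <- sqrt((p[k, 1] - q[k, 1])^2 + (p[k, 2] - q[k, 2])^2) / d
      acc <- acc + per[k]
    }
    r <- nme(p, q, d)
    expect_equal(r$mean, acc / K, tolerance = 1e-12)
    expect_equal(r$per_landmark, per, tolerance = 1e-12)
  }

  expect_error(nme(truth, truth, d = 0), "must be > 0")
  expect_error(nme(truth[1:5, ], truth, d = 1), "mismatch")
})

test_that("nme is invariant to joint scaling and translation", {
  set.seed(3)
  p <- matrix(runif(20, 0, 50), 10, 2)
  q <- p + matrix(rnorm(20), 10, 2)
  d <- 12.5
  base <- nme(p, q, d)$mean
  for (s in c(0.1, 2, 117)) {
    expect_equal(nme(p * s, q * s, d * s)$mean, base, tolerance = 1e-12)
  }
  shift <- c(33, -7)
  expect_equal(nme(p + rep(shift, each = 10), q + rep(shift, each = 10),
                   d)$mean, base, tolerance = 1e-12)
})

test_that("a ground-truth oracle predictor scores zero and a 0.05 d offset scores 0.05", {
  ds <- make_wings(10, seed = 14, render = FALSE)
  codec <- tiny_codec()

  oracle <- function(image, ann) wingmark:::keypoint_matrix(ann$keypoints)
  r0 <- evaluate_model(NULL, ds$index, codec, predict_fn = oracle)
  expect_equal(r0$mean_nme, 0)
  expect_equal(max(r0$per_landmark_nme), 0)

  offset <- function(image, ann) {
    pts <- wingmark:::keypoint_matrix(ann$keypoints)
    d <- reference_distance(annotation_landmarks(ann))
    pts + cbind(rep(0.05 * d, nrow(pts)), 0)
  }
  r5 <- evaluate_model(NULL, ds$index, codec, predict_fn = offset)
  expect_equal(r5$mean_nme, 0.05, tolerance = 1e-10)
  expect_equal(unname(r5$per_landmark_nme), rep(0.05, 36), tolerance = 1e-10)

  # internal consistency: landmark-wise and sample-wise averages agree
  expect_equal(mean(r5$per_landmark_nme), r5$mean_nme, tolerance = 1e-12)
  expect_equal(mean(r5$per_sample_nme), r5$mean_nme, tolerance = 1e-12)
})

test_that("group aggregation computes n-1 standard deviations and is order-invariant", {
  mk <- function(m, gs = 3, strat = "TS") {
    structure(list(per_landmark_nme = rep(m, 36), mean_nme = m,
                   per_sample_nme = rep(m, 5), reference_distances = rep(1, 5),
                   n_excluded = 0L,
                   metadata = list(strategy = strat, group_size = gs)),
              class = "nme_report")
  }
  ten <- lapply(rep(0.031, 10), mk)
  agg <- aggregate_groups(ten)
  expect_equal(agg$mean_nme, 0.031)
  expect_equal(agg$sd_nme, 0)
  expect_equal(agg$n_groups, 10)

  two <- list(mk(0.02), mk(0.04))
  agg2 <- aggregate_groups(two)
  expect_equal(agg2$mean_nme, 0.03)
  expect_equal(agg2$sd_nme, sqrt(((0.02 - 0.03)^2 + (0.04 - 0.03)^2) / 1))

  mixed <- c(lapply(c(0.02, 0.04), mk),
             lapply(c(0.1, 0.12), mk, gs = 1))
  expect_equal(aggregate_groups(mixed), aggregate_groups(rev(mixed)))
  expect_error(aggregate_groups(list()), "no reports")
})

test_that("overlay rendering writes both marker colors and rejects empty sets", {
  img <- matrix(0, 96, 96)  # black canvas
  truth <- cbind(seq(15, 75, length.out = 5), rep(25, 5))
  pred <- cbind(seq(15, 75, length.out = 5), rep(65, 5))
  path <- tempfile(fileext = ".png")
  render_overlay(img, truth, pred, path)
  expect_true(file.exists(path))
  out <- png::readPNG(path)
  red <- sum(out[, , 1] > 0.9 & out[, , 2] < 0.1 & out[, , 3] < 0.1)
  blue <- sum(out[, , 3] > 0.9 & out[, , 1] < 0.1)
  expect_gte(red, 5 * 9)   # at least 5 markers' worth of red pixels
  expect_gte(blue, 5 * 9)

  path2 <- tempfile(fileext = ".png")
  expect_error(render_overlay(img, truth[0, , drop = FALSE], pred, path2),
               "empty")
  expect_false(file.exists(path2))
})

test_that("degenerate reference distances exclude the sample with a warning", {
  ds <- make_wings(3, seed = 4, render = FALSE)
  # collapse the reference pair of one record
  a <- ds$index$annotations[[2]]
  a$keypoints[(18 - 1) * 3 + 1:2] <- a$keypoints[1:2]
  ds$index$annotations[[2]] <- a
  oracle <- function(image, ann) wingmark:::keypoint_matrix(ann$keypoints)
  expect_warning(
    r <- evaluate_model(NULL, ds$index, tiny_codec(), predict_fn = oracle),
    "degenerate")
  expect_equal(r$n_excluded, 1L)
  expect_length(r$per_sample_nme, 2)
})
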