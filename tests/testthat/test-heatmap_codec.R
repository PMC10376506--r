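test_that("encoded channels match a dense Gaussian loop oracle with peak 1", {
  cc <- codec_config(input_size = c(64, 64), heatmap_size = c(16, 16),
                     sigma = 1.5)
  win <- list(x0 = 10, y0 = 20, w = 64, h = 64)
  set.seed(4)
  pts <- cbind(runif(5, 20, 60), runif(5, 30, 70))
  st <- encode_heatmaps(pts, win, cc)
  expect_equal(dim(st$values), c(16, 16, 5))
  for (k in 1:5) {
    uc <- (pts[k, 1] - win$x0) * 16 / win$w - 0.5
    vc <- (pts[k, 2] - win$y0) * 16 / win$h - 0.5
    oracle <- matrix(0, 16, 16)
    for (v in 0:15) for (u in 0:15) {
      oracle[v + 1, u + 1] <- exp(-((u - uc)^2 + (v - vc)^2) / (2 * 1.5^2))
    }
    oracle <- oracle / max(oracle)
    expect_lt(max(abs(st$values[, , k] - oracle)), 1e-6)
    expect_equal(max(st$values[, , k]), 1)
  }
})

test_that("a landmark at the crop center peaks with value 1 at a center cell", {
  cc <- codec_config(input_size = c(64, 64), heatmap_size = c(64, 64),
                     sigma = 2)
  win <- list(x0 = 0, y0 = 0, w = 64, h = 64)
  st <- encode_heatmaps(rbind(c(32, 32)), win, cc)
  ix <- which(st$values[, , 1] == 1, arr.ind = TRUE)
  expect_true(all(ix[1, ] %in% c(32, 33)))  # center lands between cells 31/32
  expect_equal(max(st$values[, , 1]), 1)
})

test_that("landmarks outside the crop produce a zero channel with a warning", {
  cc <- tiny_codec()
  win <- list(x0 = 0, y0 = 0, w = 64, h = 64)
  expect_warning(st <- encode_heatmaps(rbind(c(500, 500), c(32, 32)), win, cc),
                 "outside the crop")
  expect_true(all(st$values[, , 1] == 0))
  expect_gt(max(st$values[, , 2]), 0.99)
})

test_that("decoding a delta channel returns exactly that cell's mapped center", {
  cc <- codec_config(input_size = c(64, 64), heatmap_size = c(16, 16),
                     sigma = 2, refine = "none")
  win <- list(x0 = 5, y0 = -3, w = 48, h = 48)
  vals <- array(0, c(16, 16, 1))
  vals[7, 11, 1] <- 1  # v = 6, u = 10 (0-based)
  dec <- decode_heatmaps(vals, cc, window = win)
  expect_equal(dec$points[1, 1], 5 + (10 + 0.5) * 48 / 16)
  expect_equal(dec$points[1, 2], -3 + (6 + 0.5) * 48 / 16)
  expect_false(dec$undecodable[1])
})

test_that("ties resolve to the first cell in row-major order", {
  cc <- codec_config(input_size = c(64, 64), heatmap_size = c(8, 8),
                     sigma = 2, refine = "none")
  win <- list(x0 = 0, y0 = 0, w = 8, h = 8)
  vals <- array(0, c(8, 8, 1))
  vals[3, 6, 1] <- 1   # (v=2, u=5): later in row-major than (v=1, u=7)
  vals[2, 8, 1] <- 1
  dec <- decode_heatmaps(vals, cc, window = win)
  expect_equal(dec$points[1, ], c(7 + 0.5, 1 + 0.5))
})

test_that("all-zero channels are flagged undecodable at the crop center", {
  cc <- tiny_codec()
  win <- list(x0 = 10, y0 = 10, w = 40, h = 40)
  vals <- array(0, c(16, 16, 2))
  vals[4, 4, 2] <- 1
  dec <- decode_heatmaps(vals, cc, window = win)
  expect_true(dec$undecodable[1])
  expect_false(dec$undecodable[2])
  expect_equal(dec$points[1, ], c(30, 30))
})

test_that("encode-decode roundtrip is sub-pixel with refinement, half-cell without", {
  cc_g <- codec_config(input_size = c(64, 64), heatmap_size = c(16, 16),
                       sigma = 2, refine = "gaussian")
  cc_n <- codec_config(input_size = c(64, 64), heatmap_size = c(16, 16),
                       sigma = 2, refine = "none")
  win <- list(x0 = 12, y0 = 7, w = 80, h = 80)
  scale <- 80 / 16
  set.seed(11)
  # landmarks at least 2 sigma (in image px) from crop edges
  m <- 2 * 2 * scale
  pts <- cbind(runif(400, 12 + m, 92 - m), runif(400, 7 + m, 87 - m))
  st <- encode_heatmaps(pts, win, cc_g)
  dec_g <- decode_heatmaps(st, cc_g)
  dec_n <- decode_heatmaps(st, cc_n)
  err_g <- sqrt(rowSums((dec_g$points - pts)^2))
  err_n <- abs(dec_n$points - pts)
  expect_lt(max(err_g), 0.5)            # refined: sub-pixel in image pixels
  expect_lte(max(err_n), 0.5 * scale + 1e-9)  # argmax: half a heatmap cell
})

test_that("encoding is equivariant under whole-cell translations", {
  cc <- codec_config(input_size = c(64, 64), heatmap_size = c(16, 16),
                     sigma = 2)
  win <- list(x0 = 0, y0 = 0, w = 64, h = 64)
  scale <- 4
  p <- c(25.3, 30.1)
  a <- encode_heatmaps(rbind(p), win, cc)$values[, , 1]
  b <- encode_heatmaps(rbind(p + c(2 * scale, 3 * scale)), win, cc)$values[, , 1]
  # shift a by (2, 3) cells and compare on the overlap
  expect_equal(b[(1 + 3):16, (1 + 2):16], a[1:(16 - 3), 1:(16 - 2)],
               tolerance = 1e-12)
})

test_that("mse_loss matches a dense elementwise loop and its metric properties hold", {
  set.seed(5)
  a <- array(runif(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  b <- array(runif(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  # brute-force loop oracle
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(mse_loss(a, b), acc / length(a), tolerance = 1e-10)

  expect_identical(mse_loss(a, a), 0)
  expect_equal(mse_loss(a, a + 0.37), 0.37^2, tolerance = 1e-12)
  expect_identical(mse_loss(a, b), mse_loss(b, a))
  expect_error(mse_loss(a, array(0, c(4, 4, 3, 1))), "shape mismatch")

  # quadrangle inequality: loss(a, c) <= 2 * (loss(a, b) + loss(b, c))
  for (i in 1:20) {
    x <- array(rnorm(48), c(4, 4, 3))
    y <- array(rnorm(48), c(4, 4, 3))
    z <- array(rnorm(48), c(4, 4, 3))
    expect_lte(mse_loss(x, z), 2 * (mse_loss(x, y) + mse_loss(y, z)) + 1e-12)
  }
})

test_that("crop windows respect padding, aspect ratio, and reject bad boxes", {
  cc <- codec_config(input_size = c(64, 64), heatmap_size = c(16, 16),
                     pad_frac = 0.25)
  win <- crop_window(c(10, 20, 40, 20), cc)
  expect_equal(win$w, win$h)                    # square input -> square window
  expect_gte(win$w, 40 * 1.5)                   # padded by 25% each side
  expect_equal(win$x0 + win$w / 2, 30)          # centered on the bbox
  expect_equal(win$y0 + win$h / 2, 30)
  expect_error(crop_window(c(0, 0, 0, 10), cc), "non-positive")
  expect_error(codec_config(input_size = c(60, 60), heatmap_size = c(16, 16)),
               "multiple")
})
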