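test_that("branch channels follow the doubling rule for w18 and tiny configs", {
  m18 <- build_model(hwlfc_config())
  s <- model_summary(m18)
  expect_equal(s$branch_channels, c(18, 36, 72, 144))
  # verify by parameter-shape inspection: the fusion 1x1 up-convs map
  # branch j channels to branch i channels
  w <- m18$params[["stage4.m1.fuse.f1_4.conv.w"]]
  expect_equal(dim(w$value), c(1 * 1 * 144, 18))

  st <- model_summary(build_model(tiny_config()))
  expect_equal(st$branch_channels, c(8, 16, 32, 64))
})

test_that("the full-size model has 4 stage-1 bottlenecks and fusion counts (1, 4, 3)", {
  m <- build_model(hwlfc_config())
  s <- model_summary(m)
  expect_equal(s$stage1_bottlenecks, 4)
  expect_equal(s$fusion_counts, c(1, 4, 3))
  # bottleneck structure: 1x1, 3x3, 1x1 convs with 4x expansion
  expect_equal(dim(m$params[["stage1.b1.c1.conv.w"]]$value), c(36, 36))
  expect_equal(dim(m$params[["stage1.b1.c2.conv.w"]]$value), c(9 * 36, 36))
  expect_equal(dim(m$params[["stage1.b1.c3.conv.w"]]$value), c(36, 144))
})

test_that("tiny forward propagates shapes as input/4 with halving branches", {
  m <- build_model(tiny_config())
  x <- array(0, c(64, 64, 1, 1))
  y <- predict_heatmaps(m, x)
  expect_equal(dim(y), c(16, 16, 36, 1))
  expect_true(all(is.finite(y)))  # all-zero input stays finite
})

test_that("shape contract holds across input sizes divisible by 32", {
  for (s in c(64, 96, 128)) {
    cfg <- backbone_config(base_width = 4, input_size = c(s, s),
                           in_channels = 1, num_landmarks = 7,
                           stage1_blocks = 1, blocks_per_module = 1,
                           num_modules = c(1, 1, 1), stem_width = 4)
    m <- build_model(cfg)
    y <- predict_heatmaps(m, array(rnorm(s * s), c(s, s, 1, 1)))
    expect_equal(dim(y), c(s / 4, s / 4, 7, 1))
  }
  expect_error(backbone_config(input_size = c(60, 64)), "divisible by 32")
})

test_that("every trainable parameter belongs to exactly one group", {
  m <- build_model(tiny_config())
  expect_identical(sort(names(m$params)), sort(names(m$group_of)))
  expect_true(all(m$group_of %in% c("stem", "stage1", "stage2", "stage3",
                                    "stage4", "head")))
  expect_false(anyDuplicated(names(m$params)) > 0)
  # all six groups are populated
  expect_setequal(unique(m$group_of),
                  c("stem", "stage1", "stage2", "stage3", "stage4", "head"))
})

test_that("forward is deterministic in evaluation mode", {
  m <- build_model(tiny_config())
  set.seed(1)
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  expect_identical(predict_heatmaps(m, x), predict_heatmaps(m, x))
  expect_error(predict_heatmaps(m, array(0, c(32, 32, 1, 1))),
               "does not match")
})

test_that("two-branch fusion with identity-like weights equals a hand-computed resample-and-add", {
  reg <- new_model_registry()
  fus <- new_fusion(reg, "f", "stage2", channels = c(1, 1))
  # neutralize the 1x1 up-conv and the strided 3x3 down-conv
  reg$params[["f.f1_2.conv.w"]]$value[] <- 1
  dw <- reg$params[["f.f2_1.d1.conv.w"]]$value
  dw[] <- 0
  dw[5, 1] <- 1  # center tap of the 3x3 kernel (row ki=1, kj=1, 0-based)
  reg$params[["f.f2_1.d1.conv.w"]]$value <- dw
  # make the batch norms exact identities (eval stats mean 0, var 1, eps 0)
  for (ly in reg$bn_layers) { ly$frozen <- TRUE; ly$eps <- 0 }

  set.seed(3)
  x1 <- array(rnorm(16), c(4, 4, 1, 1))
  x2 <- array(rnorm(4), c(2, 2, 1, 1))
  out <- forward_fusion(fus, list(x1, x2), training = FALSE)

  # hand oracle: bilinear 2x upsample of x2 (half-pixel convention)
  up <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    py <- (i - 0.5) / 2 - 0.5; px <- (j - 0.5) / 2 - 0.5
    y0 <- min(max(floor(py), 0), 1); x0 <- min(max(floor(px), 0), 1)
    y1 <- min(y0 + 1, 1); x1i <- min(x0 + 1, 1)
    wy <- min(max(py - y0, 0), 1); wx <- min(max(px - x0, 0), 1)
    up[i, j] <- (1 - wy) * ((1 - wx) * x2[y0 + 1, x0 + 1, 1, 1] +
                            wx * x2[y0 + 1, x1i + 1, 1, 1]) +
                wy * ((1 - wx) * x2[y1 + 1, x0 + 1, 1, 1] +
                      wx * x2[y1 + 1, x1i + 1, 1, 1])
  }
  expect_equal(out[[1]]$value[, , 1, 1], pmax(x1[, , 1, 1] + up, 0),
               tolerance = 1e-12)
  # center-tap strided conv samples x1 at the odd (1-based) grid points
  down <- x1[c(1, 3), c(1, 3), 1, 1]
  expect_equal(out[[2]]$value[, , 1, 1], pmax(x2[, , 1, 1] + down, 0),
               tolerance = 1e-12)
})

test_that("single-branch fusion is the identity", {
  reg <- new_model_registry()
  fus <- new_fusion(reg, "f1", "stage2", channels = 2)
  x <- array(rnorm(32), c(4, 4, 2, 1))
  out <- forward_fusion(fus, list(x))
  expect_identical(out[[1]]$value, x)
})

test_that("checkpoint state roundtrips through save and load", {
  m <- build_model(micro_config(init_seed = 5))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- build_model(micro_config(init_seed = 99))
  st <- load_checkpoint(path)
  wingmark:::set_model_state(m2, st)
  for (nm in names(m$params)) {
    expect_identical(m2$params[[nm]]$value, m$params[[nm]]$value)
  }
})
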