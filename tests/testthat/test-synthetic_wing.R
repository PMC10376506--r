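test_that("generation is fully deterministic given the seed pair", {
  tpl <- wing_template()
  cfg <- generator_config(image_size = 64, seed = 9)
  a <- generate_sample(tpl, cfg, sample_seed = 3)
  b <- generate_sample(tpl, cfg, sample_seed = 3)
  expect_identical(a$image, b$image)
  expect_identical(a$annotation, b$annotation)
  c_ <- generate_sample(tpl, cfg, sample_seed = 4)
  expect_false(identical(a$annotation$keypoints, c_$annotation$keypoints))
})

test_that("zero jitter and identity deformation reproduce the template exactly", {
  tpl <- wing_template()
  cfg <- generator_config(image_size = 128, shape_noise = 0, rotation = 0,
                          scale_range = c(1, 1), shear = 0, translation = 0,
                          seed = 1)
  s <- generate_sample(tpl, cfg, sample_seed = 1, render = FALSE)
  pts <- wingmark:::keypoint_matrix(s$annotation$keypoints)
  expect_equal(pts, tpl$points * 128, tolerance = 1e-12)
})

test_that("generated annotations pass dataset validation across random configs", {
  tpl <- wing_template()
  set.seed(77)
  for (i in 1:100) {
    cfg <- generator_config(
      image_size = sample(c(64, 96), 1),
      shape_noise = runif(1, 0, 0.01),
      rotation = runif(1, 0, 8),
      translation = runif(1, 0, 0.03),
      domain = sample(c("source", "target"), 1),
      seed = sample.int(1e6, 1))
    s <- generate_sample(tpl, cfg, sample_seed = sample.int(1e6, 1),
                         render = FALSE)
    ann <- s$annotation
    expect_length(wingmark:::validate_annotation(ann), 0)
    expect_length(ann$keypoints, 108)
    # keypoints inside the (padded, clipped) bbox
    pts <- wingmark:::keypoint_matrix(ann$keypoints)
    expect_true(all(pts[, 1] >= ann$bbox[1] - 1e-9 &
                    pts[, 1] <= ann$bbox[1] + ann$bbox[3] + 1e-9))
    expect_true(all(pts[, 2] >= ann$bbox[2] - 1e-9 &
                    pts[, 2] <= ann$bbox[2] + ann$bbox[4] + 1e-9))
  }
})

test_that("datasets carry unique ids and reload through the COCO dialect", {
  dir <- file.path(tempdir(), "wings_out")
  unlink(dir, recursive = TRUE)
  ds <- generate_dataset(wing_template(),
                         generator_config(image_size = 64, seed = 3),
                         n = 6, out_dir = dir)
  expect_error(generate_dataset(wing_template(),
                                generator_config(image_size = 64, seed = 3),
                                n = 2, out_dir = dir), "not empty")
  back <- load_dataset(file.path(dir, "annotations.json"))
  ids <- vapply(back$annotations, function(a) a$image_id, integer(1))
  expect_length(unique(ids), 6)
  img <- read_wing_image(file.path(dir, back$annotations[[1]]$file_name))
  expect_equal(dim(img)[1:2], c(64, 64))
  unlink(dir, recursive = TRUE)
})

test_that("source and target domains share geometry but differ in pixel statistics", {
  tpl <- wing_template()
  src <- generate_sample(tpl, generator_config(image_size = 64,
                                               domain = "source", seed = 5),
                         sample_seed = 2)
  tgt <- generate_sample(tpl, generator_config(image_size = 64,
                                               domain = "target", seed = 5),
                         sample_seed = 2)
  expect_equal(src$annotation$keypoints, tgt$annotation$keypoints,
               tolerance = 1e-12)
  expect_gt(abs(mean(src$image) - mean(tgt$image)), 0.15)
})

test_that("region difficulty elevates the cubitus-anal and distal landmarks", {
  tpl <- wing_template()
  cfg <- generator_config()
  mult <- region_difficulty(tpl, cfg)
  radial <- tpl$regions == "radial" & tpl$points[, 1] <= 0.8
  expect_true(all(mult[radial] == 1))
  expect_true(all(mult[tpl$regions == "cubitus_anal"] > 1))
  expect_gt(min(mult[tpl$regions == "cubitus_anal"]), max(mult[radial]))

  off <- generator_config(region_difficulty = FALSE)
  expect_true(all(region_difficulty(tpl, off) == 1))

  bad <- tpl
  bad$regions[1] <- "elytron"
  expect_error(region_difficulty(bad, cfg), "unknown region label")
})

test_that("a template-mean predictor suffers higher NME on elevated-jitter landmarks", {
  tpl <- wing_template()
  cfg <- generator_config(image_size = 128, shape_noise = 0.008,
                          rotation = 0, scale_range = c(1, 1), shear = 0,
                          translation = 0, seed = 42)
  ds <- generate_dataset(tpl, cfg, n = 200, render = FALSE)
  predictor <- function(image, ann) tpl$points * 128  # noise-free positions
  r <- evaluate_model(NULL, ds$index, tiny_codec(), predict_fn = predictor)
  hard <- tpl$regions == "cubitus_anal"
  easy <- tpl$regions == "radial" & tpl$points[, 1] <= 0.8
  expect_gt(mean(r$per_landmark_nme[hard]), mean(r$per_landmark_nme[easy]))
})
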