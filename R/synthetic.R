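# Procedural generator of wing-like images with exact ground-truth
# landmarks, in the same COCO dialect as real wing datasets. Two visually
# distinct domains (a high-contrast "source" and a low-contrast textured
# "target") make pretraining and transfer testable without any downloads.

#' Canonical wing landmark template
#'
#' 36 mean landmark positions in a unit frame, laid out along stylized vein
#' paths: an anterior margin chain, a radial-cell cluster, a medial chain,
#' and a cubitus-anal cluster. The reference pair (1, 18) spans the frame's
#' long axis. `vein_edges` lists the landmark pairs whose connecting
#' segments are rendered as veins; `regions` tags each landmark
#' (margin / radial / medial / cubitus_anal).
#'
#' @return a `wing_template`: list with `points` (36 x 2 in `[0, 1]^2`),
#'   `vein_edges` (m x 2), `regions`, `names`, `reference_pair`.
#' @export
wing_template <- function() {
  pts <- rbind(
    c(0.04, 0.42), c(0.10, 0.45), c(0.16, 0.47), c(0.24, 0.49),  # 1-4
    c(0.30, 0.50), c(0.42, 0.52),                                # 5-6 margin
    c(0.50, 0.54), c(0.62, 0.56), c(0.63, 0.52), c(0.66, 0.54),  # 7-10
    c(0.52, 0.50), c(0.56, 0.48), c(0.70, 0.57), c(0.72, 0.53),  # 11-14
    c(0.73, 0.49), c(0.68, 0.50), c(0.88, 0.52), c(0.96, 0.56),  # 15-18
    c(0.90, 0.44), c(0.78, 0.40), c(0.70, 0.44), c(0.46, 0.46),  # 19-22
    c(0.52, 0.38), c(0.62, 0.40), c(0.74, 0.33), c(0.50, 0.33),  # 23-26
    c(0.20, 0.38),                                               # 27 medial
    c(0.30, 0.33), c(0.38, 0.26), c(0.28, 0.29), c(0.48, 0.27),  # 28-31
    c(0.56, 0.28), c(0.36, 0.30), c(0.60, 0.24), c(0.14, 0.33),  # 32-35
    c(0.26, 0.21))                                               # 36 cub-anal
  regions <- c(rep("margin", 6), rep("radial", 12), rep("medial", 9),
               rep("cubitus_anal", 9))
  edges <- rbind(
    c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 7),   # anterior margin
    c(7, 8), c(8, 13), c(13, 14), c(14, 15), c(15, 16),      # radial cell
    c(16, 11), c(11, 7), c(8, 9), c(9, 10), c(10, 13),
    c(11, 12), c(12, 16), c(14, 17), c(17, 18),              # RA out to tip
    c(18, 19), c(19, 20), c(20, 21), c(21, 10),              # distal posterior
    c(6, 22), c(22, 23), c(23, 24), c(24, 25), c(24, 26),    # medial chain
    c(22, 27), c(20, 24),
    c(27, 28), c(27, 35), c(28, 33), c(33, 30), c(28, 29),   # cubitus-anal
    c(29, 36), c(26, 31), c(31, 32), c(32, 34), c(31, 33),
    c(35, 36))
  structure(list(points = pts, vein_edges = edges, regions = regions,
                 names = wing_landmark_names(),
                 reference_pair = c(1L, 18L)),
            class = "wing_template")
}

#' Generator configuration
#'
#' Deformation ranges and texture presets. The two domains are visually
#' distinct while sharing the landmark geometry: `source` renders
#' high-contrast dark veins on a clean light background; `target` renders
#' low-contrast veins on a darker, blotchy-textured background with the
#' distal vein traces faded (emulating membranized distal regions), standing
#' in for the domain gap between a pretraining corpus and wing photographs.
#'
#' @param image_size image side length in pixels (square images; 256 matches
#'   the network input so desk-scale training skips resizing; 64 is used by
#'   the tiny variant).
#' @param shape_noise std of per-landmark Gaussian jitter, in frame units.
#' @param rotation max |rotation| in degrees.
#' @param scale_range multiplicative scale range.
#' @param shear max |shear|.
#' @param translation max |translation| as a fraction of image size.
#' @param domain `"source"` or `"target"`.
#' @param region_difficulty elevate jitter / fade veins for the hard
#'   (cubitus-anal and distal) landmarks (default `TRUE`).
#' @param seed base RNG seed; combined with each sample's `sample_seed`.
#' @return a `generator_config`.
#' @export
generator_config <- function(image_size = 256, shape_noise = 0.006,
                             rotation = 6, scale_range = c(0.9, 1.05),
                             shear = 0.05, translation = 0.02,
                             domain = c("target", "source"),
                             region_difficulty = TRUE, seed = 1) {
  domain <- match.arg(domain)
  stopifnot(image_size >= 32, shape_noise >= 0,
            all(is.finite(c(rotation, scale_range, shear, translation))))
  tex <- if (domain == "source") {
    list(bg = 0.92, noise_sd = 0.015, blotch_sd = 0, contrast = 0.8,
         distal_fade = 0, vein_width_frac = 0.009)
  } else {
    list(bg = 0.62, noise_sd = 0.05, blotch_sd = 0.09, contrast = 0.38,
         distal_fade = 0.5, vein_width_frac = 0.007)
  }
  structure(c(list(image_size = as.integer(image_size),
                   shape_noise = shape_noise, rotation = rotation,
                   scale_range = scale_range, shear = shear,
                   translation = translation, domain = domain,
                   region_difficulty = region_difficulty, seed = seed),
              tex),
            class = "generator_config")
}

#' Per-landmark jitter multipliers by region difficulty
#'
#' Landmarks in the cubitus-anal region, and distal landmarks (canonical
#' x > 0.8), receive elevated positional jitter (and their veins reduced
#' contrast at render time), reproducing qualitatively the hard-landmark
#' structure of real wings where distal veins degenerate into faint traces.
#'
#' @param template a [wing_template()].
#' @param config a [generator_config()].
#' @return numeric vector of K multipliers (radial/margin baseline 1).
#' @export
region_difficulty <- function(template, config) {
  known <- c("margin", "radial", "medial", "cubitus_anal")
  bad <- setdiff(unique(template$regions), known)
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  mult <- rep(1, nrow(template$points))
  if (isTRUE(config$region_difficulty)) {
    mult[template$regions == "cubitus_anal"] <- 2.5
    distal <- template$points[, 1] > 0.8
    mult[distal] <- pmax(mult[distal], 2.0)
  }
  mult
}

combine_seeds <- function(seed, sample_seed) {
  as.integer((abs(seed) * 100003 + abs(sample_seed) * 7919) %% 2147483647)
}

#' Generate one synthetic wing sample
#'
#' Renders jittered, affinely deformed vein paths as dark anti-aliased
#' curves on a domain-textured background. The annotation holds the exact
#' post-deformation landmark coordinates (rendering introduces no annotation
#' error). Fully deterministic given `(config$seed, sample_seed)`.
#'
#' @param template a [wing_template()].
#' @param config a [generator_config()].
#' @param sample_seed per-sample seed (also used as the image id).
#' @param render if `FALSE`, skip rasterization and return only the
#'   annotation (fast path for split/protocol tests).
#' @return list with `image` (`(S, S)` matrix in `[0, 1]`, or `NULL`) and
#'   `annotation` (a [wing_annotation()]).
#' @export
generate_sample <- function(template, config, sample_seed, render = TRUE) {
  set.seed(combine_seeds(config$seed, sample_seed))
  S <- config$image_size
  mult <- region_difficulty(template, config)
  K <- nrow(template$points)
  for (attempt in 1:20) {
    jit <- matrix(stats::rnorm(2 * K, 0, config$shape_noise), K, 2) * mult
    pts <- template$points + jit
    th <- stats::runif(1, -config$rotation, config$rotation) * pi / 180
    sc <- stats::runif(1, config$scale_range[1], config$scale_range[2])
    sh <- stats::runif(1, -config$shear, config$shear)
    tr <- stats::runif(2, -config$translation, config$translation) * S
    A <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
      matrix(c(1, 0, sh, 1), 2, 2)
    ctr <- S / 2
    px <- t(A %*% (t(pts * S) - ctr) + ctr + tr)
    if (all(px > 2 & px < S - 2)) break
    if (attempt == 20) {
      stop("deformation keeps pushing landmarks out of frame; ",
           "reduce deformation ranges")
    }
  }
  img <- NULL
  if (render) {
    img <- render_wing(px, template, config, mult)
  }
  ann <- wing_annotation(
    image_id = sample_seed,
    file_name = sprintf("images/wing_%05d.png", sample_seed),
    width = S, height = S,
    keypoints = as.numeric(t(cbind(px, 2))),
    num_keypoints = K)
  list(image = img, annotation = ann)
}

render_wing <- function(px, template, config, mult) {
  S <- config$image_size
  bg <- matrix(config$bg, S, S)
  if (config$blotch_sd > 0) {
    g <- max(4L, S %/% 16L)
    blotch <- matrix(stats::rnorm(g * g, 0, config$blotch_sd), g, g)
    L <- interp_matrix(S, g)
    bg <- bg + L %*% blotch %*% t(L)
  }
  if (config$noise_sd > 0) {
    bg <- bg + matrix(stats::rnorm(S * S, 0, config$noise_sd), S, S)
  }
  width <- max(1.2, config$vein_width_frac * S)
  alpha <- matrix(0, S, S)
  hard <- template$regions == "cubitus_anal" | template$points[, 1] > 0.8
  for (e in seq_len(nrow(template$vein_edges))) {
    i <- template$vein_edges[e, 1]; j <- template$vein_edges[e, 2]
    contrast <- config$contrast
    if (isTRUE(config$region_difficulty) && hard[i] && hard[j]) {
      contrast <- contrast * 0.55
    }
    if (config$distal_fade > 0) {
      mx <- mean(template$points[c(i, j), 1])
      if (mx > 0.7) contrast <- contrast * (1 - config$distal_fade)
    }
    alpha <- draw_segment(alpha, px[i, ], px[j, ], width, contrast)
  }
  img <- bg * (1 - alpha) + 0.05 * alpha
  pmin(pmax(img, 0), 1)
}

# Max-composite an anti-aliased segment into an alpha canvas.
draw_segment <- function(alpha, p, q, width, a_val) {
  S <- nrow(alpha)
  r0 <- max(1L, floor(min(p[2], q[2]) - width - 1))
  r1 <- min(S, ceiling(max(p[2], q[2]) + width + 1))
  c0 <- max(1L, floor(min(p[1], q[1]) - width - 1))
  c1 <- min(S, ceiling(max(p[1], q[1]) + width + 1))
  if (r0 > r1 || c0 > c1) return(alpha)
  rows <- r0:r1; cols <- c0:c1
  yy <- rows - 0.5; xx <- cols - 0.5   # pixel centers in continuous coords
  vx <- q[1] - p[1]; vy <- q[2] - p[2]
  len2 <- vx^2 + vy^2
  X <- matrix(xx, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(yy, length(rows), length(cols))
  if (len2 < 1e-12) {
    d <- sqrt((X - p[1])^2 + (Y - p[2])^2)
  } else {
    t <- ((X - p[1]) * vx + (Y - p[2]) * vy) / len2
    t <- pmin(pmax(t, 0), 1)
    d <- sqrt((X - (p[1] + t * vx))^2 + (Y - (p[2] + t * vy))^2)
  }
  a <- pmin(1, pmax(0, width / 2 + 0.5 - d)) * a_val
  alpha[rows, cols] <- pmax(alpha[rows, cols], a)
  alpha
}

#' Generate a synthetic wing dataset
#'
#' Produces `n` samples with unique ids. With `out_dir`, writes
#' `images/wing_#####.png` files plus an `annotations.json` in the COCO
#' dialect and returns the loaded dataset; without, returns the dataset and
#' images in memory.
#'
#' @param template a [wing_template()].
#' @param config a [generator_config()].
#' @param n number of samples (a 256-sample dataset mirrors the size of the
#'   real annotated corpus).
#' @param out_dir output directory, or `NULL` for in-memory.
#' @param force overwrite a non-empty `out_dir`.
#' @param render rasterize images (see [generate_sample()]).
#' @return list with `index` (a `wing_dataset`) and `images` (named list
#'   keyed by id when in-memory, else `NULL`).
#' @export
generate_dataset <- function(template = wing_template(),
                             config = generator_config(), n = 256,
                             out_dir = NULL, force = FALSE, render = TRUE) {
  stopifnot(n >= 1)
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
      stop("output directory is not empty: ", out_dir,
           " (use force = TRUE to overwrite)")
    }
    dir.create(file.path(out_dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
  }
  anns <- vector("list", n)
  imgs <- if (is.null(out_dir)) list() else NULL
  for (i in seq_len(n)) {
    s <- generate_sample(template, config, sample_seed = i, render = render)
    anns[[i]] <- s$annotation
    if (render) {
      if (is.null(out_dir)) {
        imgs[[as.character(i)]] <- s$image
      } else {
        png::writePNG(s$image, file.path(out_dir, s$annotation$file_name))
      }
    }
  }
  index <- wing_dataset(anns, source_path = if (is.null(out_dir))
    NA_character_ else file.path(out_dir, "annotations.json"),
    landmark_names = template$names)
  if (!is.null(out_dir)) {
    save_dataset(index, file.path(out_dir, "annotations.json"))
  }
  list(index = index, images = imgs)
}
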