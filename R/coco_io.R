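# COCO-dialect keypoint annotations for single-wing images: one category,
# one annotation per image, a flat (x, y, v) keypoint array of length 3K,
# and a (x_min, y_min, w, h) bounding box, all in top-left-origin pixels.

#' Default names of the 36 wing landmarks
#'
#' Standard descriptors of the hindwing venation points (vein bases,
#' crossings, bifurcations and termini; HP = humeral plate, Sc = subcosta,
#' RA/RP = radius anterior/posterior, MP = media posterior, CuA = cubitus
#' anterior, AA/AP = anal anterior/posterior, cv = cross-vein).
#' @return character vector of length 36.
#' @export
wing_landmark_names <- function() {
  c("proximal anterior point of HP",
    "crossing of BSc and Sc",
    "bifurcation of Sc into ScA and ScP",
    "crossing of ScP and RA",
    "crossing of ScA and RA",
    "crossing of rp-m1 and RA",
    "proximal anterior point of radial cell",
    "distal anterior point of radial cell",
    "distal posterior point of radial cell",
    "anterior point of r4",
    "proximal posterior point of radial cell",
    "proximal point of r3",
    "apical hinge",
    "anterior point of radial-cell distal triangle",
    "posterior point of radial-cell distal triangle",
    "proximal point of radial-cell distal triangle",
    "distal point of RA4",
    "distal point of RA1",
    "distal point of RP2",
    "bifurcation of MP1+2",
    "posterior point of r4",
    "proximal point of RP",
    "anterior point of mp-cua",
    "crossing of rm-mp1 and MP",
    "posterior of medial spur",
    "posterior point of mp-cua",
    "bifurcation of AA",
    "fusion of AA1+2 with CuA3+4",
    "distal point of AA3+4",
    "proximal point of cv",
    "distal point of AA1+2+CuA3+4",
    "anterior point of CuA1+2+MP4",
    "distal point of cv",
    "posterior point of CuA1+2+MP4",
    "base point of AP3+4",
    "posterior point of AP3+4")
}

#' Construct a single-image wing annotation
#'
#' @param image_id unique integer id.
#' @param file_name image path relative to the dataset root.
#' @param width,height image size in pixels.
#' @param keypoints flat numeric vector of `(x, y, v)` triplets, length
#'   `3 * num_keypoints`, top-left origin. The visibility flag `v` is stored
#'   and preserved but ignored by all computation (all landmarks visible).
#' @param num_keypoints landmark count K.
#' @param bbox `c(x_min, y_min, box_width, box_height)` in pixels; if `NULL`,
#'   a tight box around the keypoints padded by `bbox_pad` is supplied.
#' @param bbox_pad padding fraction for a self-supplied bbox.
#' @return a `wing_annotation` list.
#' @export
wing_annotation <- function(image_id, file_name, width, height, keypoints,
                            num_keypoints = length(keypoints) / 3,
                            bbox = NULL, bbox_pad = 0.05) {
  keypoints <- as.numeric(keypoints)
  if (is.null(bbox)) {
    pts <- keypoint_matrix(keypoints)
    w <- max(pts[, 1]) - min(pts[, 1])
    h <- max(pts[, 2]) - min(pts[, 2])
    x0 <- max(0, min(pts[, 1]) - bbox_pad * w)
    y0 <- max(0, min(pts[, 2]) - bbox_pad * h)
    x1 <- min(width, max(pts[, 1]) + bbox_pad * w)
    y1 <- min(height, max(pts[, 2]) + bbox_pad * h)
    bbox <- c(x0, y0, x1 - x0, y1 - y0)
  }
  structure(list(image_id = as.integer(image_id), file_name = file_name,
                 width = as.numeric(width), height = as.numeric(height),
                 keypoints = keypoints,
                 num_keypoints = as.integer(num_keypoints),
                 bbox = as.numeric(bbox)),
            class = "wing_annotation")
}

keypoint_matrix <- function(keypoints) {
  matrix(keypoints, ncol = 3, byrow = TRUE)[, 1:2, drop = FALSE]
}

validate_annotation <- function(ann) {
  errs <- character(0)
  id <- ann$image_id
  eps <- 1e-6  # absorb printed-precision rounding of serialized coordinates
  if (length(ann$keypoints) != 3 * ann$num_keypoints) {
    errs <- c(errs, sprintf(
      "record %s: keypoints length %d != 3 * num_keypoints (%d)",
      id, length(ann$keypoints), 3 * ann$num_keypoints))
  } else {
    pts <- keypoint_matrix(ann$keypoints)
    if (any(pts[, 1] < -eps | pts[, 1] > ann$width + eps |
            pts[, 2] < -eps | pts[, 2] > ann$height + eps)) {
      errs <- c(errs, sprintf("record %s: keypoint outside image bounds", id))
    }
  }
  b <- ann$bbox
  if (length(b) != 4) {
    errs <- c(errs, sprintf("record %s: bbox must have 4 elements", id))
  } else {
    if (b[3] <= 0 || b[4] <= 0) {
      errs <- c(errs, sprintf("record %s: bbox has non-positive size", id))
    }
    if (b[1] < -eps || b[2] < -eps || b[1] + b[3] > ann$width + eps ||
        b[2] + b[4] > ann$height + eps) {
      errs <- c(errs, sprintf("record %s: bbox outside image", id))
    }
  }
  errs
}

#' Assemble a dataset index from annotations
#'
#' @param annotations list of [wing_annotation()] records.
#' @param source_path origin of the data (JSON path or `NA`).
#' @param landmark_names optional character vector of landmark names.
#' @param validate check all record invariants (default `TRUE`).
#' @return a `wing_dataset` with fields `annotations`, `landmark_count`,
#'   `source_path`, `landmark_names`.
#' @export
wing_dataset <- function(annotations, source_path = NA_character_,
                         landmark_names = NULL, validate = TRUE) {
  if (length(annotations) == 0) {
    warning("dataset contains zero annotations")
    return(structure(list(annotations = list(), landmark_count = NA_integer_,
                          source_path = source_path,
                          landmark_names = landmark_names),
                     class = "wing_dataset"))
  }
  ids <- vapply(annotations, function(a) a$image_id, integer(1))
  if (anyDuplicated(ids)) {
    stop("duplicate image ids: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  }
  ks <- vapply(annotations, function(a) a$num_keypoints, integer(1))
  if (length(unique(ks)) != 1) {
    stop("records disagree on num_keypoints: ",
         paste(unique(ks), collapse = ", "))
  }
  if (validate) {
    errs <- unlist(lapply(annotations, validate_annotation))
    if (length(errs)) stop("invalid annotations:\n", paste(errs, collapse = "\n"))
  }
  structure(list(annotations = annotations, landmark_count = ks[1],
                 source_path = source_path, landmark_names = landmark_names),
            class = "wing_dataset")
}

#' @export
print.wing_dataset <- function(x, ...) {
  cat(sprintf("wing_dataset: %d annotations, %s landmarks each\n",
              length(x$annotations),
              ifelse(is.na(x$landmark_count), "?", x$landmark_count)))
  invisible(x)
}

#' Load a COCO-dialect keypoint dataset
#'
#' Reads the JSON (with `images`, `annotations` and optional `categories`
#' arrays), joins annotations to their images by id, and validates every
#' record: keypoint array length `3 * num_keypoints`, points within the
#' image, bbox inside the image with positive size, unique ids, shared K.
#'
#' @param path path to the annotation JSON.
#' @return a `wing_dataset`.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$images) || is.null(js$annotations)) {
    stop("not a COCO keypoint file (missing 'images' or 'annotations'): ",
         path)
  }
  img_by_id <- list()
  for (im in js$images) {
    key <- as.character(im$id)
    if (!is.null(img_by_id[[key]])) stop("duplicate image id: ", im$id)
    img_by_id[[key]] <- im
  }
  anns <- lapply(js$annotations, function(a) {
    im <- img_by_id[[as.character(a$image_id)]]
    if (is.null(im)) stop("annotation refers to unknown image id: ", a$image_id)
    wing_annotation(image_id = a$image_id, file_name = im$file_name,
                    width = im$width, height = im$height,
                    keypoints = unlist(a$keypoints),
                    num_keypoints = a$num_keypoints,
                    bbox = if (is.null(a$bbox)) NULL else unlist(a$bbox))
  })
  nms <- NULL
  if (!is.null(js$categories) && length(js$categories) >= 1) {
    nms <- unlist(js$categories[[1]]$keypoints)
  }
  wing_dataset(anns, source_path = path, landmark_names = nms)
}

#' Save a dataset as COCO-dialect JSON
#'
#' Writing refuses an index that violates the record invariants; a reload of
#' the written file reproduces every field (integers exactly, coordinates at
#' full double precision).
#'
#' @param index a `wing_dataset`.
#' @param path output JSON path.
#' @export
save_dataset <- function(index, path) {
  stopifnot(inherits(index, "wing_dataset"))
  errs <- unlist(lapply(index$annotations, validate_annotation))
  if (length(errs)) {
    stop("refusing to save invalid dataset:\n", paste(errs, collapse = "\n"))
  }
  images <- lapply(index$annotations, function(a) {
    list(id = a$image_id, file_name = a$file_name, width = a$width,
         height = a$height)
  })
  annotations <- lapply(index$annotations, function(a) {
    list(id = a$image_id, image_id = a$image_id, category_id = 1L,
         keypoints = a$keypoints, num_keypoints = a$num_keypoints,
         bbox = a$bbox)
  })
  cats <- list(list(id = 1L, name = "wing",
                    keypoints = index$landmark_names %||%
                      as.character(seq_len(max(1L, index$landmark_count,
                                               na.rm = TRUE)))))
  jsonlite::write_json(list(images = images, annotations = annotations,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert a lower-left-origin measurement to annotation coordinates
#'
#' Measurement coordinates take the lower-left image corner as origin;
#' annotations use the top-left (COCO) convention, obtained by subtracting
#' the measured y from the image height. The operation is an involution.
#'
#' @param x x coordinate (pixels), unchanged.
#' @param y_measured y coordinate with lower-left origin, in
#'   `[0, image_height]`.
#' @param image_height image height in pixels.
#' @return list with `x` and `y` (top-left origin). Vectorized.
#' @export
convert_measurement_origin <- function(x, y_measured, image_height) {
  if (any(y_measured < 0 | y_measured > image_height)) {
    stop("y_measured outside [0, image_height]")
  }
  list(x = x, y = image_height - y_measured)
}

#' Landmark set: ordered named points with a reference pair
#'
#' @param points K x 2 numeric matrix of `(x, y)` pixel coordinates.
#' @param names optional K landmark names.
#' @param reference_pair ordered pair of 1-based landmark indices whose
#'   distance normalizes the NME (default `c(1, 18)`: proximal anterior
#'   point of the humeral plate to the distal point of RA1).
#' @return a `landmark_set`.
#' @export
landmark_set <- function(points, names = NULL, reference_pair = c(1L, 18L)) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2)
  rp <- as.integer(reference_pair)
  if (length(rp) != 2 || rp[1] == rp[2] || any(rp < 1) ||
      any(rp > nrow(points))) {
    stop("reference_pair must be two distinct indices in 1..K")
  }
  structure(list(points = unname(points), names = names,
                 reference_pair = rp),
            class = "landmark_set")
}

#' Extract the landmark set of an annotation
#' @param ann a `wing_annotation`.
#' @param reference_pair passed to [landmark_set()].
#' @param names optional landmark names.
#' @return a `landmark_set`.
#' @export
annotation_landmarks <- function(ann, reference_pair = c(1L, 18L),
                                 names = NULL) {
  landmark_set(keypoint_matrix(ann$keypoints), names = names,
               reference_pair = reference_pair)
}

#' Reference distance of a landmark set
#'
#' Euclidean distance between the two landmarks of the reference pair; the
#' specimen-specific normalizer of the NME.
#' @param landmarks a `landmark_set`.
#' @return positive scalar, in pixels.
#' @export
reference_distance <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  p <- landmarks$points[landmarks$reference_pair[1], ]
  q <- landmarks$points[landmarks$reference_pair[2], ]
  d <- sqrt(sum((p - q)^2))
  if (d == 0) {
    stop("degenerate reference: the two reference landmarks coincide, ",
         "NME is undefined")
  }
  d
}
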