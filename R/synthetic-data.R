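## Synthetic dermoscopy-like fixtures: elliptical lesions on skin-toned
## background, dark hair strokes with exact ground-truth masks, metadata
## tables, and class-coupled labeled datasets.

#' The ten diagnostic categories
#'
#' Ordered by increasing clinical risk; the first six form the benign group,
#' the last four the malignant group (actinic keratosis is counted malignant
#' as a precancerous keratinocyte lesion).
#'
#' @return character vector of length 10.
#' @export
lesion_classes <- function() {
  c("vascular lesions", "nevus", "solar lentigo", "dermatofibroma",
    "seborrheic keratosis", "benign keratosis",
    "actinic keratosis", "basal cell carcinoma",
    "squamous cell carcinoma", "melanoma")
}

#' Encode / decode a diagnostic label to its integer index
#'
#' @param label class name among [lesion_classes()].
#' @param index integer in 1..10.
#' @return `encode_label` the 1-based index; `decode_label` the class name.
#' @export
encode_label <- function(label) {
  idx <- match(label, lesion_classes())
  if (anyNA(idx)) stop("unknown class label: ", paste(label[is.na(idx)], collapse = ", "))
  idx
}

#' @rdname encode_label
#' @export
decode_label <- function(index) {
  if (any(index < 1L | index > 10L)) stop("label index out of range 1..10")
  lesion_classes()[index]
}

#' Specification of a synthetic lesion image
#'
#' Describes a flat skin background with an elliptical lesion and i.i.d.
#' Gaussian pixel noise. Intensities are 8-bit (0-255) per channel.
#'
#' @param height,width image size in pixels.
#' @param skin_level length-3 background intensity (R, G, B).
#' @param lesion_center `(row, col)` of the ellipse centre.
#' @param lesion_axes `(a, b)` semi-axes in pixels (rows, cols); `c(0, 0)`
#'   draws no lesion.
#' @param lesion_level length-3 lesion intensity.
#' @param noise_sd standard deviation of the additive noise, intensity units.
#' @param seed integer RNG seed; the generator is a pure function of the spec.
#' @return an object of class `lesion_image_spec`.
#' @export
lesion_image_spec <- function(height = 128, width = 128,
                              skin_level = c(200, 170, 150),
                              lesion_center = c(height / 2, width / 2),
                              lesion_axes = c(height / 4, width / 4),
                              lesion_level = c(120, 80, 70),
                              noise_sd = 2, seed = 1L) {
  if (height < 1 || width < 1) stop("image dimensions must be positive")
  if (any(skin_level < 0 | skin_level > 255) || any(lesion_level < 0 | lesion_level > 255))
    stop("intensity levels must lie in [0, 255]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (lesion_center[1] - lesion_axes[1] < 0 || lesion_center[1] + lesion_axes[1] > height + 1 ||
      lesion_center[2] - lesion_axes[2] < 0 || lesion_center[2] + lesion_axes[2] > width + 1)
    stop("lesion ellipse must fit inside the image")
  structure(list(height = as.integer(height), width = as.integer(width),
                 skin_level = rep_len(skin_level, 3),
                 lesion_center = lesion_center, lesion_axes = lesion_axes,
                 lesion_level = rep_len(lesion_level, 3),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "lesion_image_spec")
}

#' Generate a synthetic lesion image
#'
#' @param spec a [lesion_image_spec()].
#' @return H x W x 3 integer-valued array in \[0, 255\].
#' @export
generate_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_image_spec"))
  h <- spec$height; w <- spec$width
  inside <- lesion_membership(h, w, spec$lesion_center, spec$lesion_axes)
  with_seed(spec$seed, {
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(spec$skin_level[ch], h, w)
      plane[inside] <- spec$lesion_level[ch]
      if (spec$noise_sd > 0)
        plane <- plane + rnorm(h * w, sd = spec$noise_sd)
      img[, , ch] <- plane
    }
    clip255(round_half_up(img))
  })
}

## Discrete ellipse membership: pixel (i,j) is inside iff
## ((i-cr)/a)^2 + ((j-cc)/b)^2 <= 1. Degenerate axes draw nothing.
lesion_membership <- function(h, w, center, axes) {
  if (axes[1] <= 0 || axes[2] <= 0) return(matrix(FALSE, h, w))
  di <- (seq_len(h) - center[1]) / axes[1]
  dj <- (seq_len(w) - center[2]) / axes[2]
  outer(di^2, dj^2, `+`) <= 1
}

#' Specification of a synthetic hair overlay
#'
#' Hair is rendered as dark quadratic Bezier strokes rasterised without
#' anti-aliasing at integer width, so the ground-truth mask has hard edges
#' and is exactly the set of modified pixels.
#'
#' @param n_strokes number of strokes.
#' @param stroke_width_range `(min, max)` stroke width in pixels, min >= 1.
#' @param stroke_darkness intensity decrement applied to each channel
#'   (scalar or length 3); hair must be darker than skin, so > 0.
#' @param curvature dimensionless bow of the stroke (0 = straight chords).
#' @param seed integer RNG seed.
#' @return an object of class `hair_overlay_spec`.
#' @export
hair_overlay_spec <- function(n_strokes = 5, stroke_width_range = c(1, 3),
                              stroke_darkness = 120, curvature = 0.25,
                              seed = 1L) {
  if (n_strokes < 0) stop("n_strokes must be >= 0")
  if (stroke_width_range[1] < 1) stop("minimum stroke width must be >= 1")
  if (stroke_width_range[2] < stroke_width_range[1]) stop("invalid stroke_width_range")
  if (any(stroke_darkness <= 0)) stop("stroke_darkness must be > 0 (hair is darker than skin)")
  structure(list(n_strokes = as.integer(n_strokes),
                 stroke_width_range = as.integer(stroke_width_range),
                 stroke_darkness = rep_len(stroke_darkness, 3),
                 curvature = curvature, seed = as.integer(seed)),
            class = "hair_overlay_spec")
}

#' Overlay dark hair strokes on an image
#'
#' @param image H x W x 3 array.
#' @param spec a [hair_overlay_spec()].
#' @return list with `image` (the occluded copy) and `mask` (H x W logical,
#'   exactly the pixels whose value changed on at least one channel).
#' @export
overlay_hair <- function(image, spec) {
  assert_color_image(image)
  stopifnot(inherits(spec, "hair_overlay_spec"))
  h <- dim(image)[1]; w <- dim(image)[2]
  stamped <- with_seed(spec$seed, {
    m <- matrix(FALSE, h, w)
    for (s in seq_len(spec$n_strokes)) {
      width <- sample(seq(spec$stroke_width_range[1], spec$stroke_width_range[2]), 1)
      m <- m | rasterize_stroke(h, w, width, spec$curvature)
    }
    m
  })
  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[stamped] <- pmax(plane[stamped] - spec$stroke_darkness[ch], 0)
    out[, , ch] <- plane
  }
  ## the truth mask is the changed-pixel set; stamped pixels that were
  ## already at 0 on every channel drop out
  changed <- (out[, , 1] != image[, , 1]) | (out[, , 2] != image[, , 2]) |
    (out[, , 3] != image[, , 3])
  list(image = out, mask = changed)
}

## One quadratic Bezier chord across the image, stamped as width x width
## squares at densely sampled points (no anti-aliasing).
rasterize_stroke <- function(h, w, width, curvature) {
  ## endpoints on opposite borders so strokes span the frame like real hair
  p0 <- random_border_point(h, w)
  p1 <- random_border_point(h, w)
  mid <- (p0 + p1) / 2
  chord <- p1 - p0
  len <- sqrt(sum(chord^2))
  if (len < 1) return(matrix(FALSE, h, w))
  perp <- c(-chord[2], chord[1]) / len
  ctrl <- mid + perp * curvature * len * runif(1, -1, 1)
  t <- seq(0, 1, length.out = max(4L, ceiling(3 * len)))
  pts <- outer((1 - t)^2, p0) + outer(2 * (1 - t) * t, ctrl) + outer(t^2, p1)
  ij <- round_half_up(pts)
  off <- seq_len(width) - 1L - (width - 1L) %/% 2L
  m <- matrix(FALSE, h, w)
  for (di in off) for (dj in off) {
    ii <- ij[, 1] + di; jj <- ij[, 2] + dj
    keep <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    m[cbind(ii[keep], jj[keep])] <- TRUE
  }
  m
}

random_border_point <- function(h, w) {
  side <- sample(4, 1)
  switch(side,
         c(1, runif(1, 1, w)),
         c(h, runif(1, 1, w)),
         c(runif(1, 1, h), 1),
         c(runif(1, 1, h), w))
}

## Default metadata marginals loosely emulating the archive's skew: more
## male patients, posterior torso the most frequent site, ages peaking in
## the 15-20 bracket.
default_sex_probs <- function() c(female = 0.46, male = 0.54)

default_site_probs <- function() {
  c("anterior torso" = 0.15, "head/neck" = 0.12, "lateral torso" = 0.04,
    "lower extremity" = 0.17, "oral/genital" = 0.01, "palms/soles" = 0.02,
    "posterior torso" = 0.30, "upper extremity" = 0.19)
}

default_age_probs <- function() {
  ages <- seq(0, 85, by = 5)
  wts <- exp(-((ages - 17.5) / 30)^2) + 0.4 * exp(-((ages - 55) / 15)^2)
  wts[ages %in% c(15, 20)] <- wts[ages %in% c(15, 20)] * 1.6
  setNames(wts / sum(wts), ages)
}

#' Generate synthetic patient metadata records
#'
#' Draws sex, anatomic site and 5-year age group independently from
#' configurable marginal distributions. Defaults emulate the skew of the
#' public dermoscopy archives (male-dominated, posterior torso most common,
#' young-adult age peak).
#'
#' @param n number of records.
#' @param seed integer RNG seed.
#' @param sex_probs,site_probs,age_probs named probability vectors over the
#'   legal category sets; names must match the codebook categories exactly.
#' @return data.frame with columns `sex`, `anatom_site`, `age` (one row per
#'   record), all values drawn from the closed category sets.
#' @export
generate_metadata <- function(n, seed = 1L,
                              sex_probs = default_sex_probs(),
                              site_probs = default_site_probs(),
                              age_probs = default_age_probs()) {
  if (n < 0) stop("n must be >= 0")
  cb <- metadata_codebook()
  stopifnot(all(names(sex_probs) %in% cb$sex),
            all(names(site_probs) %in% cb$anatom_site),
            all(as.integer(names(age_probs)) %in% cb$age))
  if (n == 0)
    return(data.frame(sex = character(), anatom_site = character(),
                      age = integer(), stringsAsFactors = FALSE))
  with_seed(seed, data.frame(
    sex = sample(names(sex_probs), n, replace = TRUE, prob = sex_probs),
    anatom_site = sample(names(site_probs), n, replace = TRUE, prob = site_probs),
    age = as.integer(sample(names(age_probs), n, replace = TRUE, prob = age_probs)),
    stringsAsFactors = FALSE))
}

## Class -> appearance lookup making labels learnable from pixels: the
## lesion gets darker and slightly more elongated as the class index rises.
## A fixed deterministic mapping so a tiny model can overfit end to end.
class_appearance <- function(class_index, height, width) {
  gray <- 160 - 11 * class_index
  list(lesion_level = c(gray + 10, gray - 10, gray - 20),
       lesion_axes = c(height * (0.30 - 0.012 * class_index),
                       width * (0.18 + 0.012 * class_index)))
}

#' Generate a labeled synthetic dataset
#'
#' Produces a class-balanced list of samples, each with an image whose lesion
#' appearance is a fixed function of the class index (see Details), optional
#' hair occlusion with its exact ground-truth mask, and a metadata record.
#'
#' @details The class-to-appearance coupling is a lookup, not noise: lesion
#' mean intensity decreases linearly with the class index and the ellipse
#' aspect ratio shifts with it, so the labels are learnable from pixels alone
#' and a small model can overfit the set. This makes the dataset a plumbing
#' fixture for end-to-end tests, not a photorealistic benchmark.
#'
#' @param n_per_class samples per class.
#' @param classes subset of [lesion_classes()].
#' @param seed integer RNG seed.
#' @param height,width image size in pixels.
#' @param hair_strokes number of hair strokes per image (0 = no occlusion).
#' @param noise_sd pixel noise standard deviation.
#' @return list of samples; each sample is a list with `image`,
#'   `hair_mask_truth`, `label` and `metadata` (one-row data.frame).
#' @export
generate_dataset <- function(n_per_class, classes = lesion_classes(), seed = 1L,
                             height = 128, width = 128, hair_strokes = 0,
                             noise_sd = 2) {
  idx <- encode_label(classes)  # errors on unknown class names
  meta <- generate_metadata(n_per_class * length(classes), seed = seed + 7L)
  samples <- vector("list", n_per_class * length(classes))
  s <- 0L
  for (ci in seq_along(classes)) {
    app <- class_appearance(idx[ci], height, width)
    for (k in seq_len(n_per_class)) {
      s <- s + 1L
      sub_seed <- (seed * 1009L + s * 97L) %% 2147483647L
      spec <- lesion_image_spec(
        height = height, width = width,
        lesion_center = c(height / 2, width / 2),
        lesion_axes = app$lesion_axes, lesion_level = app$lesion_level,
        noise_sd = noise_sd, seed = sub_seed)
      img <- generate_lesion_image(spec)
      mask <- matrix(FALSE, height, width)
      if (hair_strokes > 0) {
        ov <- overlay_hair(img, hair_overlay_spec(
          n_strokes = hair_strokes, seed = sub_seed + 1L))
        img <- ov$image
        mask <- ov$mask
      }
      samples[[s]] <- list(image = img, hair_mask_truth = mask,
                           label = classes[ci], metadata = meta[s, , drop = FALSE])
    }
  }
  samples
}

#' Write a synthetic dataset to disk
#'
#' Writes each image as ASCII PPM, each ground-truth hair mask as ASCII PGM
#' (0/255), and a `manifest.csv` with columns `filename`, `mask_filename`,
#' `label`, `sex`, `age`, `anatom_site` — the layout the rest of the pipeline
#' reads.
#'
#' @param samples list of samples from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return path to the manifest, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(samples), function(i) {
    sm <- samples[[i]]
    fn <- sprintf("sample_%04d.ppm", i)
    mfn <- sprintf("sample_%04d_mask.pgm", i)
    write_netpbm(sm$image, file.path(dir, fn))
    write_netpbm(matrix(255 * sm$hair_mask_truth,
                        nrow(sm$hair_mask_truth)), file.path(dir, mfn))
    data.frame(filename = fn, mask_filename = mfn, label = sm$label,
               sex = sm$metadata$sex, age = sm$metadata$age,
               anatom_site = sm$metadata$anatom_site,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
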