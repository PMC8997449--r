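## Affine augmentation, class balancing and the 80/20 train/validation
## split. Augmentation is applied only to training data (after the split)
## to avoid leakage into validation.

#' Apply an affine transformation to an image
#'
#' Supported kinds: `rotation` (degrees, counter-clockwise; right-angle
#' rotations are exact index permutations, other angles use bilinear
#' interpolation about the image centre with edge replication), `shift`
#' (integer `(dx, dy)` = (rows down, cols right), edge-replicated),
#' `reflection` (`axis = "horizontal"` flips left/right, `"vertical"` flips
#' up/down; an involution), `scaling` (`factor > 0`, bilinear), and `crop`
#' (`box = c(row1, col1, row2, col2)` inclusive, inside the image).
#'
#' @param image H x W x 3 array.
#' @param kind one of `"rotation"`, `"shift"`, `"reflection"`, `"scaling"`,
#'   `"crop"`.
#' @param angle rotation angle in degrees.
#' @param shift integer `(dx, dy)` displacement in pixels.
#' @param axis reflection axis.
#' @param factor scaling factor.
#' @param box crop box `c(row1, col1, row2, col2)`.
#' @return transformed H' x W' x 3 array; deterministic for fixed arguments.
#' @export
apply_affine <- function(image,
                         kind = c("rotation", "shift", "reflection", "scaling", "crop"),
                         angle = 0, shift = c(0, 0),
                         axis = c("horizontal", "vertical"),
                         factor = 1, box = NULL) {
  assert_color_image(image)
  kind <- match.arg(kind)
  h <- dim(image)[1]; w <- dim(image)[2]
  switch(kind,
    rotation = rotate_image(image, angle),
    shift = {
      dx <- as.integer(round(shift[1])); dy <- as.integer(round(shift[2]))
      src_i <- pmin(pmax(seq_len(h) - dx, 1L), h)
      src_j <- pmin(pmax(seq_len(w) - dy, 1L), w)
      image[src_i, src_j, , drop = FALSE]
    },
    reflection = {
      axis <- match.arg(axis)
      if (axis == "horizontal") image[, w:1, , drop = FALSE]
      else image[h:1, , , drop = FALSE]
    },
    scaling = {
      if (factor <= 0) stop("scaling factor must be > 0")
      resize_for_backbone(image, c(max(1L, round(h * factor)),
                                   max(1L, round(w * factor))))
    },
    crop = {
      if (is.null(box) || length(box) != 4) stop("crop requires box = c(row1, col1, row2, col2)")
      if (box[1] < 1 || box[2] < 1 || box[3] > h || box[4] > w ||
          box[1] > box[3] || box[2] > box[4])
        stop("crop box must lie inside the image")
      image[box[1]:box[3], box[2]:box[4], , drop = FALSE]
    })
}

rotate_image <- function(image, angle) {
  h <- dim(image)[1]; w <- dim(image)[2]
  a <- angle %% 360
  if (a == 0) return(image)
  ## right angles: exact index permutations (90 deg CCW sends (i,j) of an
  ## H x W image to (W+1-j, i) in the W x H result)
  if (a == 90) return(aperm(image, c(2, 1, 3))[w:1, , , drop = FALSE])
  if (a == 180) return(image[h:1, w:1, , drop = FALSE])
  if (a == 270) return(aperm(image, c(2, 1, 3))[, h:1, , drop = FALSE])
  ## general angle: inverse-map each output pixel centre and interpolate
  th <- -a * pi / 180
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  gi <- rep(seq_len(h), times = w) - ci
  gj <- rep(seq_len(w), each = h) - cj
  si <- cos(th) * gi - sin(th) * gj + ci
  sj <- sin(th) * gi + cos(th) * gj + cj
  out <- array(0, dim = dim(image))
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinear_sample(image[, , ch], si, sj), h, w)
  out
}

## bilinear sample with edge replication at fractional (si, sj)
bilinear_sample <- function(plane, si, sj) {
  h <- nrow(plane); w <- ncol(plane)
  i0 <- pmin(pmax(floor(si), 1), h); i1 <- pmin(i0 + 1, h)
  j0 <- pmin(pmax(floor(sj), 1), w); j1 <- pmin(j0 + 1, w)
  fi <- pmin(pmax(si - i0, 0), 1); fj <- pmin(pmax(sj - j0, 0), 1)
  at <- function(ii, jj) plane[(jj - 1) * h + ii]
  (1 - fi) * (1 - fj) * at(i0, j0) + (1 - fi) * fj * at(i0, j1) +
    fi * (1 - fj) * at(i1, j0) + fi * fj * at(i1, j1)
}

#' Resize an image for a classifier backbone
#'
#' Bilinear resampling with half-pixel centre alignment (output pixel
#' centres map uniformly onto input pixel centres), so resizing to the
#' image's own size is exact and 2x downscaling averages 2x2 blocks.
#'
#' @param image H x W x 3 array.
#' @param target `(H', W')`, both >= 1 (e.g. `c(227, 227)` or `c(224, 224)`
#'   for the classic pretrained backbones).
#' @return H' x W' x 3 array.
#' @export
resize_for_backbone <- function(image, target) {
  assert_color_image(image)
  if (any(target < 1)) stop("target size must be >= 1 x 1")
  h <- dim(image)[1]; w <- dim(image)[2]
  th <- as.integer(target[1]); tw <- as.integer(target[2])
  si <- (seq_len(th) - 0.5) * h / th + 0.5
  sj <- (seq_len(tw) - 0.5) * w / tw + 0.5
  gi <- rep(si, times = tw)
  gj <- rep(sj, each = th)
  out <- array(0, dim = c(th, tw, 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinear_sample(image[, , ch], gi, gj), th, tw)
  out
}

## documented default ranges for random augmentation specs
random_affine <- function(image) {
  kind <- sample(c("rotation", "shift", "reflection", "scaling"), 1)
  switch(kind,
    rotation = apply_affine(image, "rotation", angle = runif(1, -30, 30)),
    shift = apply_affine(image, "shift",
                         shift = round(c(runif(1, -0.1, 0.1) * dim(image)[1],
                                         runif(1, -0.1, 0.1) * dim(image)[2]))),
    reflection = apply_affine(image, "reflection",
                              axis = sample(c("horizontal", "vertical"), 1)),
    scaling = {
      scaled <- apply_affine(image, "scaling", factor = runif(1, 0.9, 1.1))
      resize_for_backbone(scaled, dim(image)[1:2])  # back to original frame
    })
}

#' Balance classes by affine augmentation
#'
#' Every class is brought up to the size of the largest class by appending
#' affine-transformed copies (random rotation within +/-30 degrees, shift
#' within +/-10%, flips, scale 0.9-1.1) of randomly chosen originals — never
#' raw duplicates. All original samples are preserved.
#'
#' @param samples list of samples (as from [generate_dataset()]), each with
#'   `image` and `label`.
#' @param seed integer RNG seed.
#' @return list of samples with equal class counts; augmented samples carry
#'   `augmented = TRUE`.
#' @export
balance_classes <- function(samples, seed = 1L) {
  labels <- vapply(samples, `[[`, character(1), "label")
  counts <- table(labels)
  if (any(counts == 0)) stop("every class must have at least one sample")
  target <- max(counts)
  with_seed(seed, {
    extra <- list()
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need == 0) next
      pool <- which(labels == cl)
      pick <- sample(pool, need, replace = TRUE)
      for (p in pick) {
        sm <- samples[[p]]
        sm$image <- random_affine(sm$image)
        sm$augmented <- TRUE
        extra[[length(extra) + 1L]] <- sm
      }
    }
    c(samples, extra)
  })
}

#' Stratified train/validation split
#'
#' Partitions the samples into disjoint train and validation sets whose
#' union is the input. With `stratified = TRUE` (default) the train fraction
#' holds per class to within one sample.
#'
#' @param samples list of samples with a `label` field.
#' @param train_fraction fraction assigned to training, in (0, 1);
#'   default 0.8 for the standard 80/20 split.
#' @param stratified split within each class.
#' @param seed integer RNG seed.
#' @return list with `train` and `val` sample lists.
#' @export
split_train_val <- function(samples, train_fraction = 0.8, stratified = TRUE,
                            seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  labels <- vapply(samples, `[[`, character(1), "label")
  with_seed(seed, {
    if (stratified) {
      counts <- table(labels)
      if (any(counts < 2)) stop("stratified split needs >= 2 samples per class")
      train_idx <- unlist(lapply(names(counts), function(cl) {
        pool <- which(labels == cl)
        n_tr <- min(max(round(length(pool) * train_fraction), 1L),
                    length(pool) - 1L)
        sample(pool, n_tr)
      }))
    } else {
      n_tr <- min(max(round(length(samples) * train_fraction), 1L),
                  length(samples) - 1L)
      train_idx <- sample(seq_along(samples), n_tr)
    }
    train_idx <- sort(train_idx)
    list(train = samples[train_idx], val = samples[-train_idx])
  })
}
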