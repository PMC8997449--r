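## Shared image helpers: validation, rounding, seeded RNG, NetPBM I/O.

#' Clamp values to the 8-bit intensity range
#'
#' @param x numeric vector, matrix or array.
#' @return `x` with every value forced into \[0, 255\].
#' @keywords internal
clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

## round-half-up (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
assert_color_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop(sprintf("`%s` has non-positive dimensions", arg), call. = FALSE)
  invisible(image)
}

#' @noRd
assert_plane <- function(plane, arg = "plane") {
  if (!is.matrix(plane))
    stop(sprintf("`%s` must be an H x W matrix", arg), call. = FALSE)
  invisible(plane)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All generators route their randomness through this so they are pure
## functions of (spec, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Write an image as a plain-text NetPBM file
#'
#' RGB arrays are written as ASCII PPM (`P3`), single-channel matrices as
#' ASCII PGM (`P2`). NetPBM is used because it is a text format that needs no
#' external codec; any image viewer or converter understands it.
#'
#' @param image H x W x 3 array or H x W matrix, intensities 0-255.
#' @param path output file path (conventionally `.ppm` / `.pgm`).
#' @return `path`, invisibly.
#' @export
#' @examples
#' img <- generate_lesion_image(lesion_image_spec(height = 8, width = 8, seed = 1))
#' f <- tempfile(fileext = ".ppm")
#' write_netpbm(img, f)
#' all.equal(read_netpbm(f), img)
write_netpbm <- function(image, path) {
  if (is.matrix(image)) {
    vals <- as.integer(round_half_up(clip255(t(image))))
    header <- c("P2", paste(ncol(image), nrow(image)), "255")
  } else {
    assert_color_image(image)
    h <- dim(image)[1]; w <- dim(image)[2]
    ## PPM is row-major with interleaved RGB triplets
    px <- aperm(image, c(3, 2, 1))  # channel fastest, then column, then row
    vals <- as.integer(round_half_up(clip255(as.vector(px))))
    header <- c("P3", paste(w, h), "255")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' Read a plain-text NetPBM image
#'
#' @param path a `P2` (PGM) or `P3` (PPM) file as written by [write_netpbm()].
#' @return H x W matrix for PGM, H x W x 3 array for PPM.
#' @export
read_netpbm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1]
  dims <- as.integer(toks[2:4])  # width, height, maxval
  w <- dims[1]; h <- dims[2]
  vals <- as.numeric(toks[-(1:4)])
  if (magic == "P2") {
    if (length(vals) != w * h) stop("corrupt PGM payload")
    t(matrix(vals, nrow = w, ncol = h))
  } else if (magic == "P3") {
    if (length(vals) != 3 * w * h) stop("corrupt PPM payload")
    px <- array(vals, dim = c(3, w, h))
    aperm(px, c(3, 2, 1))
  } else {
    stop("unsupported NetPBM magic number: ", magic)
  }
}
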