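## Morphological hair identification and removal.
##
## Per colour channel: grayscale closing with a disk L1 fills dark, thin
## structures (hair); subtracting the original isolates them; threshold
## zeroing at K discards low-contrast residue; dilation with a smaller disk
## L2 expands the detection to cover stroke borders; the detected pixels are
## then replaced by the harmonic (Laplace-equation) extension of the
## surrounding skin. Channels are processed independently and re-merged.

#' Disk structuring element
#'
#' The metric ball \{(dx, dy) : rho((0,0),(dx,dy)) <= r\} used as the flat
#' footprint for grayscale morphology. Euclidean metric by default.
#'
#' @param r radius in pixels, >= 1.
#' @param metric `"euclidean"` (disk), `"chebyshev"` (square) or
#'   `"manhattan"` (diamond).
#' @return object of class `structuring_element` with an `offsets` matrix
#'   (one `(dx, dy)` row per footprint member). The footprint always contains
#'   the origin and is symmetric under negation.
#' @export
#' @examples
#' nrow(structuring_element(1)$offsets)  # the 5-pixel cross
structuring_element <- function(r, metric = c("euclidean", "chebyshev", "manhattan")) {
  metric <- match.arg(metric)
  if (r < 1) stop("radius must be >= 1")
  g <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
  d <- switch(metric,
              euclidean = sqrt(g$dx^2 + g$dy^2),
              chebyshev = pmax(abs(g$dx), abs(g$dy)),
              manhattan = abs(g$dx) + abs(g$dy))
  keep <- d <= r
  structure(list(r = r, metric = metric,
                 offsets = as.matrix(g[keep, , drop = FALSE])),
            class = "structuring_element")
}

#' Default hair-removal configuration
#'
#' The defaults are the empirically optimal settings for dark-hair detection:
#' closing disk radius `r1 = 5`, boundary-expansion disk radius `r2 = 3`, and
#' residual threshold `K = 40` intensity units.
#'
#' @param r1 radius of the closing element L1.
#' @param r2 radius of the dilation element L2.
#' @param threshold K, the contrast threshold in intensity units (0-255);
#'   residual values `> K` are kept, values `<= K` are zeroed.
#' @param inpaint_tolerance maximum allowed deviation of an inpainted pixel
#'   from the mean of its in-image 4-neighbours, intensity units.
#' @param inpaint_max_iterations iteration cap for the iterative fallback
#'   solver.
#' @return object of class `hair_removal_config`.
#' @export
hair_removal_config <- function(r1 = 5, r2 = 3, threshold = 40,
                                inpaint_tolerance = 1e-3,
                                inpaint_max_iterations = 10000) {
  if (r1 < 1 || r2 < 1) stop("structuring-element radii must be >= 1")
  if (threshold < 0 || threshold > 255) stop("threshold must lie in [0, 255]")
  structure(list(r1 = r1, r2 = r2, threshold = threshold,
                 inpaint_tolerance = inpaint_tolerance,
                 inpaint_max_iterations = as.integer(inpaint_max_iterations)),
            class = "hair_removal_config")
}

#' Split an RGB image into channel planes
#'
#' @param image H x W x 3 array.
#' @return list of three H x W matrices named `R`, `G`, `B`.
#' @export
split_channels <- function(image) {
  assert_color_image(image)
  list(R = image[, , 1], G = image[, , 2], B = image[, , 3])
}

#' Merge channel planes back into an RGB image
#'
#' Exact inverse of [split_channels()].
#'
#' @param planes list of three H x W matrices (R, G, B order).
#' @return H x W x 3 array.
#' @export
merge_channels <- function(planes) {
  stopifnot(length(planes) == 3L)
  array(c(planes[[1]], planes[[2]], planes[[3]]),
        dim = c(nrow(planes[[1]]), ncol(planes[[1]]), 3))
}

## Flat grayscale morphology by shifted-submatrix max/min. The footprint is
## clipped at image edges: the extremum runs over in-image pixels only, so
## no padding value can leak into the result.
morph_extremum <- function(plane, se, op = c("max", "min")) {
  assert_plane(plane)
  stopifnot(inherits(se, "structuring_element"))
  op <- match.arg(op)
  h <- nrow(plane); w <- ncol(plane)
  acc <- matrix(if (op == "max") -Inf else Inf, h, w)
  f <- if (op == "max") pmax else pmin
  for (k in seq_len(nrow(se$offsets))) {
    di <- se$offsets[k, 1]; dj <- se$offsets[k, 2]
    ri <- max(1, 1 - di):min(h, h - di)
    cj <- max(1, 1 - dj):min(w, w - dj)
    acc[ri, cj] <- f(acc[ri, cj], plane[ri + di, cj + dj])
  }
  acc
}

#' Grayscale dilation, erosion and closing
#'
#' Flat morphology over the structuring element's footprint: dilation is the
#' pixelwise maximum, erosion the minimum, and closing is dilation followed
#' by erosion with the same element. At image borders the footprint is
#' clipped to in-image pixels. Closing is extensive (`result >= plane`) and
#' idempotent.
#'
#' @param plane H x W intensity matrix.
#' @param se a [structuring_element()].
#' @return H x W matrix.
#' @export
morph_dilate <- function(plane, se) morph_extremum(plane, se, "max")

#' @rdname morph_dilate
#' @export
morph_erode <- function(plane, se) morph_extremum(plane, se, "min")

#' @rdname morph_dilate
#' @export
morph_close <- function(plane, se) morph_erode(morph_dilate(plane, se), se)

#' Subtract the original channel from its closing
#'
#' Computed in floating point; when `closed` really is the closing of
#' `original` the difference is guaranteed non-negative (closing is
#' extensive).
#'
#' @param closed,original H x W matrices of identical shape.
#' @return H x W matrix `closed - original`.
#' @export
subtract_planes <- function(closed, original) {
  if (!identical(dim(closed), dim(original))) stop("shape mismatch")
  closed - original
}

#' Threshold zeroing
#'
#' Keeps values strictly greater than `K` and zeroes the rest:
#' `out = plane` where `plane > K`, else `0`. Idempotent for fixed `K`.
#'
#' @param plane H x W matrix.
#' @param K intensity threshold in \[0, 255\].
#' @return H x W matrix.
#' @export
threshold_zero <- function(plane, K) {
  assert_plane(plane)
  if (K < 0 || K > 255) stop("K must lie in [0, 255]")
  plane * (plane > K)
}

#' Support mask of a detection plane
#'
#' @param dilated H x W matrix (the dilated thresholded residual).
#' @return H x W logical, `TRUE` where the plane is nonzero.
#' @export
extract_mask <- function(dilated) {
  assert_plane(dilated)
  dilated > 0
}

#' Laplace-equation inpainting
#'
#' Replaces masked pixels by the discrete harmonic extension of the
#' surrounding values: each masked pixel ends up equal to the mean of its
#' in-image 4-neighbours (Dirichlet data taken from the ring of unmasked
#' pixels adjacent to the mask, which are never modified). Solved as a
#' sparse linear system; the harmonic residual is verified against
#' `inpaint_tolerance` afterwards. Mask components with no unmasked
#' 4-neighbour carry no boundary data and are filled with the plane's global
#' unmasked median.
#'
#' @param plane H x W matrix.
#' @param mask H x W logical; must not cover the whole plane.
#' @param config a [hair_removal_config()] (supplies the tolerance).
#' @return H x W matrix: unmasked pixels bit-identical to the input, masked
#'   pixels harmonic, values clipped to \[0, 255\].
#' @export
inpaint_laplace <- function(plane, mask, config = hair_removal_config()) {
  assert_plane(plane)
  if (!identical(dim(mask), dim(plane))) stop("mask/plane shape mismatch")
  if (all(mask)) stop("mask covers the entire image: no boundary data to interpolate from")
  if (!any(mask)) return(plane)
  h <- nrow(plane); w <- ncol(plane)

  idx <- matrix(0L, h, w)
  unk <- which(mask)
  idx[unk] <- seq_along(unk)
  n <- length(unk)
  ui <- ((unk - 1L) %% h) + 1L
  uj <- ((unk - 1L) %/% h) + 1L

  ## assemble n x n Laplacian: deg * x_p - sum_{unmasked nb} x_q = sum known
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  rhs <- numeric(n); deg <- integer(n)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    ni <- ui + d[1]; nj <- uj + d[2]
    ok <- ni >= 1L & ni <= h & nj >= 1L & nj <= w
    deg[ok] <- deg[ok] + 1L
    nb <- (nj[ok] - 1L) * h + ni[ok]
    nb_unk <- idx[nb]
    inner <- nb_unk > 0L
    p <- which(ok)
    trip_i <- c(trip_i, p[inner])
    trip_j <- c(trip_j, nb_unk[inner])
    trip_x <- c(trip_x, rep(-1, sum(inner)))
    rhs[p[!inner]] <- rhs[p[!inner]] + plane[nb[!inner]]
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n), trip_i), j = c(seq_len(n), trip_j),
                            x = c(as.numeric(deg), trip_x), dims = c(n, n))
  ## pixels whose component has no Dirichlet data make A singular; detect
  ## them as the components unreachable from any boundary-fed pixel
  fed <- components_with_boundary(idx, ui, uj, rhs, h, w)
  out <- plane
  if (any(!fed)) {
    fill <- median(plane[!mask])
    out[unk[!fed]] <- fill
  }
  if (any(fed)) {
    keep <- which(fed)
    sub <- A[keep, keep, drop = FALSE]
    sol <- Matrix::solve(sub, rhs[keep])
    out[unk[keep]] <- as.numeric(sol)
    resid <- harmonic_residual(out, mask & replace(matrix(FALSE, h, w), unk[keep], TRUE))
    if (resid > config$inpaint_tolerance)
      stop(sprintf("inpainting failed to converge: harmonic residual %.3g > tolerance %.3g",
                   resid, config$inpaint_tolerance))
  }
  clip255(out)
}

## Flood-fill over the 4-connected mask graph, seeded at pixels that received
## any Dirichlet contribution; returns per-unknown logical "has boundary".
components_with_boundary <- function(idx, ui, uj, rhs, h, w) {
  n <- length(ui)
  fed <- rhs > 0 | vapply(seq_len(n), function(p) {
    ## rhs == 0 can also mean a boundary neighbour of value 0: check directly
    any(vapply(list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L)), function(d) {
      ni <- ui[p] + d[1]; nj <- uj[p] + d[2]
      ni >= 1L && ni <= h && nj >= 1L && nj <= w && idx[ni, nj] == 0L
    }, logical(1)))
  }, logical(1))
  queue <- which(fed)
  seen <- fed
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ni <- ui[p] + d[1]; nj <- uj[p] + d[2]
      if (ni >= 1L && ni <= h && nj >= 1L && nj <= w) {
        q <- idx[ni, nj]
        if (q > 0L && !seen[q]) {
          seen[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  seen
}

## max over masked pixels of |value - mean(in-image 4-neighbours)|
harmonic_residual <- function(plane, mask) {
  h <- nrow(plane); w <- ncol(plane)
  if (!any(mask)) return(0)
  unk <- which(mask)
  ui <- ((unk - 1L) %% h) + 1L
  uj <- ((unk - 1L) %/% h) + 1L
  s <- numeric(length(unk)); cnt <- integer(length(unk))
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    ni <- ui + d[1]; nj <- uj + d[2]
    ok <- ni >= 1L & ni <= h & nj >= 1L & nj <= w
    s[ok] <- s[ok] + plane[(nj[ok] - 1L) * h + ni[ok]]
    cnt[ok] <- cnt[ok] + 1L
  }
  max(abs(plane[unk] - s / cnt))
}

#' Identify and remove hair structures from a dermoscopic image
#'
#' Runs the full per-channel pipeline: split into R, G, B; grayscale closing
#' with disk L1 (radius `r1`); subtract the original; threshold-zero at `K`;
#' dilate with disk L2 (radius `r2`); take the support as the channel's hair
#' mask; inpaint the masked pixels by Laplace interpolation; merge the
#' cleaned channels. Dark hair strictly thinner than the L1 diameter with
#' contrast above `K` is detected; light hair is not (a documented limit of
#' the closing-based scheme).
#'
#' @param image H x W x 3 array, intensities 0-255.
#' @param config a [hair_removal_config()].
#' @param keep_intermediates if `TRUE`, attach the per-channel intermediate
#'   planes (closed, difference, thresholded, dilated) for inspection.
#' @return object of class `cleaned_image`: a list with `image` (cleaned,
#'   integer-valued in \[0, 255\]), `masks` (per-channel logicals),
#'   `merged_mask` (their union) and optionally `intermediates`. Pixels
#'   outside `merged_mask` are bit-identical to the input.
#' @export
#' @examples
#' spec <- lesion_image_spec(height = 48, width = 48, noise_sd = 0, seed = 3)
#' hairy <- overlay_hair(generate_lesion_image(spec),
#'                       hair_overlay_spec(n_strokes = 2, seed = 4))
#' res <- remove_hair(hairy$image)
#' mean(res$merged_mask[hairy$mask])  # recall of the true hair pixels
remove_hair <- function(image, config = hair_removal_config(),
                        keep_intermediates = FALSE) {
  assert_color_image(image)
  stopifnot(inherits(config, "hair_removal_config"))
  L1 <- structuring_element(config$r1)
  L2 <- structuring_element(config$r2)
  planes <- split_channels(image)
  cleaned <- vector("list", 3)
  masks <- vector("list", 3)
  inter <- vector("list", 3)
  for (ch in 1:3) {
    p <- planes[[ch]]
    closed <- morph_close(p, L1)
    diff <- subtract_planes(closed, p)
    thr <- threshold_zero(diff, config$threshold)
    dil <- morph_dilate(thr, L2)
    mask <- extract_mask(dil)
    filled <- if (any(mask)) inpaint_laplace(p, mask, config) else p
    cleaned[[ch]] <- clip255(round_half_up(filled))
    masks[[ch]] <- mask
    if (keep_intermediates)
      inter[[ch]] <- list(closed = closed, difference = diff,
                          thresholded = thr, dilated = dil)
  }
  names(masks) <- names(planes)
  out <- list(image = merge_channels(cleaned), masks = masks,
              merged_mask = masks[[1]] | masks[[2]] | masks[[3]])
  if (keep_intermediates) {
    names(inter) <- names(planes)
    out$intermediates <- inter
  }
  structure(out, class = "cleaned_image")
}

#' @export
print.cleaned_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("cleaned_image: %d x %d, %d hair pixels replaced (%.2f%%)\n",
              d[1], d[2], sum(x$merged_mask),
              100 * mean(x$merged_mask)))
  invisible(x)
}
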