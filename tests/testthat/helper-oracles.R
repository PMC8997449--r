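# Independent brute-force oracles. These deliberately share no code with
# the package internals: per-pixel loops, explicit summation, pairwise
# concordance counting.

# flat grayscale morphology by explicit per-pixel extremum over the
# Euclidean disk of radius r, footprint clipped at image edges
oracle_morph <- function(plane, r, op = c("dilate", "erode")) {
  op <- match.arg(op)
  f <- if (op == "dilate") max else min
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2, ]
  h <- nrow(plane); w <- ncol(plane)
  out <- plane
  storage.mode(out) <- "double"  # package morphology always returns double
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ii <- i + offs$di; jj <- j + offs$dj
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    out[i, j] <- f(plane[cbind(ii[ok], jj[ok])])
  }
  out
}

oracle_close <- function(plane, r) {
  oracle_morph(oracle_morph(plane, r, "dilate"), r, "erode")
}

# discrete ellipse area by brute-force membership testing
oracle_ellipse_area <- function(h, w, center, axes) {
  n <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (((i - center[1]) / axes[1])^2 + ((j - center[2]) / axes[2])^2 <= 1)
      n <- n + 1L
  }
  n
}

# Triple-loop valid-region correlation with symmetric index window and
# additive offset
oracle_conv <- function(P, W, g) {
  w <- dim(W)[1]; cc <- (w - 1) / 2
  H <- dim(P)[1]; Wd <- dim(P)[2]; D <- dim(P)[3]
  out <- matrix(0, H - w + 1, Wd - w + 1)
  for (x in (cc + 1):(H - cc)) for (y in (cc + 1):(Wd - cc)) {
    s <- g
    for (i in -cc:cc) for (j in -cc:cc) for (k in seq_len(D))
      s <- s + W[i + cc + 1, j + cc + 1, k] * P[x + i, y + j, k]
    out[x - cc, y - cc] <- s
  }
  out
}

# explicit double-sum fusion oracle
oracle_fuse <- function(fm, m, iw, mw) {
  L <- dim(iw)[length(dim(iw))]
  iw_flat <- matrix(iw, ncol = L)
  fm_flat <- as.numeric(fm)
  out <- numeric(L)
  for (l in seq_len(L)) {
    s <- 0
    for (p in seq_along(fm_flat)) s <- s + fm_flat[p] * iw_flat[p, l]
    for (i in seq_along(m)) s <- s + m[i] * mw[i, l]
    out[l] <- s
  }
  out
}

# AUC by exhaustive pairwise concordance (Mann-Whitney), ties count half
oracle_auc <- function(scores, truths) {
  pos <- scores[as.logical(truths)]
  neg <- scores[!as.logical(truths)]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

random_plane <- function(h = 9, w = 9) {
  matrix(as.double(sample(0:255, h * w, replace = TRUE)), h, w)
}

random_legal_record <- function() {
  cb <- metadata_codebook()
  list(sex = sample(cb$sex, 1),
       anatom_site = sample(cb$anatom_site, 1),
       age = sample(cb$age, 1))
}
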