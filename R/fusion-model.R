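## Multimodal image + metadata fusion classifier.
##
## The image branch is a small convolutional network (valid-region
## correlation with an additive offset per filter, ReLU, 2x2 max-pooling)
## producing a feature map {x_ijk}. The metadata branch is a stack of linear
## layers with ReLU. The fusion layer combines both linearly,
##   f_l = sum_ijk x_ijk w2[ijk,l] + sum_i m_i w3[i,l],
## (no bias, matching the concatenation-layer formulation), and a softmax
## head over per-class affine scores yields the 10-category posterior.
## Everything — forward pass, backprop, SGD with momentum — is implemented
## here so the model runs at desk scale with no deep-learning dependency.

#' 2-D convolution of a channel stack (valid region, additive offset)
#'
#' Computes `out(x, y) = g + sum_{i,j,k} W[i, j, k] * P[x+i-1, y+j-1, k]`
#' over every position where the `w x w` window fits entirely inside the
#' image (valid-region correlation with a symmetric index window).
#'
#' @param plane_stack H x W x D numeric array.
#' @param filter list with `weights` (`w x w x D` array, `w` odd) and
#'   `offset` (scalar `g`).
#' @return `(H - w + 1) x (W - w + 1)` feature-map plane.
#' @export
conv2d <- function(plane_stack, filter) {
  if (length(dim(plane_stack)) == 2L)
    plane_stack <- array(plane_stack, dim = c(dim(plane_stack), 1L))
  W <- filter$weights
  if (length(dim(W)) == 2L) W <- array(W, dim = c(dim(W), 1L))
  w <- dim(W)[1]
  if (w %% 2L == 0L) stop("filter size w must be odd")
  h <- dim(plane_stack)[1]; wd <- dim(plane_stack)[2]; D <- dim(plane_stack)[3]
  if (w > h || w > wd) stop("filter larger than image")
  if (dim(W)[3] != D) stop("filter depth must match the channel count")
  oh <- h - w + 1L; ow <- wd - w + 1L
  out <- matrix(filter$offset, oh, ow)
  for (k in seq_len(D)) for (a in seq_len(w)) for (b in seq_len(w)) {
    wt <- W[a, b, k]
    if (wt != 0)
      out <- out + wt * plane_stack[a:(a + oh - 1L), b:(b + ow - 1L), k]
  }
  out
}

#' Fuse an image feature map with a metadata vector
#'
#' The concatenation-layer map: each output unit `l` is the joint linear
#' functional `f_l = sum_ijk x_ijk w2[ijk, l] + sum_i m_i w3[i, l]` —
#' algebraically identical to flattening, concatenating and applying one
#' bias-free linear layer.
#'
#' @param feature_map numeric array (any shape) of feature-map values x_ijk.
#' @param metadata numeric vector.
#' @param layer list with `image_weights` (array whose leading dims match
#'   `feature_map` and whose last dim is the output width, or an equivalent
#'   `prod(dim) x L` matrix) and `metadata_weights`
#'   (`length(metadata) x L` matrix).
#' @return numeric vector of length L.
#' @export
fuse <- function(feature_map, metadata, layer) {
  x <- as.numeric(feature_map)
  iw <- layer$image_weights
  L <- dim(iw)[length(dim(iw))]
  iw <- matrix(iw, nrow = length(iw) / L, ncol = L)
  mw <- layer$metadata_weights
  if (nrow(iw) != length(x)) stop("image weight shape does not match the feature map")
  if (nrow(mw) != length(metadata)) stop("metadata weight shape does not match the vector")
  as.numeric(crossprod(iw, x) + crossprod(mw, as.numeric(metadata)))
}

#' Numerically stable softmax classification
#'
#' Scores each class with an affine functional of the input features and
#' normalises with a log-sum-exp-stabilised softmax, so the output is a
#' probability simplex invariant to adding a constant to all logits.
#'
#' @param features numeric feature vector.
#' @param head list with `class_weights` (`n_classes x length(features)`
#'   matrix) and `offsets` (length `n_classes`).
#' @return probability vector summing to 1.
#' @export
softmax_classify <- function(features, head) {
  logits <- as.numeric(head$class_weights %*% features + head$offsets)
  softmax_stable(logits)
}

#' @rdname softmax_classify
#' @param logits raw scores.
#' @export
softmax_stable <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

#' Model configuration
#'
#' @param backbone image-branch architecture. Only `"small_cnn"` ships with
#'   the package; the classic pretrained backbones (`"alexnet"`,
#'   `"squeezenet"`, `"resnet101"`) are recognised for input-size validation
#'   but require pretrained weights that cannot be bundled, so
#'   [build_model()] rejects them.
#' @param input_size `(H, W)`; must be 227x227 for alexnet/squeezenet and
#'   224x224 for resnet101; free for small_cnn.
#' @param n_classes number of diagnostic categories (default 10).
#' @param n_filters,filter_size conv layer of the small_cnn backbone.
#' @param metadata_branch hidden widths of the metadata MLP (input is the
#'   28-dim one-hot vector).
#' @param n_fusion width of the fusion (concatenation) layer.
#' @param learning_rate,momentum,batch_size,epochs SGD settings.
#' @param seed integer seed for initialisation and batch shuffling.
#' @return object of class `model_config`.
#' @export
model_config <- function(backbone = "small_cnn", input_size = c(32, 32),
                         n_classes = 10L, n_filters = 8L, filter_size = 3L,
                         metadata_branch = c(32L, 32L), n_fusion = 64L,
                         learning_rate = 0.01, momentum = 0.9,
                         batch_size = 16L, epochs = 50L, seed = 1L) {
  known <- c("small_cnn", "alexnet", "squeezenet", "resnet101")
  if (!backbone %in% known)
    stop("unknown backbone: ", backbone)
  need <- switch(backbone, alexnet = c(227, 227), squeezenet = c(227, 227),
                 resnet101 = c(224, 224), NULL)
  if (!is.null(need) && !all(input_size == need))
    stop(sprintf("backbone %s requires input size %dx%d", backbone, need[1], need[2]))
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 n_filters = as.integer(n_filters),
                 filter_size = as.integer(filter_size),
                 metadata_branch = as.integer(metadata_branch),
                 n_fusion = as.integer(n_fusion),
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "model_config")
}

#' Build a multimodal fusion model
#'
#' Assembles the image branch, the metadata branch (linear layers + ReLU on
#' the 28-dim one-hot vector), the bias-free fusion layer and the softmax
#' head, with seeded He-scaled Gaussian initialisation.
#'
#' @param config a [model_config()].
#' @return object of class `fusion_model` holding the parameters, their
#'   shapes and the config; `n_parameters` reports the trainable count.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  if (config$backbone != "small_cnn")
    stop("backbone '", config$backbone, "' needs pretrained weights that are ",
         "not bundled; use backbone = \"small_cnn\"")
  fs <- config$filter_size; nf <- config$n_filters
  h <- config$input_size[1]; w <- config$input_size[2]
  ch <- h - fs + 1L; cw <- w - fs + 1L       # conv output (valid)
  ph <- ch %/% 2L; pw <- cw %/% 2L           # after 2x2 max-pool
  if (ph < 1L || pw < 1L) stop("input too small for the conv + pool stack")
  meta_dims <- c(28L, config$metadata_branch)
  L <- config$n_fusion
  with_seed(config$seed, {
    init <- function(...) {
      d <- c(...)
      array(rnorm(prod(d), sd = sqrt(2 / prod(d[-length(d)]))), dim = d)
    }
    params <- list(
      Wc = init(fs, fs, 3L, nf), gc = numeric(nf),
      Wm = lapply(seq_len(length(meta_dims) - 1L), function(i)
        init(meta_dims[i + 1L], meta_dims[i])),
      bm = lapply(seq_len(length(meta_dims) - 1L), function(i)
        numeric(meta_dims[i + 1L])),
      W2 = init(ph * pw * nf, L),
      W3 = init(meta_dims[length(meta_dims)], L),
      Wh = init(config$n_classes, L), gh = numeric(config$n_classes))
    structure(list(params = params, config = config,
                   shapes = list(conv_out = c(ch, cw), pooled = c(ph, pw, nf)),
                   n_parameters = sum(vapply(rapply(params, length, how = "unlist"),
                                             identity, numeric(1))),
                   trained_epochs = 0L),
              class = "fusion_model")
  })
}

## ---- forward / backward ---------------------------------------------------

## forward one sample; returns activations needed for backprop
fm_forward <- function(model, image, mvec) {
  p <- model$params; cfg <- model$config
  x <- image / 255
  fs <- cfg$filter_size; nf <- cfg$n_filters
  conv <- array(0, dim = c(model$shapes$conv_out, nf))
  for (f in seq_len(nf))
    conv[, , f] <- conv2d(x, list(weights = p$Wc[, , , f], offset = p$gc[f]))
  relu <- pmax(conv, 0)
  pooled <- maxpool2(relu)
  ## metadata branch
  a <- as.numeric(mvec)
  acts <- list(a)
  for (i in seq_along(p$Wm)) {
    a <- pmax(as.numeric(p$Wm[[i]] %*% a + p$bm[[i]]), 0)
    acts[[i + 1L]] <- a
  }
  xflat <- as.numeric(pooled$values)
  f_raw <- as.numeric(crossprod(p$W2, xflat) + crossprod(p$W3, a))
  f_act <- pmax(f_raw, 0)
  logits <- as.numeric(p$Wh %*% f_act + p$gh)
  probs <- softmax_stable(logits)
  list(x = x, conv = conv, relu = relu, pooled = pooled, meta_acts = acts,
       xflat = xflat, f_raw = f_raw, f_act = f_act, probs = probs)
}

## 2x2 non-overlapping max pool; keeps argmax positions for backprop
maxpool2 <- function(a) {
  h <- dim(a)[1]; w <- dim(a)[2]; nf <- dim(a)[3]
  ph <- h %/% 2L; pw <- w %/% 2L
  i1 <- seq(1L, 2L * ph, by = 2L); j1 <- seq(1L, 2L * pw, by = 2L)
  vals <- array(0, dim = c(ph, pw, nf))
  arg <- array(0L, dim = c(ph, pw, nf))
  for (f in seq_len(nf)) {
    c11 <- a[i1, j1, f]; c21 <- a[i1 + 1L, j1, f]
    c12 <- a[i1, j1 + 1L, f]; c22 <- a[i1 + 1L, j1 + 1L, f]
    m <- pmax(c11, c21, c12, c22)
    vals[, , f] <- m
    ## first-match argmax, fixed order for determinism
    w4 <- ifelse(m == c11, 1L, ifelse(m == c21, 2L, ifelse(m == c12, 3L, 4L)))
    arg[, , f] <- w4
  }
  list(values = vals, argmax = arg)
}

## gradient of one sample given forward activations; label is 1..n_classes
fm_backward <- function(model, fwd, label) {
  p <- model$params; cfg <- model$config
  g <- list()
  dlogit <- fwd$probs
  dlogit[label] <- dlogit[label] - 1
  g$Wh <- outer(dlogit, fwd$f_act)
  g$gh <- dlogit
  df <- as.numeric(crossprod(p$Wh, dlogit))
  df[fwd$f_raw <= 0] <- 0
  g$W2 <- outer(fwd$xflat, df)
  a_last <- fwd$meta_acts[[length(fwd$meta_acts)]]
  g$W3 <- outer(a_last, df)
  dx <- as.numeric(p$W2 %*% df)
  da <- as.numeric(p$W3 %*% df)
  ## metadata branch
  g$Wm <- vector("list", length(p$Wm)); g$bm <- vector("list", length(p$bm))
  for (i in rev(seq_along(p$Wm))) {
    da[fwd$meta_acts[[i + 1L]] <= 0] <- 0
    g$Wm[[i]] <- outer(da, fwd$meta_acts[[i]])
    g$bm[[i]] <- da
    da <- as.numeric(crossprod(p$Wm[[i]], da))
  }
  ## un-pool, un-relu, conv weight gradients
  sh <- model$shapes
  dpool <- array(dx, dim = sh$pooled)
  dconv <- array(0, dim = c(sh$conv_out, cfg$n_filters))
  ph <- sh$pooled[1]; pw <- sh$pooled[2]
  for (f in seq_len(cfg$n_filters)) {
    arg <- fwd$pooled$argmax[, , f]
    dv <- dpool[, , f]
    pi <- rep(seq_len(ph), times = pw); pj <- rep(seq_len(pw), each = ph)
    di <- 2L * pi - 1L + as.integer(arg %in% c(2L, 4L))
    dj <- 2L * pj - 1L + as.integer(arg %in% c(3L, 4L))
    dpl <- matrix(0, sh$conv_out[1], sh$conv_out[2])
    dpl[cbind(di, dj)] <- as.numeric(dv)
    dpl[fwd$conv[, , f] <= 0] <- 0
    dconv[, , f] <- dpl
  }
  fs <- cfg$filter_size
  oh <- sh$conv_out[1]; ow <- sh$conv_out[2]
  g$Wc <- array(0, dim = dim(p$Wc))
  g$gc <- numeric(cfg$n_filters)
  for (f in seq_len(cfg$n_filters)) {
    d <- dconv[, , f]
    g$gc[f] <- sum(d)
    for (k in 1:3) for (a in seq_len(fs)) for (b in seq_len(fs))
      g$Wc[a, b, k, f] <- sum(d * fwd$x[a:(a + oh - 1L), b:(b + ow - 1L), k])
  }
  g
}

## elementwise parameter update with momentum; v and g mirror params' shape
sgd_step <- function(params, grads, vel, lr, mom) {
  upd <- function(p, g, v) {
    if (is.list(p)) return(Map(upd, p, g, v) )
    v_new <- mom * v - lr * g
    list(p = p + v_new, v = v_new)
  }
  out_p <- params; out_v <- vel
  for (nm in names(params)) {
    if (is.list(params[[nm]])) {
      for (i in seq_along(params[[nm]])) {
        v_new <- mom * vel[[nm]][[i]] - lr * grads[[nm]][[i]]
        out_p[[nm]][[i]] <- params[[nm]][[i]] + v_new
        out_v[[nm]][[i]] <- v_new
      }
    } else {
      v_new <- mom * vel[[nm]] - lr * grads[[nm]]
      out_p[[nm]] <- params[[nm]] + v_new
      out_v[[nm]] <- v_new
    }
  }
  list(params = out_p, vel = out_v)
}

zero_like <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

accumulate <- function(acc, g) {
  for (nm in names(g)) {
    if (is.list(g[[nm]])) {
      for (i in seq_along(g[[nm]]))
        acc[[nm]][[i]] <- acc[[nm]][[i]] + g[[nm]][[i]]
    } else acc[[nm]] <- acc[[nm]] + g[[nm]]
  }
  acc
}

## samples -> list(images = list of arrays, mvecs = matrix, labels = int)
prepare_samples <- function(samples, config) {
  cb <- metadata_codebook()
  imgs <- lapply(samples, function(s) {
    img <- s$image
    if (!all(dim(img)[1:2] == config$input_size))
      img <- resize_for_backbone(img, config$input_size)
    img
  })
  mvecs <- t(vapply(samples, function(s) encode_record(s$metadata, cb),
                    numeric(sum(cb$dims))))
  labels <- encode_label(vapply(samples, `[[`, character(1), "label"))
  list(images = imgs, mvecs = mvecs, labels = labels)
}

#' Train a fusion model
#'
#' Minimises the cross-entropy of the softmax head with mini-batch SGD plus
#' momentum. Deterministic for a fixed config seed (initialisation and batch
#' shuffling both derive from it). Images whose size differs from the
#' config's `input_size` are resized on the fly.
#'
#' @param model a [build_model()] result.
#' @param train_set,val_set sample lists (as from [generate_dataset()]);
#'   `val_set` may be `NULL`.
#' @param epochs number of passes; defaults to the config's value. `0`
#'   returns the model unchanged with an empty history.
#' @return list with `model` (trained) and `history` (data.frame of
#'   per-epoch train/val loss and accuracy).
#' @export
train_model <- function(model, train_set, val_set = NULL,
                        epochs = model$config$epochs) {
  stopifnot(inherits(model, "fusion_model"))
  if (length(train_set) == 0) stop("empty training set")
  cfg <- model$config
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  if (epochs == 0) return(list(model = model, history = hist))
  tr <- prepare_samples(train_set, cfg)
  va <- if (length(val_set)) prepare_samples(val_set, cfg) else NULL
  vel <- zero_like(model$params)
  n <- length(tr$images)
  with_seed(cfg$seed + 1000L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        acc_g <- zero_like(model$params)
        for (s in idx) {
          fwd <- fm_forward(model, tr$images[[s]], tr$mvecs[s, ])
          if (!is.finite(sum(fwd$probs))) stop("training diverged: NaN loss")
          acc_g <- accumulate(acc_g, fm_backward(model, fwd, tr$labels[s]))
        }
        acc_g <- rapply(acc_g, function(x) x / length(idx), how = "replace")
        st <- sgd_step(model$params, acc_g, vel, cfg$learning_rate, cfg$momentum)
        model$params <- st$params
        vel <- st$vel
      }
      trm <- evaluate_on(model, tr)
      if (!is.finite(trm$loss)) stop("training diverged: NaN loss")
      vam <- if (!is.null(va)) evaluate_on(model, va) else list(loss = NA_real_, acc = NA_real_)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = trm$loss,
                                     train_acc = trm$acc, val_loss = vam$loss,
                                     val_acc = vam$acc))
    }
  })
  model$trained_epochs <- model$trained_epochs + epochs
  list(model = model, history = hist)
}

evaluate_on <- function(model, prep) {
  n <- length(prep$images)
  loss <- 0; correct <- 0L
  for (s in seq_len(n)) {
    pr <- fm_forward(model, prep$images[[s]], prep$mvecs[s, ])$probs
    loss <- loss - log(max(pr[prep$labels[s]], 1e-12))
    if (which.max(pr) == prep$labels[s]) correct <- correct + 1L
  }
  list(loss = loss / n, acc = correct / n)
}

#' Predict class probabilities for samples
#'
#' @param object a trained [build_model()] result.
#' @param samples sample list; each needs `image` and `metadata`.
#' @param ... unused.
#' @return list with `probabilities` (n x n_classes matrix, rows on the
#'   probability simplex) and `labels` (argmax class names; ties break to
#'   the lowest class index).
#' @export
predict.fusion_model <- function(object, samples, ...) {
  prep <- prepare_samples(samples, object$config)
  n <- length(prep$images)
  probs <- matrix(0, n, object$config$n_classes)
  for (s in seq_len(n))
    probs[s, ] <- fm_forward(object, prep$images[[s]], prep$mvecs[s, ])$probs
  colnames(probs) <- lesion_classes()[seq_len(object$config$n_classes)]
  list(probabilities = probs,
       labels = lesion_classes()[apply(probs, 1, which.max)])
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("fusion_model (%s): input %dx%d, %d classes, %d parameters, %d epochs trained\n",
              x$config$backbone, x$config$input_size[1], x$config$input_size[2],
              x$config$n_classes, x$n_parameters, x$trained_epochs))
  invisible(x)
}

#' Save / load a fusion model as JSON
#'
#' The checkpoint is a single JSON file with the config and every parameter
#' tensor (shape + values), so it is text-only and platform independent.
#'
#' @param model a `fusion_model`.
#' @param path file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  ser_tensor <- function(x) list(dim = dim(x) %||% length(x), values = as.numeric(x))
  payload <- list(
    config = unclass(model$config),
    shapes = model$shapes,
    trained_epochs = model$trained_epochs,
    params = rapply(model$params, ser_tensor, how = "replace"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  de <- function(x) {
    if (is.list(x) && !is.null(x$values)) {
      v <- as.numeric(x$values)
      if (length(x$dim) > 1L) array(v, dim = as.integer(x$dim)) else v
    } else lapply(x, de)
  }
  cfg <- do.call(model_config, raw$config[names(formals(model_config))[
    names(formals(model_config)) %in% names(raw$config)]])
  params <- lapply(raw$params, de)
  structure(list(params = params, config = cfg,
                 shapes = list(conv_out = as.integer(raw$shapes$conv_out),
                               pooled = as.integer(raw$shapes$pooled)),
                 n_parameters = sum(unlist(rapply(params, length, how = "unlist"))),
                 trained_epochs = raw$trained_epochs),
            class = "fusion_model")
}
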