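test_that("conv2d matches the triple-loop summation oracle", {
  set.seed(11)
  # degenerate filters first
  P <- array(runif(6 * 6 * 2), dim = c(6, 6, 2))
  zero_w <- list(weights = array(0, dim = c(3, 3, 2)), offset = 7)
  expect_true(all(conv2d(P, zero_w) == 7))
  ident <- array(0, dim = c(3, 3, 2)); ident[2, 2, 1] <- 1
  expect_equal(conv2d(P, list(weights = ident, offset = 0)),
               P[2:5, 2:5, 1], tolerance = 1e-12)

  for (rep in 1:20) {
    P <- array(rnorm(6 * 6 * 2), dim = c(6, 6, 2))
    W <- array(rnorm(3 * 3 * 2), dim = c(3, 3, 2))
    g <- rnorm(1)
    got <- conv2d(P, list(weights = W, offset = g))
    expect_equal(got, oracle_conv(P, W, g), tolerance = 1e-9)
  }
  expect_error(conv2d(array(0, c(2, 2, 1)),
                      list(weights = array(0, c(3, 3, 1)), offset = 0)),
               "larger than image")
  expect_error(conv2d(P, list(weights = array(0, c(2, 2, 2)), offset = 0)),
               "odd")
})

test_that("fuse matches the explicit double-sum oracle and is linear", {
  set.seed(22)
  for (rep in 1:20) {
    fm <- array(rnorm(4 * 3 * 2), dim = c(4, 3, 2))
    m <- rnorm(5)
    iw <- array(rnorm(4 * 3 * 2 * 6), dim = c(4, 3, 2, 6))
    mw <- matrix(rnorm(5 * 6), 5, 6)
    layer <- list(image_weights = iw, metadata_weights = mw)
    got <- fuse(fm, m, layer)
    expect_equal(got, oracle_fuse(fm, m, iw, mw), tolerance = 1e-9)
    # additivity and homogeneity
    expect_equal(fuse(2.5 * fm, 2.5 * m, layer), 2.5 * got, tolerance = 1e-9)
    expect_equal(fuse(fm, numeric(5), layer) + fuse(array(0, dim(fm)), m, layer),
                 got, tolerance = 1e-9)
  }
  zl <- list(image_weights = array(0, c(4, 3, 2, 6)),
             metadata_weights = matrix(0, 5, 6))
  expect_identical(fuse(fm, m, zl), numeric(6))
})

test_that("softmax is a stable shift-invariant simplex map", {
  expect_equal(softmax_stable(rep(3, 10)), rep(0.1, 10), tolerance = 1e-12)
  big <- softmax_stable(c(1000, 1000, 1000))
  expect_equal(big, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(softmax_stable(c(0, log(3))), c(0.25, 0.75), tolerance = 1e-12)
  set.seed(33)
  for (rep in 1:50) {
    z <- rnorm(10, sd = 5)
    p <- softmax_stable(z)
    expect_true(all(p > 0))
    expect_lt(abs(sum(p) - 1), 1e-9)
    expect_equal(softmax_stable(z + 123.4), p, tolerance = 1e-9)
  }
  head <- list(class_weights = diag(3), offsets = c(0, 0, 0))
  expect_equal(softmax_classify(c(0, 0, log(3) - log(1)), head),
               c(0.2, 0.2, 0.6), tolerance = 1e-12)
})

test_that("build_model validates configs and initialises deterministically", {
  m1 <- build_model(model_config(input_size = c(16, 16), seed = 7))
  m2 <- build_model(model_config(input_size = c(16, 16), seed = 7))
  expect_identical(m1$params, m2$params)
  expect_gt(m1$n_parameters, 0)
  expect_identical(nrow(m1$params$Wm[[1]]), 32L)
  expect_identical(ncol(m1$params$Wm[[1]]), 28L)  # sum of codebook block sizes

  expect_error(model_config(backbone = "vgg"), "unknown backbone")
  expect_error(model_config(backbone = "alexnet", input_size = c(64, 64)),
               "227")
  expect_error(model_config(backbone = "resnet101", input_size = c(227, 227)),
               "224")
  expect_error(build_model(model_config(backbone = "alexnet",
                                        input_size = c(227, 227))),
               "pretrained")
})

test_that("forward pass returns simplex vectors and predictions are deterministic", {
  ds <- generate_dataset(2, classes = lesion_classes()[c(1, 5)], seed = 9,
                         height = 16, width = 16)
  model <- build_model(model_config(input_size = c(16, 16), seed = 1))
  pr <- predict(model, ds)
  expect_identical(dim(pr$probabilities), c(4L, 10L))
  expect_true(all(abs(rowSums(pr$probabilities) - 1) < 1e-9))
  expect_true(all(pr$probabilities > 0))
  expect_identical(predict(model, ds), pr)
})

test_that("training descends, is seed-deterministic, and 0 epochs is a no-op", {
  ds <- generate_dataset(3, classes = lesion_classes()[c(2, 8)], seed = 13,
                         height = 16, width = 16)
  cfg <- model_config(input_size = c(16, 16), seed = 2, epochs = 3,
                      batch_size = 4)
  model <- build_model(cfg)

  none <- train_model(model, ds, epochs = 0)
  expect_identical(none$model$params, model$params)
  expect_identical(nrow(none$history), 0L)

  init_loss <- dermafuse:::evaluate_on(model, dermafuse:::prepare_samples(ds, cfg))$loss
  res <- train_model(model, ds, epochs = 1)
  expect_lt(res$history$train_loss[1], init_loss)

  res_a <- train_model(model, ds)
  res_b <- train_model(model, ds)
  expect_identical(res_a$history, res_b$history)
  expect_identical(res_a$model$params, res_b$model$params)

  # predict agrees with the history's final train accuracy
  pr <- predict(res_a$model, ds)
  truth <- vapply(ds, `[[`, character(1), "label")
  expect_equal(mean(pr$labels == truth),
               res_a$history$train_acc[nrow(res_a$history)])
})

test_that("model checkpoints round-trip through JSON", {
  ds <- generate_dataset(2, classes = lesion_classes()[c(3, 6)], seed = 17,
                         height = 16, width = 16)
  model <- build_model(model_config(input_size = c(16, 16), seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$params, model$params, tolerance = 1e-12)
  pr1 <- predict(model, ds)
  pr2 <- predict(back, ds)
  expect_equal(pr1$probabilities, pr2$probabilities, tolerance = 1e-12)
})
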