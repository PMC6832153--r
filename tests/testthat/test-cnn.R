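test_that("shape propagation matches valid-padding arithmetic and flags collapse", {
  # 1x1 kernel, stride 1, no pool: shape unchanged
  sp <- shape_propagation(architecture_spec(
    conv_layers = list(conv_layer(4, c(1, 1), c(1, 1))),
    dense_units = 8, input_shape = c(10, 12, 1)))
  conv_row <- sp$layers[sp$layers$stage == "conv1", ]
  expect_equal(c(conv_row$rows, conv_row$cols), c(10, 12))
  # pool larger than the feature map is an architecture error
  expect_error(shape_propagation(architecture_spec(
    conv_layers = list(conv_layer(2, c(1, 1), c(1, 1), pool = c(4, 4))),
    dense_units = 4, input_shape = c(3, 3, 1))),
    class = "mipipe_error_architecture")
})

test_that("propagated shapes equal the shapes realized by a forward pass", {
  withr::with_seed(7, {
    tried <- 0
    attempts <- 0
    while (tried < 12 && (attempts <- attempts + 1) < 200) {
      spec <- try(architecture_spec(
        conv_layers = list(conv_layer(sample(2:5, 1), c(sample(1:4, 1), sample(1:4, 1)),
                                      c(sample(1:2, 1), sample(1:2, 1)),
                                      pool = c(sample(1:3, 1), sample(1:3, 1))),
                           conv_layer(sample(2:4, 1), c(sample(1:3, 1), sample(1:3, 1)))),
        dense_units = sample(4:10, 1), dropout = 0,
        input_shape = c(sample(10:24, 1), sample(10:24, 1), 1)), silent = TRUE)
      if (inherits(spec, "try-error")) next
      sp <- try(shape_propagation(spec), silent = TRUE)
      if (inherits(sp, "try-error")) next
      tried <- tried + 1
      model <- build_model(spec, seed = tried)
      X <- matrix(rnorm(prod(spec$input_shape) * 3), ncol = 3)
      fwd <- mipipe:::cnn_forward(model$params, X, spec, train = FALSE)
      expect_equal(nrow(fwd$caches$flat), sp$flatten_length)
      expect_equal(dim(fwd$probs), c(spec$n_classes, 3L))
    }
  })
})

test_that("relu matches its piecewise definition", {
  expect_identical(relu(-2), 0)
  expect_identical(relu(3), 3)
  expect_identical(relu(0), 0)
  expect_equal(relu(c(-1.5, 0.5)), c(0, 0.5))
})

test_that("models build reproducibly and emit normalized probabilities", {
  spec <- tiny_spec()
  m1 <- build_model(spec, seed = 5)
  m2 <- build_model(spec, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, build_model(spec, seed = 6)$params))
  probs <- predict(m1, matrix(0, prod(spec$input_shape), 4))
  expect_equal(dim(probs), c(4L, 2L))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  spec <- architecture_spec(
    conv_layers = list(conv_layer(3, c(3, 2), c(1, 1), c(2, 2)),
                       conv_layer(4, c(2, 2), c(1, 1), c(2, 2))),
    dense_units = 5, dropout = 0, n_classes = 2, input_shape = c(14, 13, 1))
  m <- build_model(spec, seed = 3)
  X <- withr::with_seed(1, matrix(rnorm(14 * 13 * 4), 14 * 13, 4))
  y <- c(1L, 2L, 1L, 2L)
  onehot <- matrix(0, 2, 4); onehot[cbind(y, 1:4)] <- 1
  fwd <- mipipe:::cnn_forward(m$params, X, spec, train = FALSE)
  gr <- mipipe:::cnn_backward(m$params, spec, fwd, onehot)
  loss <- function(params) {
    p <- mipipe:::cnn_forward(params, X, spec, train = FALSE)$probs
    -mean(log(p[cbind(y, 1:4)]))
  }
  eps <- 1e-6
  base <- loss(m$params)
  probe <- function(get, set, g, k) {
    p2 <- set(m$params, k, get(m$params)[k] + eps)
    expect_equal((loss(p2) - base) / eps, g[k], tolerance = 1e-3)
  }
  withr::with_seed(2, {
    for (k in sample(length(m$params$conv[[1]]$W), 4)) {
      probe(function(p) p$conv[[1]]$W,
            function(p, k, v) { p$conv[[1]]$W[k] <- v; p }, gr$conv[[1]]$W, k)
    }
    for (k in sample(length(m$params$conv[[2]]$W), 4)) {
      probe(function(p) p$conv[[2]]$W,
            function(p, k, v) { p$conv[[2]]$W[k] <- v; p }, gr$conv[[2]]$W, k)
    }
    for (k in sample(length(m$params$dense$W), 4)) {
      probe(function(p) p$dense$W,
            function(p, k, v) { p$dense$W[k] <- v; p }, gr$dense$W, k)
    }
    probe(function(p) p$out$b, function(p, k, v) { p$out$b[k] <- v; p }, gr$out$b, 1)
  })
})

test_that("training reaches 100% on separable images and is seed-deterministic", {
  iset <- separable_images()
  m <- build_model(tiny_spec(), seed = 1)
  cfg <- train_config(epochs = 10, batch_size = 8, learning_rate = 5e-3, seed = 1)
  m <- train(m, iset, cfg)
  expect_equal(nrow(m$history), 10)
  expect_equal(m$history$accuracy[10], 1)
  # loss decreases over epochs, allowing at most 3 non-improving steps
  expect_lte(sum(diff(m$history$loss) > 0), 3)
  m2 <- train(build_model(tiny_spec(), seed = 1), iset, cfg)
  expect_identical(m$params, m2$params)
  expect_identical(m$history, m2$history)
})

test_that("degenerate training inputs are handled", {
  iset <- separable_images()
  m <- build_model(tiny_spec(), seed = 1)
  m0 <- train(m, iset, train_config(epochs = 0, seed = 1))
  expect_identical(m0$params, m$params)
  expect_equal(nrow(m0$history), 0)
  one_class <- image_set(array(rnorm(12 * 14 * 4), c(12, 14, 4)), rep(1L, 4))
  expect_error(train(m, one_class, train_config(epochs = 1)),
               class = "mipipe_error_label")
})

test_that("dropout training still learns and stays deterministic", {
  iset <- separable_images(n = 20)
  cfg <- train_config(epochs = 8, batch_size = 10, learning_rate = 5e-3, seed = 4)
  m <- train(build_model(tiny_spec(dropout = 0.4), seed = 2), iset, cfg)
  m2 <- train(build_model(tiny_spec(dropout = 0.4), seed = 2), iset, cfg)
  expect_identical(m$params, m2$params)
  expect_gt(m$history$accuracy[8], 0.7)
})
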