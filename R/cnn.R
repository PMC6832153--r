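# A small convolutional network for stacked scalogram images, written with
# plain BLAS matrix operations: valid-padding convolution via im2col,
# max-pooling with floor division, a dense ReLU layer with inverted
# dropout, and a softmax output trained by backpropagation (Adam or SGD).
#
# Feature maps are stored column-major as (rows, cols, channels) vectors,
# one column per sample, so every layer is a matrix on (h*w*c, batch).

#' Rectified linear unit
#'
#' `f(c) = 0` for `c < 0` and `c` otherwise, elementwise.
#' @param c Numeric vector/matrix.
#' @return Same shape as `c`.
#' @examples relu(c(-2, 0, 3))
#' @export
relu <- function(c) pmax(c, 0)

#' Convolutional layer description
#'
#' @param filters Number of output filters.
#' @param kernel Kernel size `c(rows, cols)`.
#' @param stride Stride `c(rows, cols)`.
#' @param pool Max-pooling size `c(rows, cols)`, or `NULL` for none.
#' @return A `conv_layer` list.
#' @export
conv_layer <- function(filters, kernel, stride = c(1, 1), pool = NULL) {
  mp_assert(is_count(filters), "filters must be a positive count", "architecture")
  mp_assert(length(kernel) == 2 && all(vapply(kernel, is_count, logical(1))),
            "kernel must be two positive counts", "architecture")
  mp_assert(length(stride) == 2 && all(vapply(stride, is_count, logical(1))),
            "stride must be two positive counts", "architecture")
  if (!is.null(pool)) {
    mp_assert(length(pool) == 2 && all(vapply(pool, is_count, logical(1))),
              "pool must be two positive counts", "architecture")
  }
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 stride = as.integer(stride),
                 pool = if (is.null(pool)) NULL else as.integer(pool)),
            class = "conv_layer")
}

#' CNN architecture specification
#'
#' The default reproduces the reference two-stage architecture for
#' 128x256x1 scalogram images: conv 250 filters, kernel (3,1), effective
#' stride (2,1), pool (4,4); conv 150 filters, kernel (1,2), stride (1,1),
#' pool (3,3); dense 2048 with ReLU and dropout 0.4; softmax over 2
#' classes. All convolutions and pools use valid padding and floor
#' division, which is what makes the printed shape chain
#' (63,256,250) -> (15,64,250) -> (15,63,150) -> (5,21,150) -> 15750 hold.
#'
#' @param conv_layers List of [conv_layer()] objects.
#' @param dense_units Width of the fully connected ReLU layer.
#' @param dropout Dropout fraction applied after the dense layer.
#' @param n_classes Number of output classes.
#' @param input_shape Input image shape `c(rows, cols, channels)`.
#' @return An `architecture_spec` object.
#' @examples
#' shape_propagation(architecture_spec())
#' @export
architecture_spec <- function(conv_layers = list(conv_layer(250, c(3, 1), c(2, 1), c(4, 4)),
                                                 conv_layer(150, c(1, 2), c(1, 1), c(3, 3))),
                              dense_units = 2048, dropout = 0.4, n_classes = 2,
                              input_shape = c(128, 256, 1)) {
  mp_assert(length(conv_layers) >= 1 &&
              all(vapply(conv_layers, inherits, logical(1), "conv_layer")),
            "conv_layers must be a list of conv_layer objects", "architecture")
  mp_assert(is_count(dense_units) && is_count(n_classes) && n_classes >= 2,
            "dense_units and n_classes must be positive counts (n_classes >= 2)",
            "architecture")
  mp_assert(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)", "architecture")
  mp_assert(length(input_shape) == 3 && all(vapply(input_shape, is_count, logical(1))),
            "input_shape must be c(rows, cols, channels)", "architecture")
  structure(list(conv_layers = conv_layers, dense_units = as.integer(dense_units),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape)),
            class = "architecture_spec")
}

#' Reduced architecture for quick synthetic experiments
#'
#' Same layer structure, kernels, strides and pools as [architecture_spec()]
#' but with 8 + 8 filters and a 32-unit dense layer, so end-to-end runs on
#' synthetic data finish in seconds rather than hours.
#' @param input_shape Input image shape.
#' @return An `architecture_spec`.
#' @export
reduced_architecture_spec <- function(input_shape = c(128, 256, 1)) {
  architecture_spec(conv_layers = list(conv_layer(8, c(3, 1), c(2, 1), c(4, 4)),
                                       conv_layer(8, c(1, 2), c(1, 1), c(3, 3))),
                    dense_units = 32, dropout = 0.4, n_classes = 2,
                    input_shape = input_shape)
}

#' Propagate shapes through an architecture
#'
#' Valid-padding convolution arithmetic `floor((n - k) / s) + 1` per axis
#' and floor-division pooling. Errors (`architecture`) if any intermediate
#' dimension drops below 1.
#'
#' @param spec An [architecture_spec()].
#' @param input_shape Input shape `c(rows, cols, channels)`; defaults to
#'   the spec's.
#' @return A `shape_propagation` object: `layers` (a tibble with one row
#'   per stage) and `flatten_length`.
#' @export
shape_propagation <- function(spec, input_shape = spec$input_shape) {
  mp_assert(inherits(spec, "architecture_spec"), "spec must be an architecture_spec",
            "parameter")
  shp <- as.integer(input_shape)
  stages <- list(list(stage = "input", operation = "input", shape = shp))
  for (i in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[i]]
    out <- as.integer(c(floor((shp[1] - cl$kernel[1]) / cl$stride[1]) + 1,
                        floor((shp[2] - cl$kernel[2]) / cl$stride[2]) + 1,
                        cl$filters))
    if (any(out[1:2] < 1)) {
      mp_abort(sprintf("conv layer %d collapses the feature map (shape %s)", i,
                       paste(out, collapse = "x")), "architecture")
    }
    shp <- out
    stages <- c(stages, list(list(stage = sprintf("conv%d", i),
                              operation = sprintf("conv %dx%d stride %dx%d -> %d + relu",
                                                  cl$kernel[1], cl$kernel[2],
                                                  cl$stride[1], cl$stride[2], cl$filters),
                              shape = shp)))
    if (!is.null(cl$pool)) {
      out <- c(shp[1] %/% cl$pool[1], shp[2] %/% cl$pool[2], shp[3])
      if (any(out[1:2] < 1)) {
        mp_abort(sprintf("pool %dx%d exceeds the %dx%d feature map at layer %d",
                         cl$pool[1], cl$pool[2], shp[1], shp[2], i), "architecture")
      }
      shp <- out
      stages <- c(stages, list(list(stage = sprintf("pool%d", i),
                                operation = sprintf("maxpool %dx%d", cl$pool[1], cl$pool[2]),
                                shape = shp)))
    }
  }
  flat <- as.integer(prod(shp))
  stages <- c(stages,
            list(list(stage = "flatten", operation = "flatten", shape = c(flat, 1L, 1L))),
            list(list(stage = "dense", operation = sprintf("dense %d + relu + dropout %.2f",
                                                           spec$dense_units, spec$dropout),
                      shape = c(spec$dense_units, 1L, 1L))),
            list(list(stage = "output", operation = sprintf("dense %d + softmax",
                                                            spec$n_classes),
                      shape = c(spec$n_classes, 1L, 1L))))
  layers <- tibble::tibble(
    stage = vapply(stages, `[[`, character(1), "stage"),
    operation = vapply(stages, `[[`, character(1), "operation"),
    rows = vapply(stages, function(r) r$shape[1], integer(1)),
    cols = vapply(stages, function(r) r$shape[2], integer(1)),
    channels = vapply(stages, function(r) r$shape[3], integer(1)))
  structure(list(layers = layers, flatten_length = as.integer(flat),
                 shapes = lapply(stages, `[[`, "shape")),
            class = "shape_propagation")
}

#' @export
print.shape_propagation <- function(x, ...) {
  print(x$layers)
  cat("flattened length:", x$flatten_length, "\n")
  invisible(x)
}

# --- internal layer machinery --------------------------------------------

# Convolution and pooling are delegated to compiled kernels (src/), which
# share the channel-fastest layout: each sample is one column enumerating
# (channel, row, col) with channel varying fastest.

# relu = TRUE fuses the rectifier into the kernel; the backward pass then
# gates gradients by the stored post-relu activations.
conv_forward <- function(Xmat, in_shape, W, b, stride, relu = FALSE) {
  kern <- dim(W)[2:3]; f <- dim(W)[4]
  oh <- (in_shape[1] - kern[1]) %/% stride[1] + 1L
  ow <- (in_shape[2] - kern[2]) %/% stride[2] + 1L
  out <- .conv_fwd_cpp(Xmat, as.integer(in_shape), matrix(W, ncol = f), b,
                       as.integer(kern), as.integer(stride), relu)
  list(out = out, cache = list(X = Xmat, in_shape = in_shape, W = W,
                               kernel = kern, stride = stride, relu = relu,
                               out_shape = c(oh, ow, f), A = out))
}

conv_backward <- function(dOut, cache) {
  f <- cache$out_shape[3]
  g <- .conv_bwd_cpp(cache$X, as.integer(cache$in_shape),
                     matrix(cache$W, ncol = f), as.integer(cache$kernel),
                     as.integer(cache$stride), dOut, cache$A, cache$relu)
  list(dX = g$dX, dW = array(g$dW, dim(cache$W)), db = g$db)
}

pool_forward <- function(Xmat, in_shape, pool) {
  fh <- in_shape[1] %/% pool[1]; fw <- in_shape[2] %/% pool[2]
  r <- .pool_fwd_cpp(Xmat, as.integer(in_shape), as.integer(pool))
  list(out = r$out, cache = list(amax = r$amax, in_len = nrow(Xmat),
                                 out_shape = c(fh, fw, in_shape[3])))
}

pool_backward <- function(dOut, cache) {
  .pool_bwd_cpp(dOut, cache$amax, cache$in_len)
}

softmax_cols <- function(L) {
  L <- L - rep(apply(L, 2, max), each = nrow(L))
  E <- exp(L)
  E / rep(colSums(E), each = nrow(L))
}

init_params <- function(spec, seed) {
  with_seed(seed, {
    params <- list(conv = list())
    shp <- spec$input_shape
    for (i in seq_along(spec$conv_layers)) {
      cl <- spec$conv_layers[[i]]
      fan_in <- prod(cl$kernel) * shp[3]
      W <- array(rnorm(fan_in * cl$filters, sd = sqrt(2 / fan_in)),
                 c(shp[3], cl$kernel[1], cl$kernel[2], cl$filters))
      params$conv[[i]] <- list(W = W, b = numeric(cl$filters))
      shp <- c(floor((shp[1] - cl$kernel[1]) / cl$stride[1]) + 1L,
               floor((shp[2] - cl$kernel[2]) / cl$stride[2]) + 1L, cl$filters)
      if (!is.null(cl$pool)) shp <- c(shp[1] %/% cl$pool[1], shp[2] %/% cl$pool[2], shp[3])
    }
    flat <- prod(shp)
    params$dense <- list(W = matrix(rnorm(flat * spec$dense_units, sd = sqrt(2 / flat)),
                                    flat, spec$dense_units),
                         b = numeric(spec$dense_units))
    params$out <- list(W = matrix(rnorm(spec$dense_units * spec$n_classes,
                                        sd = sqrt(2 / spec$dense_units)),
                                  spec$dense_units, spec$n_classes),
                       b = numeric(spec$n_classes))
    params
  })
}

# Forward pass on Xmat (h*w*c, n). In training mode dropout draws from the
# current RNG stream.
cnn_forward <- function(params, Xmat, spec, train = FALSE) {
  caches <- list(conv = vector("list", length(spec$conv_layers)))
  shp <- spec$input_shape
  A <- Xmat
  for (i in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[i]]
    cf <- conv_forward(A, shp, params$conv[[i]]$W, params$conv[[i]]$b, cl$stride,
                       relu = TRUE)
    A <- cf$out
    shp <- cf$cache$out_shape
    pc <- NULL
    if (!is.null(cl$pool)) {
      pf <- pool_forward(A, shp, cl$pool)
      pc <- pf$cache
      A <- pf$out
      shp <- pc$out_shape
    }
    caches$conv[[i]] <- list(conv = cf$cache, pool = pc)
  }
  caches$flat <- A
  Zd <- crossprod(params$dense$W, A) + params$dense$b
  Ad <- relu(Zd)
  mask <- NULL
  if (train && spec$dropout > 0) {
    mask <- matrix((runif(length(Ad)) >= spec$dropout) / (1 - spec$dropout),
                   nrow(Ad), ncol(Ad))
    Ad <- Ad * mask
  }
  logits <- crossprod(params$out$W, Ad) + params$out$b
  probs <- softmax_cols(logits)
  caches$dense <- list(relu_mask = Zd > 0, A = Ad, mask = mask)
  list(probs = probs, caches = caches)
}

cnn_backward <- function(params, spec, fwd, y_onehot) {
  n <- ncol(y_onehot)
  grads <- list(conv = vector("list", length(spec$conv_layers)))
  dL <- (fwd$probs - y_onehot) / n                          # (classes, n)
  grads$out <- list(W = fwd$caches$dense$A %*% t(dL), b = rowSums(dL))
  dA <- params$out$W %*% dL
  if (!is.null(fwd$caches$dense$mask)) dA <- dA * fwd$caches$dense$mask
  dZ <- dA * fwd$caches$dense$relu_mask
  grads$dense <- list(W = fwd$caches$flat %*% t(dZ), b = rowSums(dZ))
  dA <- params$dense$W %*% dZ
  for (i in rev(seq_along(spec$conv_layers))) {
    cc <- fwd$caches$conv[[i]]
    if (!is.null(cc$pool)) dA <- pool_backward(dA, cc$pool)
    cb <- conv_backward(dA, cc$conv)   # relu gating happens in the kernel
    grads$conv[[i]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  grads
}

# Flatten/unflatten parameter lists for the optimizer.
param_walk <- function(params, grads, f) {
  for (i in seq_along(params$conv)) {
    params$conv[[i]]$W <- f(paste0("cW", i), params$conv[[i]]$W, grads$conv[[i]]$W)
    params$conv[[i]]$b <- f(paste0("cb", i), params$conv[[i]]$b, grads$conv[[i]]$b)
  }
  params$dense$W <- f("dW", params$dense$W, grads$dense$W)
  params$dense$b <- f("db", params$dense$b, grads$dense$b)
  params$out$W <- f("oW", params$out$W, grads$out$W)
  params$out$b <- f("ob", params$out$b, grads$out$b)
  params
}

#' Build a trainable CNN
#'
#' Initializes parameters (He-scaled normal weights, zero biases) from a
#' seed; two builds with the same spec and seed are identical.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed.
#' @return A `cnn_model` (untrained).
#' @export
build_model <- function(spec, seed = 1) {
  sp <- shape_propagation(spec)   # validates; propagates architecture errors
  structure(list(spec = spec, params = init_params(spec, seed), seed = as.integer(seed),
                 shapes = sp, checkpoints = list(),
                 history = empty_history(), trained_epochs = 0L),
            class = "cnn_model")
}

empty_history <- function() {
  tibble::tibble(epoch = integer(0), loss = numeric(0), accuracy = numeric(0),
                 val_loss = numeric(0), val_accuracy = numeric(0))
}

#' @export
print.cnn_model <- function(x, ...) {
  np <- sum(vapply(unlist(x$params, recursive = FALSE),
                   function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("<cnn_model> input %s, %d conv stages, %d parameters, trained %d epochs\n",
              paste(x$spec$input_shape, collapse = "x"), length(x$spec$conv_layers),
              np, x$trained_epochs))
  invisible(x)
}

#' Labelled image set
#'
#' @param x Array of images, dim `c(rows, cols, n)`, or a list of
#'   `trial_image` objects (labels then taken from them).
#' @param labels Integer class labels in `1..n_classes`.
#' @return An `image_set` with `x` (matrix, pixels by samples) and `y`.
#' @export
image_set <- function(x, labels = NULL) {
  if (is.list(x) && !is.array(x)) {
    mp_assert(all(vapply(x, inherits, logical(1), "trial_image")),
              "list input must contain trial_image objects", "parameter")
    labels <- vapply(x, function(im) as.integer(im$label), integer(1))
    shp <- dim(x[[1]]$pixels)
    xm <- vapply(x, function(im) as.vector(im$pixels), numeric(prod(shp)))
    meta <- tibble::tibble(trial_id = vapply(x, function(im) as.character(im$trial_id),
                                             character(1)),
                           window_index = vapply(x, function(im)
                             as.integer(im$window_index), integer(1)))
  } else {
    mp_assert(is.array(x) && length(dim(x)) == 3, "x must be a (rows, cols, n) array",
              "parameter")
    shp <- dim(x)[1:2]
    xm <- matrix(x, prod(shp), dim(x)[3])
    meta <- NULL
  }
  mp_assert(length(labels) == ncol(xm), "one label per image required", "parameter")
  structure(list(x = xm, y = as.integer(labels), shape = c(shp, 1L), meta = meta),
            class = "image_set")
}

#' Training configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Step size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed Seed controlling dropout and (optional) shuffling.
#' @param train_fraction Fraction of trials used for training when a
#'   pipeline splits a dataset (default 0.5, i.e. a 50/50 split).
#' @param shuffle Reshuffle the batch order each epoch.
#' @param keep_checkpoints Store a parameter snapshot after every epoch
#'   (needed for max-over-epochs k-fold evaluation).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 20, batch_size = 32, learning_rate = 1e-4,
                         optimizer = c("adam", "sgd"), seed = 1, train_fraction = 0.5,
                         shuffle = FALSE, keep_checkpoints = TRUE) {
  optimizer <- match.arg(optimizer)
  mp_assert(is.numeric(epochs) && epochs >= 0 && epochs == floor(epochs),
            "epochs must be a nonnegative integer", "parameter")
  mp_assert(is_count(batch_size), "batch_size must be a positive count", "parameter")
  mp_assert(train_fraction > 0 && train_fraction < 1,
            "train_fraction must be in (0, 1)", "parameter")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), train_fraction = train_fraction,
                 shuffle = isTRUE(shuffle), keep_checkpoints = isTRUE(keep_checkpoints)),
            class = "train_config")
}

cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(y, seq_along(y))], 1e-12)))
}

#' Train a CNN
#'
#' Minibatch backpropagation with softmax cross-entropy loss. Training is
#' deterministic given the config seed and a fixed data order. With
#' `epochs = 0` the model is returned unchanged with an empty history.
#'
#' @param model A [build_model()] result.
#' @param train_set An [image_set()] containing at least two classes.
#' @param config A [train_config()].
#' @param validation_set Optional [image_set()] evaluated after each epoch.
#' @return The updated `cnn_model`, with `history` (one row per epoch) and,
#'   if requested, per-epoch parameter `checkpoints`.
#' @export
train <- function(model, train_set, config = train_config(), validation_set = NULL) {
  mp_assert(inherits(model, "cnn_model"), "model must be a cnn_model", "parameter")
  mp_assert(inherits(train_set, "image_set"), "train_set must be an image_set", "parameter")
  mp_assert(inherits(config, "train_config"), "config must be a train_config", "parameter")
  if (length(unique(train_set$y)) < 2) {
    mp_abort("training set contains a single class", "label")
  }
  if (config$epochs == 0L) {
    model$history <- empty_history()
    return(model)
  }
  spec <- model$spec
  params <- model$params
  n <- ncol(train_set$x)
  K <- spec$n_classes
  onehot <- function(y, idx) {
    Y <- matrix(0, K, length(idx)); Y[cbind(y[idx], seq_along(idx))] <- 1; Y
  }
  state <- new.env(parent = emptyenv())
  state$t <- 0
  adam <- function(name, p, g) {
    key_m <- paste0(name, "_m"); key_v <- paste0(name, "_v")
    if (is.null(state[[key_m]])) { state[[key_m]] <- p * 0; state[[key_v]] <- p * 0 }
    state[[key_m]] <- 0.9 * state[[key_m]] + 0.1 * g
    state[[key_v]] <- 0.999 * state[[key_v]] + 0.001 * g^2
    mhat <- state[[key_m]] / (1 - 0.9^state$t)
    vhat <- state[[key_v]] / (1 - 0.999^state$t)
    p - config$learning_rate * mhat / (sqrt(vhat) + 1e-8)
  }
  sgd <- function(name, p, g) p - config$learning_rate * g
  update <- if (config$optimizer == "adam") adam else sgd
  hist <- vector("list", config$epochs)
  checkpoints <- list()
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- if (config$shuffle) sample.int(n) else seq_len(n)
      batch_starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0; ep_correct <- 0
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
        fwd <- cnn_forward(params, train_set$x[, idx, drop = FALSE], spec, train = TRUE)
        state$t <- state$t + 1
        grads <- cnn_backward(params, spec, fwd, onehot(train_set$y, idx))
        params <- param_walk(params, grads, update)
        ep_loss <- ep_loss + cross_entropy(fwd$probs, train_set$y[idx]) * length(idx)
        ep_correct <- ep_correct + sum(max.col(t(fwd$probs), "first") == train_set$y[idx])
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(validation_set)) {
        vp <- cnn_forward(params, validation_set$x, spec, train = FALSE)$probs
        val_loss <- cross_entropy(vp, validation_set$y)
        val_acc <- mean(max.col(t(vp), "first") == validation_set$y)
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / n,
                                   accuracy = ep_correct / n,
                                   val_loss = val_loss, val_accuracy = val_acc)
      if (config$keep_checkpoints) checkpoints[[ep]] <- params
    }
  })
  model$params <- params
  model$checkpoints <- checkpoints
  model$history <- do.call(rbind, hist)
  model$trained_epochs <- model$trained_epochs + config$epochs
  model$train_config <- config
  model
}

#' Predict class probabilities or labels
#'
#' @param object A trained `cnn_model`.
#' @param newdata An [image_set()] or pixel matrix (pixels by samples).
#' @param type `"prob"` for a samples-by-classes probability matrix,
#'   `"class"` for hard labels.
#' @param params Optional parameter snapshot (e.g. a checkpoint) to use
#'   instead of the final parameters.
#' @param ... Unused.
#' @return Probability matrix or integer labels.
#' @export
predict.cnn_model <- function(object, newdata, type = c("prob", "class"),
                              params = NULL, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "image_set")) newdata$x else newdata
  probs <- cnn_forward(params %||% object$params, X, object$spec, train = FALSE)$probs
  if (type == "prob") t(probs) else max.col(t(probs), "first")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
tidy.cnn_model <- function(x, ...) x$history

#' @export
glance.cnn_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = x$trained_epochs,
                 final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
                 final_accuracy = if (nrow(h)) h$accuracy[nrow(h)] else NA_real_,
                 final_val_accuracy = if (nrow(h)) h$val_accuracy[nrow(h)] else NA_real_)
}
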