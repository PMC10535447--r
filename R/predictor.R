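#' Classifier architecture configuration
#'
#' Fully connected network with rectifier activations between consecutive
#' layers and dropout after the first and second hidden layers. The
#' default widths (400, 256, 64, 32, 8, 2) take the 400-coordinate
#' descriptor vector down to two class logits.
#'
#' @param layer_widths integer vector of layer widths, input first.
#' @param dropout_rate dropout probability p (default 0.3).
#' @param dropout_layers hidden layers after which dropout applies
#'   (default the first and second).
#' @param standardize if `TRUE`, a per-coordinate z-scoring transform is
#'   fitted on the training data inside [train_model()] and applied to
#'   every subsequent input. Off by default: inputs are used as encoded.
#' @param seed integer seed for weight initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(layer_widths = c(400L, 256L, 64L, 32L, 8L, 2L),
                         dropout_rate = 0.3,
                         dropout_layers = c(1L, 2L),
                         standardize = FALSE,
                         seed = 1L) {
  layer_widths <- as.integer(layer_widths)
  if (length(layer_widths) < 2L) stop("need at least input and output widths")
  if (layer_widths[length(layer_widths)] != 2L) stop("output width must be 2")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(layer_widths = layer_widths, dropout_rate = dropout_rate,
                 dropout_layers = as.integer(dropout_layers),
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "model_config")
}

#' Training configuration
#'
#' Mini-batch stochastic gradient descent with classical momentum on
#' cross-entropy. The learning rate follows a step-decay schedule: it is
#' multiplied by `lr_decay` every `lr_step` epochs, starting from
#' `initial_lr`.
#'
#' @param epochs number of epochs E (>= 1).
#' @param batch_size mini-batch size (>= 1).
#' @param initial_lr initial learning rate (default 0.001).
#' @param momentum classical momentum coefficient in \[0, 1) (default
#'   0.9; set to 0 for vanilla SGD).
#' @param lr_decay multiplicative decay factor (default 0.5).
#' @param lr_step epochs between decays (default 20).
#' @param seed integer seed for shuffling and training-time dropout.
#' @param verbose if `TRUE`, print one log line per epoch.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L, initial_lr = 0.001,
                         momentum = 0.9, lr_decay = 0.5, lr_step = 20L,
                         seed = 1L, verbose = FALSE) {
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (initial_lr <= 0) stop("initial_lr must be > 0")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, momentum = momentum,
                 lr_decay = lr_decay,
                 lr_step = as.integer(lr_step), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Initialize model parameters
#'
#' Fan-in-scaled uniform initialization suited to rectifier networks:
#' weights of a layer with `n_in` inputs are drawn from
#' U(-sqrt(6/n_in), sqrt(6/n_in)) (He-uniform), biases from
#' U(-1/sqrt(n_in), 1/sqrt(n_in)). Deterministic given `config$seed`.
#'
#' @param config a [model_config()].
#' @return An `acp_model` (untrained).
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  widths <- config$layer_widths
  n_layers <- length(widths) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    bound <- sqrt(6 / widths[k])
    W[[k]] <- matrix(runif(widths[k] * widths[k + 1L], -bound, bound),
                     widths[k], widths[k + 1L])
    b[[k]] <- runif(widths[k + 1L], -1 / sqrt(widths[k]), 1 / sqrt(widths[k]))
  }
  structure(list(W = W, b = b, config = config, trained = FALSE,
                 center = NULL, scale = NULL, history = NULL),
            class = "acp_model")
}

#' Number of trainable parameters
#' @param model an `acp_model`.
#' @return Integer count of weights plus biases.
#' @export
n_params <- function(model) {
  sum(vapply(model$W, length, integer(1))) +
    sum(vapply(model$b, length, integer(1)))
}

#' @export
print.acp_model <- function(x, ...) {
  cat(sprintf("acp_model: widths %s, %d parameters, %s\n",
              paste(x$config$layer_widths, collapse = "-"), n_params(x),
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

.apply_standardizer <- function(model, x) {
  if (is.null(model$center)) return(x)
  sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
}

# Forward pass. Returns the softmax probabilities plus per-layer caches
# (inputs and dropout masks) for backpropagation. Dropout masks are drawn
# from the current RNG stream (inverted dropout, scale 1/(1-p)).
.mlp_forward <- function(model, x, dropout) {
  cfg <- model$config
  n_layers <- length(model$W)
  a <- x
  inputs <- vector("list", n_layers)
  masks <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    inputs[[k]] <- a
    z <- a %*% model$W[[k]] + rep(model$b[[k]], each = nrow(a))
    if (k < n_layers) {
      a <- z * (z > 0)
      if (dropout && cfg$dropout_rate > 0 && k %in% cfg$dropout_layers) {
        keep <- matrix(rbinom(length(a), 1L, 1 - cfg$dropout_rate),
                       nrow(a), ncol(a)) / (1 - cfg$dropout_rate)
        a <- a * keep
        masks[[k]] <- keep
      }
    } else {
      zmax <- apply(z, 1L, max)
      ez <- exp(z - zmax)
      a <- ez / rowSums(ez)
    }
  }
  list(probs = a, inputs = inputs, masks = masks)
}

#' Train the classifier
#'
#' Runs `tcfg$epochs` epochs of mini-batch SGD on cross-entropy with
#' dropout active, shuffling the data each epoch. Deterministic given
#' the data and the seeds in `model$config` and `tcfg`.
#'
#' @param model an `acp_model` from [init_model()].
#' @param x numeric sample x feature matrix.
#' @param y binary (0/1) label vector.
#' @param tcfg a [train_config()].
#' @return The trained `acp_model`, with an epoch-level `history` data
#'   frame (epoch, loss, lr).
#' @export
train_model <- function(model, x, y, tcfg) {
  stopifnot(inherits(model, "acp_model"), inherits(tcfg, "train_config"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!nrow(x)) stop("training data is empty")
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  if (ncol(x) != model$config$layer_widths[1L]) {
    stop("input width ", ncol(x), " does not match model input ",
         model$config$layer_widths[1L])
  }
  if (model$config$standardize) {
    model$center <- colMeans(x)
    sds <- apply(x, 2L, sd)
    model$scale <- ifelse(sds > 0, sds, 1)
  }
  xs <- .apply_standardizer(model, x)
  set.seed(tcfg$seed)
  res <- cpp_train_mlp(model$W, model$b, xs, y,
                       tcfg$epochs, tcfg$batch_size,
                       tcfg$initial_lr, tcfg$lr_decay, tcfg$lr_step,
                       tcfg$momentum %||% 0,
                       model$config$dropout_rate,
                       model$config$dropout_layers)
  model$W <- res$W
  model$b <- lapply(res$b, as.numeric)
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(tcfg$epochs),
                              loss = res$loss, lr = res$lr)
  if (tcfg$verbose) {
    for (i in seq_len(nrow(model$history))) {
      message(sprintf("epoch %3d  loss %.5f  lr %.6f", i,
                      model$history$loss[i], model$history$lr[i]))
    }
  }
  model
}

#' Predict class probabilities
#'
#' With `dropout_active = FALSE` (the default) the map is deterministic.
#' With `dropout_active = TRUE` a fresh dropout mask is drawn from the
#' current RNG stream on every call, which is the stochastic forward pass
#' used for Monte-Carlo dropout.
#'
#' @param model a trained `acp_model`.
#' @param x numeric sample x feature matrix (or single vector).
#' @param dropout_active keep dropout on during the forward pass?
#' @return Numeric n x 2 matrix of class probabilities (columns: class 0,
#'   class 1); rows sum to 1.
#' @export
predict_proba <- function(model, x, dropout_active = FALSE) {
  stopifnot(inherits(model, "acp_model"))
  if (!isTRUE(model$trained)) stop("model is not trained")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$config$layer_widths[1L]) {
    stop("input width ", ncol(x), " does not match model input ",
         model$config$layer_widths[1L])
  }
  xs <- .apply_standardizer(model, x)
  p <- .mlp_forward(model, xs, dropout = dropout_active)$probs
  colnames(p) <- c("class0", "class1")
  p
}

#' Predict hard class labels (dropout off)
#' @param model a trained `acp_model`.
#' @param x numeric sample x feature matrix.
#' @return Integer 0/1 vector (ties go to class 0).
#' @export
predict_label <- function(model, x) {
  p <- predict_proba(model, x, dropout_active = FALSE)
  as.integer(p[, 2L] > p[, 1L])
}

#' Monte-Carlo dropout forward passes
#'
#' Runs `T` stochastic forward passes with dropout on; each pass applies
#' independent dropout masks. Deterministic given `seed`.
#'
#' @param model a trained `acp_model`.
#' @param x numeric sample x feature matrix.
#' @param T number of passes (>= 2, so the standard deviation over passes
#'   is defined).
#' @param seed integer seed.
#' @return Numeric array of dimension `c(T, n_samples, 2)`: element
#'   `[t, j, c]` is the probability of class c-1 for sample j on pass t.
#'   Each `[t, j, ]` row pair sums to 1.
#' @export
mc_dropout_passes <- function(model, x, T = 10L, seed = 1L) {
  T <- as.integer(T)
  if (is.na(T) || T < 2L) stop("T must be >= 2")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (!isTRUE(model$trained)) stop("model is not trained")
  if (ncol(x) != model$config$layer_widths[1L]) {
    stop("input width ", ncol(x), " does not match model input ",
         model$config$layer_widths[1L])
  }
  xs <- .apply_standardizer(model, x)
  set.seed(as.integer(seed))
  cube <- cpp_mc_forward(model$W, model$b, xs, T,
                         model$config$dropout_rate,
                         model$config$dropout_layers)
  aperm(cube, c(3L, 1L, 2L))             # (T, n, 2)
}

#' Save / load a model checkpoint
#' @param model an `acp_model`.
#' @param path file path.
#' @return `load_model` returns the `acp_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "acp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "acp_model"))
  m
}
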