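#' Framework configuration
#'
#' Collects every hyperparameter of the augmented-sample selection loop:
#' the uncertainty threshold lambda, the confidence threshold gamma, the
#' number of stochastic forward passes T, the number of selection
#' iterations I, and the model / training configurations.
#'
#' @param lambda uncertainty threshold (> 0); an augmented sample is kept
#'   only if the standard deviation of its pseudo-label-class probability
#'   over the T passes is strictly below `lambda`. Default 0.03.
#' @param gamma confidence threshold in (0.5, 1); the mean
#'   pseudo-label-class probability must strictly exceed `gamma`.
#'   Default 0.8.
#' @param T number of stochastic forward passes (>= 2). Default 10.
#' @param iterations number of selection iterations I (>= 1). Default 10.
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param seed master seed; per-iteration initialization and scoring
#'   seeds are derived from it deterministically.
#' @return An `assf_config` object.
#' @export
assf_config <- function(lambda = 0.03, gamma = 0.8, T = 10L,
                        iterations = 10L,
                        model = model_config(),
                        train = train_config(),
                        seed = 1L) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (gamma <= 0.5 || gamma >= 1) stop("gamma must be in (0.5, 1)")
  T <- as.integer(T)
  if (is.na(T) || T < 2L) stop("T must be >= 2")
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) stop("iterations must be >= 1")
  stopifnot(inherits(model, "model_config"), inherits(train, "train_config"))
  structure(list(lambda = lambda, gamma = gamma, T = T,
                 iterations = iterations, model = model, train = train,
                 seed = as.integer(seed)),
            class = "assf_config")
}

#' Score augmented samples by Monte-Carlo dropout
#'
#' Runs T stochastic forward passes over the augmented set and fills in,
#' for each sample: the pseudo-label (argmax of the per-class mean
#' probability, ties toward class 0), the confidence (mean probability of
#' the pseudo-label class), and the uncertainty (sample standard
#' deviation, divisor T - 1, of the pseudo-label-class probability over
#' the passes).
#'
#' @param model a trained `acp_model`.
#' @param augset an `acp_augset`.
#' @param T number of passes (>= 2).
#' @param seed integer seed.
#' @return The `acp_augset` with `pseudo_label`, `confidence`,
#'   `uncertainty` filled and `scored = TRUE`.
#' @export
score_augmented <- function(model, augset, T = 10L, seed = 1L) {
  stopifnot(inherits(augset, "acp_augset"))
  passes <- mc_dropout_passes(model, augset$x, T = T, seed = seed)
  p1 <- passes[, , 2L, drop = FALSE]
  dim(p1) <- dim(passes)[1:2]            # T x n
  mean1 <- colMeans(p1)
  mean0 <- 1 - mean1
  # strict >: a 0.5/0.5 tie goes to class 0
  pseudo <- as.integer(mean1 > mean0)
  m <- nrow(augset$x)
  conf <- ifelse(pseudo == 1L, mean1, mean0)
  unc <- vapply(seq_len(m), function(j) {
    sd(passes[, j, pseudo[j] + 1L])
  }, numeric(1))
  augset$pseudo_label <- pseudo
  augset$confidence <- as.numeric(conf)
  augset$uncertainty <- unc
  augset$scored <- TRUE
  augset
}

#' Select high-quality augmented samples
#'
#' A scored augmented sample enters the selected set Ds iff all three
#' predicates hold: uncertainty strictly below `lambda`, confidence
#' strictly above `gamma`, and pseudo-label equal to the inherited label.
#'
#' @param augset a scored `acp_augset`.
#' @param lambda uncertainty threshold.
#' @param gamma confidence threshold.
#' @return Integer indices (in input order) of the selected samples.
#' @export
select_samples <- function(augset, lambda, gamma) {
  stopifnot(inherits(augset, "acp_augset"))
  if (!isTRUE(augset$scored)) stop("augmented set has not been scored")
  keep <- augset$uncertainty < lambda &
    augset$confidence > gamma &
    augset$pseudo_label == augset$label
  which(keep)
}

#' Subset an augmented set by index
#' @param augset an `acp_augset`.
#' @param idx integer indices.
#' @return The restricted `acp_augset`.
#' @export
augset_subset <- function(augset, idx) {
  stopifnot(inherits(augset, "acp_augset"))
  structure(list(x = augset$x[idx, , drop = FALSE],
                 label = augset$label[idx],
                 source_id = augset$source_id[idx],
                 pseudo_label = augset$pseudo_label[idx],
                 confidence = augset$confidence[idx],
                 uncertainty = augset$uncertainty[idx],
                 scored = augset$scored,
                 layout = augset$layout),
            class = "acp_augset")
}

#' Iterative uncertainty-aware selection training
#'
#' The core training loop. For each of I iterations: re-initialize the
#' model parameters (fresh seed derived from the master seed and the
#' iteration number), train E epochs on the original set Do (iteration 1)
#' or on Do merged with the previously selected augmented samples Ds,
#' then run T dropout passes over the full augmented set Da and recompute
#' the selection from scratch. Da itself is fixed across iterations.
#'
#' @param features an `acp_features` object (Do: the encoded original
#'   training set).
#' @param augset an `acp_augset` (Da).
#' @param cfg an [assf_config()].
#' @return A list with `model` (the final trained model), `selected`
#'   (integer indices into Da of the final Ds), `augset` (Da with final
#'   scores), and `report` (data frame with one row per iteration:
#'   iteration, n_selected, n_pos, n_neg, selection_rate).
#' @export
assf_train <- function(features, augset, cfg) {
  stopifnot(inherits(features, "acp_features"),
            inherits(augset, "acp_augset"),
            inherits(cfg, "assf_config"))
  if (!nrow(features$x)) stop("original training set is empty")
  if (length(unique(features$label)) < 2L) {
    stop("original training set must contain both classes")
  }
  if (!nrow(augset$x)) stop("augmented set is empty")

  selected <- integer(0)
  report <- data.frame(iteration = integer(0), n_selected = integer(0),
                       n_pos = integer(0), n_neg = integer(0),
                       selection_rate = numeric(0))
  model <- NULL
  m <- nrow(augset$x)
  for (it in seq_len(cfg$iterations)) {
    init_seed <- .derive_seed(cfg$seed, it, 1L)
    train_seed <- .derive_seed(cfg$seed, it, 2L)
    score_seed <- .derive_seed(cfg$seed, it, 3L)
    mcfg <- cfg$model
    mcfg$seed <- init_seed
    model <- init_model(mcfg)
    if (it == 1L || !length(selected)) {
      x <- features$x
      y <- features$label
    } else {
      x <- rbind(features$x, augset$x[selected, , drop = FALSE])
      y <- c(features$label, augset$label[selected])
    }
    tcfg <- cfg$train
    tcfg$seed <- train_seed
    model <- train_model(model, x, y, tcfg)
    augset <- score_augmented(model, augset, T = cfg$T, seed = score_seed)
    selected <- select_samples(augset, cfg$lambda, cfg$gamma)
    report <- rbind(report, data.frame(
      iteration = it,
      n_selected = length(selected),
      n_pos = sum(augset$label[selected] == 1L),
      n_neg = sum(augset$label[selected] == 0L),
      selection_rate = length(selected) / m))
  }
  list(model = model, selected = selected, augset = augset, report = report)
}
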