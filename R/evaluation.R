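#' Confusion counts from labels and predictions
#'
#' The positive class (label 1) is the ACP class.
#'
#' @param truth binary (0/1) true labels.
#' @param pred binary (0/1) predicted labels.
#' @return Named list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (length(truth) != length(pred)) stop("length mismatch")
  list(tp = sum(truth == 1L & pred == 1L),
       tn = sum(truth == 0L & pred == 0L),
       fp = sum(truth == 0L & pred == 1L),
       fn = sum(truth == 1L & pred == 0L))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, specificity, F1-score and the Matthews correlation
#' coefficient:
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' Degenerate denominators are mapped to 0: MCC is 0 when any factor
#' under the root is 0, F1 is 0 when 2TP + FP + FN = 0, and specificity
#' is 0 when TN + FP = 0.
#'
#' @param tp,tn,fp,fn non-negative integer confusion counts; at least one
#'   must be positive.
#' @return Named list with `accuracy`, `specificity`, `f1`, `mcc` and the
#'   counts.
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("no samples to evaluate")
  accuracy <- (tp + tn) / n
  specificity <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom) else 0
  list(accuracy = accuracy, specificity = specificity, f1 = f1, mcc = mcc,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Seeded stratified fold assignment
#'
#' @param labels binary label vector.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return Integer fold index (1..folds) per sample; each class is
#'   spread as evenly as possible across folds.
#' @export
stratified_folds <- function(labels, folds = 5L, seed = 1L) {
  labels <- as.integer(labels)
  folds <- as.integer(folds)
  if (min(tabulate(labels + 1L, 2L)) < folds) {
    stop("need at least ", folds, " samples per class")
  }
  set.seed(as.integer(seed))
  assignment <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

# Train one method on an encoded training fold. `augset` may be NULL for
# the baseline. Returns list(model, selected, report).
.train_method <- function(method, features, augset, cfg, fold_seed) {
  mcfg <- cfg$model
  tcfg <- cfg$train
  mcfg$seed <- .derive_seed(fold_seed, 11L)
  tcfg$seed <- .derive_seed(fold_seed, 12L)
  if (method == "baseline") {
    model <- train_model(init_model(mcfg), features$x, features$label, tcfg)
    return(list(model = model, selected = integer(0), report = NULL))
  }
  if (method == "tda") {
    x <- rbind(features$x, augset$x)
    y <- c(features$label, augset$label)
    model <- train_model(init_model(mcfg), x, y, tcfg)
    return(list(model = model, selected = seq_len(nrow(augset$x)),
                report = NULL))
  }
  fcfg <- cfg
  fcfg$seed <- .derive_seed(fold_seed, 13L)
  fit <- assf_train(features, augset, fcfg)
  list(model = fit$model, selected = fit$selected, report = fit$report)
}

.metrics_row <- function(model, test_features) {
  pred <- predict_label(model, test_features$x)
  cc <- confusion_counts(test_features$label, pred)
  compute_metrics(cc$tp, cc$tn, cc$fp, cc$fn)
}

#' Stratified k-fold cross-validation of one training method
#'
#' Per fold: the descriptor pipeline is fitted on the training split only
#' ([fit_encoder()]), both splits are encoded with it, augmentation (for
#' the `tda` and `assf` methods) is applied to the training split only,
#' the method is trained, and the held-out fold is evaluated with
#' deterministic (dropout-off) predictions.
#'
#' @param data a [peptide_dataset()].
#' @param method `"baseline"` (no augmentation), `"tda"` (train on all
#'   augmented samples) or `"assf"` (iterative uncertainty-aware
#'   selection).
#' @param cfg an [assf_config()].
#' @param pspec a [perturbation_spec()]; ignored for the baseline.
#' @param table an `aa_index_table` for the encoder.
#' @param folds number of folds (default 5).
#' @param seed integer seed fixing fold assignment and all per-fold
#'   stochastic stages.
#' @return A list with `per_fold` (data frame of per-fold metrics),
#'   `mean` (fold-mean metrics), `pooled` (metrics of the pooled
#'   confusion counts), and `fold_info` (per fold: test ids, train ids).
#' @export
cross_validate <- function(data, method = c("baseline", "tda", "assf"),
                           cfg = assf_config(), pspec = perturbation_spec(),
                           table = default_index_table(),
                           folds = 5L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(data, "peptide_dataset"))
  assignment <- stratified_folds(data$label, folds = folds, seed = seed)
  per_fold <- NULL
  pooled <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  fold_info <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(assignment == f)
    train_idx <- which(assignment != f)
    train_ds <- peptide_dataset(data$id[train_idx], data$sequence[train_idx],
                                data$label[train_idx], name = "train")
    test_ds <- peptide_dataset(data$id[test_idx], data$sequence[test_idx],
                               data$label[test_idx], name = "test")
    fold_seed <- .derive_seed(seed, f)
    enc <- fit_encoder(train_ds, table = table)
    ftr <- encode_dataset(train_ds, enc)
    fte <- encode_dataset(test_ds, enc)
    augset <- NULL
    if (method != "baseline") {
      ps <- pspec
      ps$seed <- .derive_seed(fold_seed, 7L)
      augset <- build_augmented_set(ftr, ps)
    }
    fit <- .train_method(method, ftr, augset, cfg, fold_seed)
    met <- .metrics_row(fit$model, fte)
    per_fold <- rbind(per_fold,
                      data.frame(fold = f, method = method,
                                 accuracy = met$accuracy,
                                 specificity = met$specificity,
                                 f1 = met$f1, mcc = met$mcc,
                                 tp = met$tp, tn = met$tn,
                                 fp = met$fp, fn = met$fn))
    pooled <- pooled + c(tp = met$tp, tn = met$tn, fp = met$fp, fn = met$fn)
    fold_info[[f]] <- list(test_ids = test_ds$id, train_ids = train_ds$id,
                           n_selected = length(fit$selected),
                           report = fit$report)
  }
  pooled_metrics <- compute_metrics(pooled["tp"], pooled["tn"],
                                    pooled["fp"], pooled["fn"])
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, c("accuracy", "specificity", "f1", "mcc")]),
       pooled = pooled_metrics,
       fold_info = fold_info)
}

#' Synthetic noisy-augmentation benchmark
#'
#' Emulates the baseline / traditional-augmentation / selection comparison
#' on generated peptides with injected label noise. Per seed: a two-class
#' synthetic dataset is generated, and in each stratified fold an
#' augmented set is built from the training split and a fraction
#' `flip_fraction` of its inherited labels is flipped. All three methods
#' share the encoder, folds and augmented set; the selection method
#' additionally reports how many flipped samples it excluded from its
#' final selected set.
#'
#' @param n_per_class peptides per class (default 100).
#' @param class_bias composition bias of the generator (default 0.9).
#' @param length_range sequence length interval.
#' @param cfg an [assf_config()].
#' @param pspec a [perturbation_spec()].
#' @param flip_fraction fraction of augmented samples whose inherited
#'   label is flipped (default 0.3).
#' @param seeds integer vector of benchmark seeds.
#' @param folds number of CV folds (default 5).
#' @param table an `aa_index_table`.
#' @param verbose print one line per seed/fold?
#' @return A list with `results` (tidy data frame: seed, fold, method,
#'   metrics), `per_seed` (per-seed fold-mean metrics per method),
#'   `exclusion` (per-seed flipped-sample exclusion rate of the selection
#'   method) and `summary` (median over seeds of per-seed mean metrics
#'   per method, plus the median exclusion rate).
#' @export
run_noisy_benchmark <- function(n_per_class = 100L, class_bias = 0.9,
                                length_range = c(10, 40),
                                cfg = assf_config(),
                                pspec = perturbation_spec(),
                                flip_fraction = 0.3,
                                seeds = 1:5, folds = 5L,
                                table = default_index_table(),
                                verbose = FALSE) {
  if (flip_fraction < 0 || flip_fraction > 1) {
    stop("flip_fraction must be in [0, 1]")
  }
  methods <- c("baseline", "tda", "assf")
  results <- NULL
  exclusion <- data.frame(seed = integer(0), flipped = integer(0),
                          flipped_selected = integer(0),
                          exclusion_rate = numeric(0))
  for (s in seeds) {
    data <- generate_synthetic_peptides(n_per_class, n_per_class,
                                        length_range = length_range,
                                        class_bias = class_bias,
                                        seed = .derive_seed(s, 1L))
    assignment <- stratified_folds(data$label, folds = folds,
                                   seed = .derive_seed(s, 2L))
    flipped_total <- 0L
    flipped_kept <- 0L
    for (f in seq_len(folds)) {
      train_idx <- which(assignment != f)
      test_idx <- which(assignment == f)
      train_ds <- peptide_dataset(data$id[train_idx], data$sequence[train_idx],
                                  data$label[train_idx])
      test_ds <- peptide_dataset(data$id[test_idx], data$sequence[test_idx],
                                 data$label[test_idx])
      fold_seed <- .derive_seed(s, 100L + f)
      enc <- fit_encoder(train_ds, table = table)
      ftr <- encode_dataset(train_ds, enc)
      fte <- encode_dataset(test_ds, enc)
      ps <- pspec
      ps$seed <- .derive_seed(fold_seed, 7L)
      augset <- build_augmented_set(ftr, ps)
      m <- nrow(augset$x)
      n_flip <- round(flip_fraction * m)
      set.seed(.derive_seed(fold_seed, 8L))
      flip_idx <- if (n_flip) sample.int(m, n_flip) else integer(0)
      augset$label[flip_idx] <- 1L - augset$label[flip_idx]
      for (method in methods) {
        fit <- .train_method(method, ftr, augset, cfg, fold_seed)
        met <- .metrics_row(fit$model, fte)
        results <- rbind(results, data.frame(
          seed = s, fold = f, method = method,
          accuracy = met$accuracy, specificity = met$specificity,
          f1 = met$f1, mcc = met$mcc,
          n_selected = length(fit$selected)))
        if (method == "assf") {
          flipped_total <- flipped_total + n_flip
          flipped_kept <- flipped_kept + sum(fit$selected %in% flip_idx)
        }
        if (verbose) {
          message(sprintf("seed %d fold %d %-8s acc %.3f", s, f, method,
                          met$accuracy))
        }
      }
    }
    exclusion <- rbind(exclusion, data.frame(
      seed = s, flipped = flipped_total,
      flipped_selected = flipped_kept,
      exclusion_rate = if (flipped_total) 1 - flipped_kept / flipped_total else NA_real_))
  }
  per_seed <- do.call(rbind, lapply(split(results, list(results$seed, results$method)),
    function(d) data.frame(seed = d$seed[1], method = d$method[1],
                           accuracy = mean(d$accuracy),
                           specificity = mean(d$specificity),
                           f1 = mean(d$f1), mcc = mean(d$mcc))))
  rownames(per_seed) <- NULL
  summarize <- function(meth) {
    d <- per_seed[per_seed$method == meth, ]
    c(accuracy = median(d$accuracy), specificity = median(d$specificity),
      f1 = median(d$f1), mcc = median(d$mcc))
  }
  summary <- list(baseline = summarize("baseline"),
                  tda = summarize("tda"),
                  assf = summarize("assf"),
                  exclusion_rate = median(exclusion$exclusion_rate))
  list(results = results, per_seed = per_seed, exclusion = exclusion,
       summary = summary)
}
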