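# Independent oracles and fixture builders shared across test files.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GROUP_OF <- local({
  groups <- list(G1 = c("G", "A", "V", "L", "M", "I"),
                 G2 = c("F", "Y", "W"),
                 G3 = c("K", "R", "H"),
                 G4 = c("D", "E"),
                 G5 = c("S", "T", "C", "P", "N", "Q"))
  m <- integer(0)
  for (g in seq_along(groups)) m[groups[[g]]] <- g
  m
})

random_peptide <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

# Brute-force k-spaced group-pair composition: enumerate every index pair
# (i, i + k + 1) and count ordered group pairs, independent of the
# vectorized encoder.
oracle_cksaagp <- function(sequence, k_values = 0:5) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  g <- GROUP_OF[chars]
  L <- length(chars)
  out <- numeric(0)
  for (k in k_values) {
    counts <- matrix(0, 5, 5)
    for (i in seq_len(max(L - k - 1L, 0L))) {
      counts[g[i], g[i + k + 1L]] <- counts[g[i], g[i + k + 1L]] + 1
    }
    denom <- L - (k + 1L)
    block <- if (denom >= 1L) as.vector(t(counts)) / denom else numeric(25)
    out <- c(out, block)
  }
  out
}

# Recompute the four evaluation metrics from a list of (label, prediction)
# pairs, formula by formula, without confusion_counts()/compute_metrics().
oracle_metrics <- function(truth, pred) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    else if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
    else if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    else fn <- fn + 1
  }
  acc <- (tn + tp) / (tn + tp + fn + fp)
  spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (d == 0) 0 else (tp * tn - fp * fn) / sqrt(d)
  list(accuracy = acc, specificity = spec, f1 = f1, mcc = mcc)
}

# Plug-in mutual information from a contingency table; written against
# table() so it shares no code with the package's tabulate-based estimator.
oracle_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) mi <- mi + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
    }
  }
  mi
}

# A small index table built in code (values are arbitrary but fixed).
toy_index_table <- function(n_scales = 4L, seed = 42L) {
  set.seed(seed)
  m <- matrix(round(rnorm(n_scales * 20), 3), n_scales, 20,
              dimnames = list(sprintf("scale%02d", seq_len(n_scales)), AA20))
  as_index_table(m)
}

# Encoded features for a small synthetic dataset; memoized per options.
toy_features <- local({
  cache <- new.env()
  function(n_per_class = 10L, bias = 0.9, seed = 7L) {
    key <- paste(n_per_class, bias, seed, sep = "_")
    if (is.null(cache[[key]])) {
      ds <- generate_synthetic_peptides(n_per_class, n_per_class,
                                        length_range = c(10, 40),
                                        class_bias = bias, seed = seed)
      enc <- fit_encoder(ds)
      cache[[key]] <- list(data = ds, encoder = enc,
                           features = encode_dataset(ds, enc))
    }
    cache[[key]]
  }
})

# Hand-built scored augmented set for selection-rule tests.
scored_augset <- function(u, mu, pseudo, label) {
  m <- length(u)
  structure(list(x = matrix(0, m, 4L),
                 label = as.integer(label),
                 source_id = sprintf("src%d", seq_len(m)),
                 pseudo_label = as.integer(pseudo),
                 confidence = as.numeric(mu),
                 uncertainty = as.numeric(u),
                 scored = TRUE,
                 layout = NULL),
            class = "acp_augset")
}

# Two linearly separable clusters for predictor tests (feature width 10).
toy_clusters <- function(n = 40L, width = 10L, seed = 3L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  centers <- ifelse(y == 1L, 1, -1)
  x <- matrix(rnorm(n * width, sd = 0.2), n, width) + centers
  list(x = x, y = y)
}

small_model_config <- function(width = 10L, ...) {
  model_config(layer_widths = c(width, 16L, 8L, 2L), ...)
}
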