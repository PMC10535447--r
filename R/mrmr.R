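#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy incremental mRMR with the MID (difference) criterion. Each
#' feature column is discretized into `n_bins` equal-frequency bins and
#' mutual information is estimated with the plug-in discrete estimator.
#' The first selected feature maximizes MI with the label; each subsequent
#' pick maximizes relevance MI(f; label) minus the mean MI(f; s) over the
#' already-selected features s. Ties are broken toward the lowest column
#' index, so the procedure is fully deterministic.
#'
#' @param feature_matrix numeric samples x features matrix.
#' @param labels binary (0/1) label vector, one per row.
#' @param n_select number of columns to retain.
#' @param n_bins number of equal-frequency bins (default 5).
#' @return Integer vector of `n_select` column indices in selection order.
#' @export
mrmr_select <- function(feature_matrix, labels, n_select, n_bins = 5L) {
  x <- as.matrix(feature_matrix)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("labels must match rows of feature_matrix")
  if (length(unique(labels)) < 2L) {
    stop("labels are constant; relevance is undefined")
  }
  if (min(tabulate(labels + 1L, 2L)) < 2L) {
    stop("need at least 2 samples per class")
  }
  p <- ncol(x)
  if (n_select > p) stop("n_select (", n_select, ") exceeds ", p, " columns")
  if (n_select < 1L) stop("n_select must be >= 1")

  bins <- apply(x, 2L, .equal_freq_bin, n_bins = n_bins)
  bins <- matrix(as.integer(bins), nrow(x), p)
  y <- labels + 1L

  relevance <- vapply(seq_len(p), function(j) .mi_discrete(bins[, j], y),
                      numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)          # cumulative MI with selected features
  remaining <- rep(TRUE, p)
  for (step in seq_len(n_select)) {
    score <- if (step == 1L) relevance else relevance - red_sum / (step - 1L)
    score[!remaining] <- -Inf
    pick <- which.max(score)     # which.max returns the first (lowest) index
    selected <- c(selected, pick)
    remaining[pick] <- FALSE
    if (step < n_select) {
      idx <- which(remaining)
      red_sum[idx] <- red_sum[idx] + vapply(idx, function(j) {
        .mi_discrete(bins[, j], bins[, pick])
      }, numeric(1))
    }
  }
  selected
}

# Equal-frequency binning via quantile breaks. Columns with at most
# n_bins distinct values keep one bin per value (quantile breaks would
# merge them); a constant column maps to a single bin (MI 0 with anything).
.equal_freq_bin <- function(v, n_bins) {
  uv <- sort(unique(v))
  if (length(uv) <= n_bins) return(match(v, uv))
  br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE, type = 7))
  if (length(br) <= 2L) return(rep(1L, length(v)))
  findInterval(v, br[-c(1L, length(br))]) + 1L
}

# Plug-in MI (nats) between two small positive-integer codes.
.mi_discrete <- function(a, b) {
  ka <- max(a); kb <- max(b)
  joint <- tabulate((a - 1L) * kb + b, nbins = ka * kb)
  n <- length(a)
  pj <- joint / n
  pa <- tabulate(a, ka) / n
  pb <- tabulate(b, kb) / n
  outer_p <- as.vector(t(outer(pa, pb)))   # matches (a-1)*kb + b indexing
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer_p[nz]))
}
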