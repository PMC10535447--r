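#' Feature layout of the concatenated descriptor vector
#'
#' The five descriptor segments are concatenated in a fixed order. With the
#' default 50 retained index-feature columns the layout is
#' BPF (offset 0, width 140), OPE (140, 40), CKSAAGP (180, 150),
#' AAC (330, 20), AAIF (350, 50): 400 coordinates in total, of which the
#' first 180 (BPF + OPE) are the non-perturbable part.
#'
#' @param n_aaif number of retained index-feature columns.
#' @return A data frame with columns `name`, `offset`, `width` and
#'   attribute `total_width`.
#' @export
feature_layout <- function(n_aaif = 50L) {
  widths <- c(BPF = 140L, OPE = 40L, CKSAAGP = 150L, AAC = 20L,
              AAIF = as.integer(n_aaif))
  out <- data.frame(name = names(widths),
                    offset = cumsum(c(0L, unname(widths[-5L]))),
                    width = unname(widths),
                    stringsAsFactors = FALSE)
  attr(out, "total_width") <- sum(widths)
  class(out) <- c("feature_layout", "data.frame")
  out
}

#' Indices of a layout segment
#' @param layout a [feature_layout()].
#' @param name segment name.
#' @return 1-based column indices of the segment.
#' @export
layout_segment <- function(layout, name) {
  row <- layout[layout$name == name, ]
  if (!nrow(row)) stop("unknown segment: ", name)
  seq(row$offset + 1L, row$offset + row$width)
}

.check_sequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (!length(chars)) stop("sequence must have length >= 1")
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  chars
}

# Standardize to 40 residues: truncate beyond 40, pad with "X".
.pad40 <- function(chars) {
  if (length(chars) >= 40L) chars[1:40] else c(chars, rep("X", 40L - length(chars)))
}

#' Binary profile feature (BPF)
#'
#' One-hot encoding of the first seven residues: for position i (0-based,
#' i < 7) holding the residue of alphabetical rank m, coordinate
#' 20 * i + m is 1. Positions beyond the sequence end stay all-zero.
#'
#' @param sequence peptide sequence.
#' @return Numeric 0/1 vector of length 140.
#' @export
encode_bpf <- function(sequence) {
  chars <- .check_sequence(sequence)
  out <- numeric(140L)
  n <- min(7L, length(chars))
  idx <- 20L * (seq_len(n) - 1L) + .aa_rank(chars[seq_len(n)]) + 1L
  out[idx] <- 1
  out
}

#' Ordinal positional encoding (OPE)
#'
#' The sequence is standardized to 40 residues (truncate / pad with X);
#' the residue of rank m at 0-based position l is coded as the integer
#' m * 40 + l, and padding positions are coded -1.
#'
#' @param sequence peptide sequence.
#' @return Numeric vector of length 40 with values in \{-1\} or
#'   \[0, 799\].
#' @export
encode_ope <- function(sequence) {
  chars <- .pad40(.check_sequence(sequence))
  l <- 0:39
  m <- .aa_rank(chars)           # NA for the X padding
  out <- m * 40 + l
  out[is.na(out)] <- -1
  as.numeric(out)
}

#' Composition of k-spaced amino acid group pairs (CKSAAGP)
#'
#' Residues are mapped to five physicochemical groups (aliphatic GAVLMI,
#' aromatic FYW, cationic KRH, anionic DE, uncharged STCPNQ). For each gap
#' k the 25 ordered group pairs at positions (i, i + k + 1) are counted
#' and divided by L - (k + 1). Blocks are ordered by ascending k; within a
#' block pairs are ordered G1G1, G1G2, ..., G5G5. A block whose gap
#' exceeds the sequence (L <= k + 1) is all zeros.
#'
#' @param sequence peptide sequence.
#' @param k_values gaps to include (default 0..5).
#' @return Numeric vector of length `25 * length(k_values)`.
#' @export
encode_cksaagp <- function(sequence, k_values = 0:5) {
  chars <- .check_sequence(sequence)
  g <- .aa_group(chars)
  L <- length(chars)
  out <- numeric(0)
  for (k in k_values) {
    npairs <- L - (k + 1L)
    if (npairs < 1L) {
      out <- c(out, numeric(25L))
    } else {
      first <- g[seq_len(npairs)]
      second <- g[seq_len(npairs) + k + 1L]
      counts <- tabulate((first - 1L) * 5L + second, nbins = 25L)
      out <- c(out, counts / npairs)
    }
  }
  out
}

#' Amino acid composition (AAC)
#'
#' Frequency of each of the 20 standard residues, ordered alphabetically.
#'
#' @param sequence peptide sequence.
#' @return Numeric vector of length 20 summing to 1.
#' @export
encode_aac <- function(sequence) {
  chars <- .check_sequence(sequence)
  tabulate(.aa_rank(chars) + 1L, nbins = 20L) / length(chars)
}

#' Positional physicochemical index feature (AAIF, unreduced)
#'
#' The sequence is standardized to 40 residues as in [encode_ope()]; the
#' output coordinate for (scale j, position l) holds the value of scale j
#' for the residue at l, and 0 at padded positions. Coordinates are laid
#' out scale-major: the 40 positions of scale 1, then scale 2, and so on,
#' giving `nrow(table) * 40` coordinates (e.g. 21,240 for a 531-scale
#' table).
#'
#' @param sequence peptide sequence.
#' @param table an `aa_index_table`.
#' @return Named numeric vector of length `nrow(table) * 40`.
#' @export
encode_aaindex_positional <- function(sequence, table) {
  stopifnot(inherits(table, "aa_index_table"))
  chars <- .pad40(.check_sequence(sequence))
  col <- match(chars, AA_ALPHABET)          # NA at padding
  m <- matrix(0, nrow(table), 40L)
  ok <- !is.na(col)
  m[, ok] <- table[, col[ok], drop = FALSE]
  out <- as.vector(t(m))
  names(out) <- paste0(rep(rownames(table), each = 40L), "_p", rep(1:40, nrow(table)))
  out
}

#' Fit the descriptor pipeline on a training set
#'
#' Computes the positional index-feature matrix of the training records,
#' selects `n_aaif` of its columns by minimum-redundancy maximum-relevance
#' ([mrmr_select()]) against the training labels, and freezes the feature
#' layout. The fitted state is reusable on unseen sequences, so test
#' records never influence feature selection.
#'
#' @param train a [peptide_dataset()] with both classes present.
#' @param table an `aa_index_table` (default: the bundled scale set).
#' @param n_aaif number of retained index-feature columns (default 50).
#' @param n_bins discretization bins for the mutual-information estimates.
#' @return An object of class `acp_encoder`.
#' @export
fit_encoder <- function(train, table = default_index_table(),
                        n_aaif = 50L, n_bins = 5L) {
  stopifnot(inherits(train, "peptide_dataset"))
  n_candidates <- nrow(table) * 40L
  if (n_aaif > n_candidates) {
    stop("n_aaif (", n_aaif, ") exceeds the ", n_candidates,
         " candidate index-feature columns")
  }
  aaif <- t(vapply(train$sequence, encode_aaindex_positional,
                   numeric(n_candidates), table = table, USE.NAMES = FALSE))
  cols <- mrmr_select(aaif, train$label, n_select = n_aaif, n_bins = n_bins)
  structure(list(table = table,
                 aaif_cols = cols,
                 aaif_names = colnames(aaif)[cols] %||%
                   names(encode_aaindex_positional(train$sequence[1L], table))[cols],
                 layout = feature_layout(n_aaif),
                 n_bins = n_bins),
            class = "acp_encoder")
}

#' @export
print.acp_encoder <- function(x, ...) {
  cat(sprintf("acp_encoder: %d scales, %d retained AAIF columns, total width %d\n",
              nrow(x$table), length(x$aaif_cols),
              attr(x$layout, "total_width")))
  invisible(x)
}

#' Encode one sequence with a fitted encoder
#'
#' @param sequence peptide sequence.
#' @param encoder a fitted `acp_encoder`.
#' @return Numeric vector of length `total_width` in the fixed segment
#'   order BPF, OPE, CKSAAGP, AAC, AAIF.
#' @export
encode_sequence <- function(sequence, encoder) {
  stopifnot(inherits(encoder, "acp_encoder"))
  aaif <- encode_aaindex_positional(sequence, encoder$table)[encoder$aaif_cols]
  c(encode_bpf(sequence), encode_ope(sequence), encode_cksaagp(sequence),
    encode_aac(sequence), unname(aaif))
}

#' Encode a dataset with a fitted encoder
#'
#' @param data a [peptide_dataset()].
#' @param encoder a fitted `acp_encoder`.
#' @return An `acp_features` object: list with the numeric matrix `x`
#'   (one row per record), integer `label`, character `id` and the frozen
#'   `layout`.
#' @export
encode_dataset <- function(data, encoder) {
  stopifnot(inherits(data, "peptide_dataset"), inherits(encoder, "acp_encoder"))
  width <- attr(encoder$layout, "total_width")
  x <- t(vapply(data$sequence, encode_sequence, numeric(width),
                encoder = encoder, USE.NAMES = FALSE))
  rownames(x) <- data$id
  structure(list(x = x, label = data$label, id = data$id,
                 layout = encoder$layout),
            class = "acp_features")
}

#' @export
print.acp_features <- function(x, ...) {
  cat(sprintf("acp_features: %d samples x %d coordinates (%d positive)\n",
              nrow(x$x), ncol(x$x), sum(x$label == 1L)))
  invisible(x)
}

#' Save / load a fitted encoder
#'
#' The fitted state (index table, retained column identifiers, layout) is
#' written to a single sidecar file so train/test encoding is reproducible
#' across sessions.
#'
#' @param encoder a fitted `acp_encoder`.
#' @param path file path.
#' @return `load_encoder` returns the `acp_encoder`.
#' @export
save_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "acp_encoder"))
  saveRDS(encoder, path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  enc <- readRDS(path)
  stopifnot(inherits(enc, "acp_encoder"))
  enc
}
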