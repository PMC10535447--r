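#' Construct a labeled peptide dataset
#'
#' A peptide dataset is a data frame with columns `id`, `sequence` and
#' `label` (1 = ACP/positive, 0 = non-ACP/negative). Sequences must use the
#' 20 standard one-letter residue codes; lowercase input is uppercased.
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of peptide sequences.
#' @param label integer vector of binary class labels (0/1).
#' @param name dataset name.
#' @return An object of class `peptide_dataset` (a data frame).
#' @export
peptide_dataset <- function(id, sequence, label, name = "dataset") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  label <- as.integer(label)
  if (length(id) != length(sequence) || length(id) != length(label)) {
    stop("id, sequence and label must have equal length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate record ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (length(label) && !all(label %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)")
  }
  if (length(sequence) && any(nchar(sequence) < 1L)) {
    stop("sequences must have length >= 1")
  }
  for (i in seq_along(sequence)) {
    chars <- strsplit(sequence[i], "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), AA_ALPHABET)
    if (length(bad)) {
      stop("record '", id[i], "' contains non-standard residue(s): ",
           paste(bad, collapse = ", "))
    }
  }
  out <- data.frame(id = id, sequence = sequence, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_dataset", "data.frame")
  attr(out, "name") <- name
  out
}

#' @export
print.peptide_dataset <- function(x, ...) {
  cat(sprintf("peptide_dataset '%s': %d records (%d positive, %d negative)\n",
              attr(x, "name") %||% "dataset", nrow(x),
              sum(x$label == 1L), sum(x$label == 0L)))
  if (nrow(x)) print(head(as.data.frame(x), 6))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a labeled peptide FASTA file
#'
#' Labels are taken either from a trailing `|1` / `|0` token on each header
#' line (`header_suffix`, the default) or from a two-column tab-separated
#' sidecar file mapping ids to labels (`sidecar`).
#'
#' @param path FASTA file path.
#' @param label_scheme `"header_suffix"` or `"sidecar"`.
#' @param sidecar_path path of the id/label TSV; required for the sidecar
#'   scheme. The file must have two columns (id, label) and no header.
#' @param name dataset name; defaults to the file name.
#' @return A [peptide_dataset()].
#' @export
read_labeled_fasta <- function(path,
                               label_scheme = c("header_suffix", "sidecar"),
                               sidecar_path = NULL,
                               name = basename(path)) {
  label_scheme <- match.arg(label_scheme)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) {
    return(peptide_dataset(character(0), character(0), integer(0), name = name))
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("malformed FASTA at line ", nonempty[1], ": expected '>' header")
  }
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  sequences <- as.character(seqs)

  if (label_scheme == "header_suffix") {
    has_tok <- grepl("\\|[01]\\s*$", headers)
    if (any(!has_tok)) {
      stop("missing '|0'/'|1' label token on header(s): ",
           paste(headers[!has_tok], collapse = ", "))
    }
    label <- as.integer(sub("^.*\\|([01])\\s*$", "\\1", headers))
    id <- sub("\\|[01]\\s*$", "", headers)
  } else {
    if (is.null(sidecar_path)) stop("sidecar_path is required for the sidecar scheme")
    tab <- read.delim(sidecar_path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("sidecar label file must have two columns (id, label)")
    id <- sub("\\s.*$", "", headers)
    label <- as.integer(tab[[2L]][match(id, as.character(tab[[1L]]))])
    if (anyNA(label)) {
      stop("no label found in sidecar for id(s): ",
           paste(id[is.na(label)], collapse = ", "))
    }
  }
  peptide_dataset(id = id, sequence = sequences, label = label, name = name)
}

#' Write a labeled peptide FASTA file
#'
#' Writes one entry per record with the label appended to the header as
#' `|<0/1>`, so that [read_labeled_fasta()] round-trips the dataset.
#'
#' @param dataset a [peptide_dataset()].
#' @param path output file path.
#' @export
write_labeled_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  if (anyDuplicated(dataset$id)) stop("refusing to write dataset with duplicate ids")
  if (!nrow(dataset)) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- Biostrings::AAStringSet(dataset$sequence)
  names(seqs) <- paste0(dataset$id, "|", dataset$label)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a dataset distributed as separate positive / negative FASTA files
#'
#' Public ACP benchmark sets are often shipped as one FASTA of validated
#' anticancer peptides and one of non-ACP sequences; this loader maps the
#' file split to labels (1 for every record of `positive_path`, 0 for
#' `negative_path`). Headers need no label token; the first whitespace
#' token of each header is used as the id, prefixed with `pos_`/`neg_`
#' when the two files reuse ids.
#'
#' @param positive_path FASTA of positive (ACP) sequences.
#' @param negative_path FASTA of negative sequences.
#' @param name dataset name.
#' @return A [peptide_dataset()].
#' @export
read_split_fasta <- function(positive_path, negative_path, name = "acp") {
  read_one <- function(path) {
    seqs <- Biostrings::readBStringSet(path)
    list(id = sub("\\s.*$", "", names(seqs)), seq = as.character(seqs))
  }
  pos <- read_one(positive_path)
  neg <- read_one(negative_path)
  if (length(intersect(pos$id, neg$id))) {
    pos$id <- paste0("pos_", pos$id)
    neg$id <- paste0("neg_", neg$id)
  }
  peptide_dataset(id = c(pos$id, neg$id),
                  sequence = c(pos$seq, neg$seq),
                  label = rep(c(1L, 0L), c(length(pos$id), length(neg$id))),
                  name = name)
}

#' Generate a synthetic labeled peptide dataset
#'
#' Emulates a two-class therapeutic-peptide benchmark: positive (ACP-like)
#' sequences are composition-tilted toward the cationic residues K, R, H,
#' negatives toward D, E, S, T. The tilt is multiplicative on a uniform
#' 20-residue frequency vector (favored residues get weight `1 + 3 *
#' class_bias`, then the vector is renormalized), so `class_bias = 0`
#' yields exchangeable classes and larger values make the classes
#' separable by composition-based descriptors. Lengths are drawn uniformly
#' on `length_range`.
#'
#' @param n_pos,n_neg number of positive / negative records.
#' @param length_range integer interval of sequence lengths, within
#'   \[5, 60\].
#' @param class_bias composition bias in \[0, 1\].
#' @param seed integer seed; output is a deterministic function of the
#'   arguments.
#' @return A [peptide_dataset()].
#' @export
generate_synthetic_peptides <- function(n_pos, n_neg,
                                        length_range = c(10, 40),
                                        class_bias = 0.5,
                                        seed = 1L) {
  if (n_pos < 0 || n_neg < 0) stop("counts must be >= 0")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 5L || length_range[2] > 60L) {
    stop("length_range must be an interval within [5, 60]")
  }
  if (class_bias < 0 || class_bias > 1) stop("class_bias must be in [0, 1]")
  set.seed(as.integer(seed))

  tilt <- function(favored) {
    w <- rep(1, 20)
    w[match(favored, AA_ALPHABET)] <- 1 + 3 * class_bias
    w / sum(w)
  }
  freq_pos <- tilt(c("K", "R", "H"))
  freq_neg <- tilt(c("D", "E", "S", "T"))

  draw <- function(n, freq, prefix) {
    if (!n) return(list(id = character(0), seq = character(0)))
    len <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(len, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = freq), collapse = "")
    }, character(1))
    list(id = sprintf("%s_%04d", prefix, seq_len(n)), seq = seqs)
  }
  pos <- draw(n_pos, freq_pos, "pos")
  neg <- draw(n_neg, freq_neg, "neg")
  peptide_dataset(id = c(pos$id, neg$id),
                  sequence = c(pos$seq, neg$seq),
                  label = c(rep(1L, n_pos), rep(0L, n_neg)),
                  name = sprintf("synthetic_bias%.2f_seed%d", class_bias,
                                 as.integer(seed)))
}
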