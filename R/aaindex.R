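#' Read a physicochemical index table
#'
#' An index table maps each of the 20 standard residues to a numeric value
#' under a named physicochemical scale (AAindex-style). Two plain-text
#' layouts are accepted:
#'
#' * **TSV** — header row `index<TAB>A<TAB>C...Y`, one scale per row;
#' * **AAindex flat file** — records introduced by `H <accession>` whose
#'   `I` line is followed by two rows of 10 values in the canonical
#'   AAindex residue order `A R N D C Q E G H I / L K M F P S T W Y V`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"aaindex"`; guessed from the first line when
#'   omitted.
#' @return An `aa_index_table`: a numeric matrix with one row per scale and
#'   the 20 residues (alphabetical one-letter order) as columns.
#' @export
read_index_table <- function(path, format = c("auto", "tsv", "aaindex")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("index table not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "H ")) "aaindex" else "tsv"
  }
  if (format == "tsv") {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (!all(AA_ALPHABET %in% colnames(tab))) {
      stop("TSV index table must have one column per residue A..Y")
    }
    m <- as.matrix(tab[, AA_ALPHABET, drop = FALSE])
    rownames(m) <- as.character(tab[[1L]])
  } else {
    m <- .parse_aaindex_flat(readLines(path, warn = FALSE))
  }
  as_index_table(m)
}

# AAindex flat files list values in the order A R N D C Q E G H I (row 1)
# then L K M F P S T W Y V (row 2).
.parse_aaindex_flat <- function(lines) {
  order_flat <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  entries <- list()
  i <- 1L
  current <- NULL
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "H ")) current <- trimws(sub("^H ", "", ln))
    if (startsWith(ln, "I ")) {
      vals <- suppressWarnings(as.numeric(strsplit(
        trimws(paste(lines[i + 1L], lines[i + 2L])), "\\s+")[[1L]]))
      if (length(vals) != 20L || anyNA(vals)) {
        stop("malformed AAindex record '", current, "'")
      }
      names(vals) <- order_flat
      entries[[current]] <- vals[AA_ALPHABET]
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (!length(entries)) stop("no AAindex records found")
  do.call(rbind, entries)
}

#' Coerce a matrix to an index table
#'
#' @param m numeric matrix with named rows (scales) and a column per
#'   residue; columns are reordered to the alphabetical residue order.
#' @return An `aa_index_table`.
#' @export
as_index_table <- function(m) {
  m <- as.matrix(m)
  if (!all(AA_ALPHABET %in% colnames(m))) {
    stop("index table must define a value for all 20 residues")
  }
  m <- m[, AA_ALPHABET, drop = FALSE]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("index table contains missing values")
  if (nrow(m) < 2L) stop("index table must contain at least 2 scales")
  if (is.null(rownames(m))) rownames(m) <- sprintf("index_%03d", seq_len(nrow(m)))
  class(m) <- c("aa_index_table", "matrix")
  m
}

#' Bundled physicochemical scale set
#'
#' Returns the compact curated set of physicochemical scales shipped with
#' the package (hydropathy, hydrophilicity, volume, polarity, charge,
#' secondary-structure propensities, residue-class indicators, ...). It is
#' a small stand-in for the full 500+ scale AAindex database: large enough
#' for minimum-redundancy feature selection to have real choices, small
#' enough to keep encoding fast.
#'
#' @return An `aa_index_table` with 23 scales.
#' @export
default_index_table <- function() {
  read_index_table(system.file("extdata", "aaindex_subset.tsv",
                               package = "acpassf"),
                   format = "tsv")
}
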