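#' Perturbation specification for feature-space augmentation
#'
#' Augmented samples are generated as `xa = xo * V * omega + xo`, where
#' `V` is the elementwise product of a fixed 0/1 mask and a fresh uniform
#' draw on \[0, 1\]. The mask zeroes the BPF and OPE segments (the first
#' 180 coordinates under the default layout), so one-hot and ordinal codes
#' are never perturbed; the remaining 220 composition/index coordinates
#' are scaled by at most a factor `1 + omega`.
#'
#' @param omega perturbation factor in \[0, 1\].
#' @param ratio positive integer: number of augmented samples generated
#'   per original training sample (the N/R ratio).
#' @param seed integer seed making augmentation reproducible.
#' @param layout a [feature_layout()]; fixes the mask.
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(omega = 0.006, ratio = 2L, seed = 1L,
                              layout = feature_layout()) {
  if (omega < 0 || omega > 1) stop("omega must be in [0, 1]")
  ratio <- as.integer(ratio)
  if (is.na(ratio) || ratio < 1L) stop("ratio must be a positive integer")
  width <- attr(layout, "total_width")
  mask <- rep(1, width)
  mask[c(layout_segment(layout, "BPF"), layout_segment(layout, "OPE"))] <- 0
  structure(list(omega = omega, ratio = ratio, seed = as.integer(seed),
                 mask = mask, layout = layout),
            class = "perturbation_spec")
}

#' Perturb one feature vector
#'
#' @param source numeric feature vector.
#' @param spec a [perturbation_spec()].
#' @param draw uniform random vector in \[0, 1\], same length as `source`.
#' @return The perturbed vector `source * (mask * draw) * omega + source`.
#' @export
perturb <- function(source, spec, draw) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (length(source) != length(spec$mask)) {
    stop("source has ", length(source), " coordinates; mask expects ",
         length(spec$mask))
  }
  if (length(draw) != length(source)) stop("draw length mismatch")
  if (any(draw < 0 | draw > 1)) stop("draw values must lie in [0, 1]")
  source * (spec$mask * draw) * spec$omega + source
}

#' Build an augmented sample set
#'
#' Source vectors are drawn uniformly at random with replacement from the
#' training collection; each augmented sample inherits its source label
#' and uses a fresh uniform draw. Output is deterministic given
#' `spec$seed`.
#'
#' @param features an `acp_features` object (the encoded training fold).
#' @param spec a [perturbation_spec()].
#' @return An `acp_augset`: list with matrix `x`
#'   (`ratio * n` rows), `label`, `source_id`, and unscored
#'   `pseudo_label` / `confidence` / `uncertainty` slots.
#' @export
build_augmented_set <- function(features, spec) {
  stopifnot(inherits(features, "acp_features"), inherits(spec, "perturbation_spec"))
  n <- nrow(features$x)
  if (!n) stop("training collection is empty")
  if (ncol(features$x) != length(spec$mask)) {
    stop("feature width does not match the perturbation mask")
  }
  m <- spec$ratio * n
  set.seed(spec$seed)
  src <- sample.int(n, m, replace = TRUE)
  draws <- matrix(runif(m * ncol(features$x)), nrow = m)
  draws[, spec$mask == 0] <- 0
  xs <- features$x[src, , drop = FALSE]
  xa <- xs * draws * spec$omega + xs
  rownames(xa) <- sprintf("aug_%05d", seq_len(m))
  structure(list(x = xa,
                 label = features$label[src],
                 source_id = features$id[src],
                 pseudo_label = rep(NA_integer_, m),
                 confidence = rep(NA_real_, m),
                 uncertainty = rep(NA_real_, m),
                 scored = FALSE,
                 layout = features$layout),
            class = "acp_augset")
}

#' @export
print.acp_augset <- function(x, ...) {
  cat(sprintf("acp_augset: %d augmented samples (%s)\n", nrow(x$x),
              if (isTRUE(x$scored)) "scored" else "unscored"))
  invisible(x)
}

#' Export an augmented set as a data frame
#'
#' One row per augmented sample: source id, inherited label, scoring
#' columns (NA until [score_augmented()] has run), then the feature
#' coordinates. Intended for audit / CLI export.
#'
#' @param augset an `acp_augset`.
#' @return A data frame.
#' @export
augset_as_data_frame <- function(augset) {
  stopifnot(inherits(augset, "acp_augset"))
  data.frame(sample = rownames(augset$x),
             source_id = augset$source_id,
             label = augset$label,
             pseudo_label = augset$pseudo_label,
             confidence = augset$confidence,
             uncertainty = augset$uncertainty,
             augset$x,
             check.names = FALSE,
             stringsAsFactors = FALSE)
}
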