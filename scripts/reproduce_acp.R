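#!/usr/bin/env Rscript
# Optional: run the full baseline / TDA / selection comparison on a public
# ACP benchmark distributed as positive/negative FASTA files (e.g. the
# ACP-DL datasets). Asserts nothing; prints and writes the fold metrics.
#
# Usage:
#   Rscript scripts/reproduce_acp.R <positive.fasta> <negative.fasta> [out.csv]
#
# Expect runtimes of tens of minutes on one CPU for a ~740-sequence set.

suppressPackageStartupMessages(library(acpassf))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2) {
  stop("usage: reproduce_acp.R <positive.fasta> <negative.fasta> [out.csv]")
}
ds <- read_split_fasta(args[1], args[2])
cat(sprintf("loaded %d sequences (%d positive / %d negative)\n",
            nrow(ds), sum(ds$label == 1), sum(ds$label == 0)))

batch <- if (nrow(ds) > 400) 64L else 32L
cfg <- assf_config(model = model_config(standardize = TRUE),
                   train = train_config(batch_size = batch))
pspec <- perturbation_spec(omega = 0.006, ratio = 2)

all_rows <- NULL
for (method in c("baseline", "tda", "assf")) {
  res <- cross_validate(ds, method = method, cfg = cfg, pspec = pspec,
                        folds = 5, seed = 1)
  cat(sprintf("%-8s  fold-mean: acc %.4f  spec %.4f  f1 %.4f  mcc %.4f\n",
              method, res$mean[["accuracy"]], res$mean[["specificity"]],
              res$mean[["f1"]], res$mean[["mcc"]]))
  all_rows <- rbind(all_rows, res$per_fold)
}
if (length(args) >= 3) {
  write.csv(all_rows, args[3], row.names = FALSE)
  cat("wrote", args[3], "\n")
}
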