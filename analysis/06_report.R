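#!/usr/bin/env Rscript
# Assemble the stage outputs into one deterministic summary report.

suppressPackageStartupMessages(library(smaccess))

out <- "results/analysis"
read_tsv <- function(f) {
  p <- file.path(out, f)
  if (file.exists(p)) utils::read.table(p, sep = "\t", header = TRUE) else NULL
}

cf <- read_tsv("class_fractions.tsv")
kin <- read_tsv("kinetics_summary.tsv")
fc <- NULL
if (!is.null(cf)) {
  s7pos <- sum(cf$fraction[grepl("S7\\+", cf$class_label)])
  fc <- list("S7+ observed vs 50% baseline" = fold_change(0.5, s7pos))
}

report <- build_report(list(
  class_fractions = cf,
  fold_changes = fc,
  kinetics = kin,
  seed = 20260101L))
writeLines(report, file.path(out, "report.md"))
message("report written to ", file.path(out, "report.md"))
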