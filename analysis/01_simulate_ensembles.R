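#!/usr/bin/env Rscript
# Simulate the reference ensembles used by the downstream analysis steps:
# an immobilized-ssRNA H30 probing experiment (positive control for maximal
# accessibility) and a cotranscriptional two-reporter experiment (S7 protein
# + H2829 probe, mutually exclusive binding). Traces are written in the
# package's directory format together with the ground-truth event table, so
# every later stage can be checked against what was actually generated.

suppressPackageStartupMessages(library(smaccess))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Simulating 60 immobilized ssRNA molecules (H30 probe, 600 s) ...")
cfg_ssrna <- sim_config(
  60,
  reporters = list(H30 = reporter_preset("H30")),
  class_probabilities = c("H30+" = 0.9, "H30-" = 0.1),
  mode = "immobilized_rna", duration = 600, seed = 20260101)
ssrna <- simulate_ensemble(cfg_ssrna)
write_traces(ssrna$traces, file.path(out, "ssrna_h30"))
write_events(truth_event_table(ssrna$truth),
             file.path(out, "ssrna_h30_truth_events.tsv"))

message("Simulating 80 cotranscriptional molecules (S7 + H2829) ...")
cfg_cotx <- sim_config(
  80,
  reporters = list(S7 = reporter_preset("S7"),
                   H2829 = reporter_preset("H2829")),
  class_probabilities = c("S7+/H2829+" = 0.375, "S7+/H2829-" = 0.125,
                          "S7-/H2829+" = 0.35, "S7-/H2829-" = 0.15),
  exclusivity_pairs = list(c("S7", "H2829")),
  mode = "cotranscriptional", duration = 600, seed = 20260102)
cotx <- simulate_ensemble(cfg_cotx)
write_traces(cotx$traces, file.path(out, "cotx_s7_h2829"))
write_events(truth_event_table(cotx$truth),
             file.path(out, "cotx_s7_h2829_truth_events.tsv"))

message("True class composition (cotranscriptional run):")
print(table(cotx$truth$classes$class_label))
message("Traces and ground truth written under ", out)
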