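# smaccess

Single-molecule trace analysis for dynamic RNA structure probing: from
multicolor TIRF intensity traces to binding events, folding classes,
accessibility scores, kinetics and equilibrium constants — plus a
ground-truth trace simulator that makes every stage testable.

## What problem this addresses

In cotranscriptional RNA structure probing experiments, a surface-attached
nascent RNA (e.g. the 16S rRNA 3' domain) is watched while short
acceptor-labeled DNA probes transiently hybridize to single-stranded sites
(FRET against a donor on the RNA), a labeled ribosomal protein reports
functional folding, and a labeled DNA template reports transcription
elongation. The analysis questions are per-molecule: *when is each site
accessible, does the protein bind, and how do these co-vary across the
conformational ensemble?* This package implements that trace analysis as a
reusable, tested pipeline for people building or reanalyzing such
experiments. Raw traces for the motivating experiments are not publicly
deposited, so the package includes a kinetic Monte Carlo simulator of the
full experiment (binding renewal processes, transcription signal, donor
bleaching, crosstalk, camera noise, laser dead time) whose ground truth
validates every downstream stage.

## The core quantities

* FRET efficiency per acceptor against the shared donor,
  `E = I_A / (I_A + I_D)`; frames are bound when `E` exceeds the midpoint
  of the two FRET states (estimated per reporter from pooled data), with a
  donor-acceptor anticorrelation screen separating binding from
  fluorophore sticking.
* Dwell and arrival kinetics by censored exponential maximum likelihood,
  with missed-event (detection dead time) corrections; medians via
  Kaplan-Meier under heavy censoring.
* Equilibrium constant from the bound-time fraction
  `Y = t_PR / (t_PR + t_R)` over a 200 s-to-bleach window:
  `Kd = (1 - Y) / Y * [P]0`, per molecule and pooled per folding class.
* Folding classes by the at-least-one-event rule over `k` reporters
  (`2^k` classes, e.g. `S7+/H2829-`), class fractions and fold changes,
  accessibility scores (mean fraction of time bound), 5-s time-binned
  accessibility profiles.
* Event-count-weighted WPGMA clustering of molecules on Spearman
  dissimilarity of binding occupancy, with rasterplot rendering.

## Worked example

Simulate an immobilized-ssRNA probing experiment (H30 probe, 200 nM,
600-s traces) and run the full pipeline:

```r
library(smaccess)

cfg <- sim_config(60,
  reporters = list(H30 = reporter_preset("H30")),
  class_probabilities = c("H30+" = 0.9, "H30-" = 0.1),
  mode = "immobilized_rna", duration = 600, seed = 20260101)
sim  <- simulate_ensemble(cfg)
pipe <- run_pipeline(sim$traces)

sum(pipe$annotations$selected)                     # 54 of 60 molecules pass
pipe$thresholds$H30$threshold                      # 0.441 (states 0.138 / 0.743)
kinetics_summary(pipe, "H30", cfg$frame_period)
```

The selection passes 54/60 molecules (the rest lack a single terminal
bleach step), the two FRET states are found at 0.138 and 0.743 giving a
midpoint threshold of 0.441, and the kinetics summary reports a median
bound lifetime of 1.55 s with `koff = 0.433 /s` — the generating unbinding
rate (`ln 2 / 0.433 = 1.6 s`). Classification (`pipe$assignments`)
recovers ~90% `H30+` molecules, matching the simulated class mix.

The numbered scripts under `analysis/` run the same workflow as a narrative
sequence — simulate (`01`), select + detect (`02`), kinetics incl. on-rate
vs concentration and per-class S7 Kd (`03`), classes + profiles (`04`),
clustering + raster (`05`), report (`06`) — writing their tables under
`results/analysis/`.

## Documentation

The methods vignette (`vignettes/trace-analysis-methods.Rmd`) describes the
simulator's generative model, the selection and detection algorithms, the
missed-event corrections, all tunable parameters with their defaults and
rationale, and known limitations.
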