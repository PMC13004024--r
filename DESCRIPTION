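Package: smaccess
Title: Single-Molecule Trace Analysis of Nascent RNA Accessibility and
    Protein Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of multicolor single-molecule
    fluorescence intensity traces from cotranscriptional RNA structure
    probing experiments, in which transient hybridization of short
    dye-labeled DNA probes reports local RNA accessibility and binding of a
    labeled ribosomal protein reports functional folding. Provides a
    kinetic Monte Carlo trace simulator with ground truth, trace selection
    by transcription-signal and single-step donor-photobleach criteria,
    FRET-threshold binding-event detection with donor-acceptor
    anticorrelation filtering, censored exponential dwell-time and arrival
    kinetics, equilibrium dissociation constants from bound-time
    fractions, per-molecule folding-class assignment with accessibility
    scores and time-binned accessibility profiles, and event-count
    weighted hierarchical clustering of binding rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
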