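#' Reporter binding kinetics
#'
#' Describes the binding/unbinding kinetics and photophysics of one reporter
#' (a short DNA probe or a labeled protein) in the trace simulator. Binding is
#' pseudo-first-order at rate `binding_rate_constant * probe_concentration`;
#' the bound dwell is exponential (`unbinding_rate`) or a finite mixture of
#' exponentials (`dwell_rates` + `dwell_weights`), matching the
#' single-exponential probe dwells and the two-phase protein dwells seen in
#' this kind of experiment.
#'
#' @param binding_rate_constant Association rate constant, in M^-1 s^-1.
#' @param probe_concentration Reporter concentration, in molar.
#' @param unbinding_rate Single-exponential unbinding rate, s^-1. Mutually
#'   exclusive with `dwell_rates`.
#' @param dwell_rates,dwell_weights Rates (s^-1) and mixing weights of a
#'   mixture-of-exponentials bound dwell. Weights must sum to 1.
#' @param fret_efficiency FRET efficiency of the bound state, in (0, 1].
#' @param gate Optional two-state accessibility gate: a numeric vector
#'   `c(on_rate, off_rate)` in s^-1 (rates of switching the site accessible /
#'   inaccessible), or `NULL` for a permanently accessible site. Binding is
#'   only possible while the gate is on; an optional third element
#'   `start_on` (0/1, default 1) sets the initial gate state.
#'
#' @return An object of class `reporter_kinetics`.
#' @export
reporter_kinetics <- function(binding_rate_constant, probe_concentration,
                              unbinding_rate = NULL, dwell_rates = NULL,
                              dwell_weights = NULL, fret_efficiency = 0.75,
                              gate = NULL) {
  stopifnot(is.numeric(binding_rate_constant), binding_rate_constant >= 0,
            is.numeric(probe_concentration), probe_concentration >= 0,
            fret_efficiency > 0, fret_efficiency <= 1)
  if (is.null(dwell_rates)) {
    if (is.null(unbinding_rate)) {
      stop("supply either 'unbinding_rate' or a 'dwell_rates' mixture")
    }
    dwell_rates <- unbinding_rate
    dwell_weights <- 1
  } else {
    if (!is.null(unbinding_rate)) {
      stop("'unbinding_rate' and 'dwell_rates' are mutually exclusive")
    }
    if (is.null(dwell_weights) || length(dwell_weights) != length(dwell_rates)) {
      stop("'dwell_weights' must match 'dwell_rates' in length")
    }
    if (abs(sum(dwell_weights) - 1) > 1e-9) {
      stop("dwell mixture weights must sum to 1")
    }
  }
  if (any(dwell_rates < 0)) stop("all rates must be >= 0")
  if (!is.null(gate)) {
    if (length(gate) < 2L || any(gate[1:2] < 0)) {
      stop("'gate' must be c(on_rate, off_rate) with non-negative rates")
    }
    if (length(gate) < 3L) gate <- c(gate[1:2], 1)
  }
  structure(
    list(binding_rate_constant = binding_rate_constant,
         probe_concentration = probe_concentration,
         pseudo_first_order_rate = binding_rate_constant * probe_concentration,
         dwell_rates = dwell_rates,
         dwell_weights = dwell_weights,
         fret_efficiency = fret_efficiency,
         gate = gate),
    class = "reporter_kinetics")
}

#' Built-in reporter presets
#'
#' Kinetic presets for the reporters used throughout the package examples:
#' short DNA probes against three 16S rRNA 3'-domain sites (`H30`, `H32`,
#' `H2829`) at 200 nM, and ribosomal protein `S7` at 20 nM. Probe presets
#' reproduce median arrival times of 3.2, 11.5 and 10.2 s and median bound
#' lifetimes of 1.6, 5.7 and 11.5 s (H30, H32, H2829); the S7 preset has a
#' ~12-s median arrival and a two-phase bound dwell (means ~1 s and ~15 s).
#'
#' @param name Preset name: `"H30"`, `"H32"`, `"H2829"` or `"S7"`.
#' @param ... Overrides passed on to [reporter_kinetics()].
#' @return A `reporter_kinetics` object.
#' @export
reporter_preset <- function(name, ...) {
  presets <- list(
    # kon chosen so that kon * c reproduces the reference median arrival
    # times at 200 nM probe: rate = ln(2) / median.
    H30   = list(binding_rate_constant = 1.083e6, probe_concentration = 200e-9,
                 unbinding_rate = 0.433),
    H32   = list(binding_rate_constant = 3.014e5, probe_concentration = 200e-9,
                 unbinding_rate = log(2) / 5.7),
    H2829 = list(binding_rate_constant = 3.398e5, probe_concentration = 200e-9,
                 unbinding_rate = log(2) / 11.5),
    S7    = list(binding_rate_constant = 2.9e6, probe_concentration = 20e-9,
                 dwell_rates = c(1, 1 / 15), dwell_weights = c(0.5, 0.5))
  )
  if (!name %in% names(presets)) {
    stop("unknown reporter preset: ", name)
  }
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(reporter_kinetics, args)
}

# 5'->3' target positions used for canonical class-label ordering.
.reporter_positions <- c(H2829 = 933, H30 = 950, H32 = 986)

#' Canonical reporter ordering
#'
#' Orders reporter names for class labels: the protein readout (S7) first,
#' then probes 5' to 3' by target position on the rRNA; unknown reporters
#' keep their input order after the known ones.
#'
#' @param reporters Character vector of reporter names.
#' @return Reordered character vector.
#' @export
canonical_reporter_order <- function(reporters) {
  is_s7 <- reporters == "S7"
  rest <- reporters[!is_s7]
  pos <- .reporter_positions[rest]
  known <- rest[!is.na(pos)][order(pos[!is.na(pos)])]
  c(reporters[is_s7], known, rest[is.na(pos)])
}

#' Parse a folding-class label
#'
#' Class labels are strings such as `"S7+/H30-"`: reporter names each
#' followed by `+` (at least one binding event possible) or `-`
#' (binding-incompetent at that site), joined by `/`.
#'
#' @param label Class label string.
#' @return Named logical vector (`TRUE` for `+`) keyed by reporter.
#' @export
parse_class_label <- function(label) {
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  sign <- substring(parts, nchar(parts))
  if (!all(sign %in% c("+", "-"))) {
    stop("malformed class label: ", label)
  }
  stats::setNames(sign == "+", substring(parts, 1, nchar(parts) - 1))
}

#' Build a canonical class label from per-reporter signs
#'
#' @param signs Named logical vector (`TRUE` = `+`), keyed by reporter.
#' @return Class label string in canonical reporter order.
#' @export
make_class_label <- function(signs) {
  ord <- canonical_reporter_order(names(signs))
  paste0(ord, ifelse(signs[ord], "+", "-"), collapse = "/")
}

#' Simulation configuration
#'
#' Assembles and validates the full configuration of the multicolor trace
#' simulator. Defaults emulate the cotranscriptional probing experiment:
#' 100-ms frames, 600-s traces, a 10-s laser dead time starting at 15 s
#' (during which the reaction mix is injected), a transcription reporter
#' rising exponentially until template dissociation (log-normal residence,
#' median 50 s), deliberate donor photobleaching near the end of the
#' acquisition, 10% spectral crosstalk into the next redder channel, and
#' additive Gaussian camera noise.
#'
#' @param n_molecules Number of molecules to simulate.
#' @param reporters Named list of [reporter_kinetics()] objects. Names are the
#'   reporter names used in class labels and event tables.
#' @param class_probabilities Named numeric vector of folding-class
#'   probabilities; names are class labels over exactly the configured
#'   reporters (see [parse_class_label()]). Must sum to 1.
#' @param mode `"cotranscriptional"` (transcription channel present) or
#'   `"immobilized_rna"`.
#' @param frame_period Camera integration time, seconds.
#' @param duration Trace length, seconds.
#' @param exclusivity_pairs List of length-2 character vectors; the two
#'   reporters of a pair can never be bound concurrently (binding of one is
#'   blocked while the other is bound).
#' @param transcription List: `peak` (AU at dissociation), `rise_time_constant`
#'   (s), `dissociation_median` (s, log-normal median of template residence
#'   after reinitiation), `dissociation_sdlog`, `max_allowed_dissociation`
#'   (s; selection rule, recorded in metadata).
#' @param photophysics List: `donor_baseline` (AU), `background` (AU, added to
#'   every channel), `noise_sd` (AU), `crosstalk` (`"default"` for 10% leak
#'   into the next redder channel, `"identity"`, or an explicit row-stochastic
#'   matrix over the rendered channels).
#' @param bleach List: `donor_mean` (s, spontaneous exponential donor bleach),
#'   `forced_window` (fractions of `duration`; deliberate bleaching induced by
#'   the final low-quencher injection occurs uniformly in this window),
#'   `acceptor_mean`, `transcription_mean` (s, `Inf` = no bleaching; transient
#'   probes exchange so acceptor bleaching is off by default).
#' @param dead_time Numeric `c(start, length)` in seconds; all channels read
#'   zero while the lasers are off.
#' @param t0 Reagent-delivery time, seconds; reference for arrival times and
#'   binding processes. Default: end of the dead time.
#' @param nonspecific List describing optional acceptor-only sticking
#'   artifacts (no donor anticorrelation): `rate` (s^-1 per molecule,
#'   default 0), `mean_duration` (s), `amplitude` (AU), `channel` (acceptor
#'   channel index).
#' @param seed Master seed; molecule `i` uses a substream derived from
#'   `(seed, i)` so ensembles are reproducible molecule-by-molecule.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_molecules,
                       reporters,
                       class_probabilities = NULL,
                       mode = c("cotranscriptional", "immobilized_rna"),
                       frame_period = 0.1,
                       duration = 600,
                       exclusivity_pairs = list(),
                       transcription = list(),
                       photophysics = list(),
                       bleach = list(),
                       dead_time = c(start = 15, length = 10),
                       t0 = NULL,
                       nonspecific = list(),
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_molecules >= 1, frame_period > 0)
  if (is.null(names(reporters)) || any(!nzchar(names(reporters)))) {
    stop("'reporters' must be a named list")
  }
  if (!all(vapply(reporters, inherits, logical(1), "reporter_kinetics"))) {
    stop("every reporter must be a reporter_kinetics() object")
  }
  rn <- names(reporters)

  if (is.null(class_probabilities)) {
    class_probabilities <- stats::setNames(
      1, paste0(rn, "+", collapse = "/"))
  }
  if (abs(sum(class_probabilities) - 1) > 1e-9) {
    stop("class probabilities must sum to 1")
  }
  for (lab in names(class_probabilities)) {
    signs <- parse_class_label(lab)
    if (!setequal(names(signs), rn)) {
      stop("class label '", lab,
           "' does not cover exactly the configured reporters")
    }
  }
  for (pair in exclusivity_pairs) {
    if (length(pair) != 2L || !all(pair %in% rn)) {
      stop("exclusivity pair references an unknown reporter: ",
           paste(pair, collapse = ", "))
    }
  }

  transcription <- utils::modifyList(
    list(peak = 800, rise_time_constant = 25, dissociation_median = 50,
         dissociation_sdlog = 0.8, max_allowed_dissociation = 200),
    transcription)
  photophysics <- utils::modifyList(
    list(donor_baseline = 1000, background = 50, noise_sd = 30,
         crosstalk = "default"),
    photophysics)
  bleach <- utils::modifyList(
    list(donor_mean = 6000, forced_window = c(0.985, 0.998),
         acceptor_mean = Inf, transcription_mean = Inf),
    bleach)
  nonspecific <- utils::modifyList(
    list(rate = 0, mean_duration = 0.5, amplitude = 600, channel = 1L),
    nonspecific)

  dead_time <- as.numeric(dead_time)
  if (length(dead_time) != 2L || any(dead_time < 0)) {
    stop("'dead_time' must be c(start, length) >= 0")
  }
  if (duration < dead_time[1] + dead_time[2]) {
    stop("duration must cover the dead-time window")
  }
  if (is.null(t0)) t0 <- dead_time[1] + dead_time[2]
  stopifnot(t0 >= 0, t0 < duration)

  structure(
    list(n_molecules = as.integer(n_molecules),
         reporters = reporters,
         class_probabilities = class_probabilities,
         mode = mode,
         frame_period = frame_period,
         duration = duration,
         exclusivity_pairs = exclusivity_pairs,
         transcription = transcription,
         photophysics = photophysics,
         bleach = bleach,
         dead_time = c(start = dead_time[1], length = dead_time[2]),
         t0 = t0,
         nonspecific = nonspecific,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Trace simulation config:", x$n_molecules, "molecules,",
      x$duration, "s at", x$frame_period, "s/frame,", x$mode, "\n")
  cat("  reporters:", paste(names(x$reporters), collapse = ", "), "\n")
  cat("  classes:",
      paste(sprintf("%s (%.3g)", names(x$class_probabilities),
                    x$class_probabilities), collapse = ", "), "\n")
  invisible(x)
}

# Channel layout for a config, in spectral (blue -> red) order.
sim_channels <- function(config) {
  k <- length(config$reporters)
  acc <- paste0("acceptor_", seq_len(k))
  if (config$mode == "cotranscriptional") {
    c("donor", "transcription", acc)
  } else {
    c("donor", acc)
  }
}

# Row-stochastic crosstalk matrix over the rendered channels.
crosstalk_matrix <- function(config, leak = 0.1) {
  ch <- sim_channels(config)
  spec <- config$photophysics$crosstalk
  if (is.matrix(spec)) {
    if (!all(dim(spec) == length(ch))) {
      stop("crosstalk matrix must be ", length(ch), "x", length(ch))
    }
    return(spec)
  }
  C <- diag(length(ch))
  if (identical(spec, "default")) {
    for (i in seq_len(length(ch) - 1L)) {
      C[i, i] <- 1 - leak
      C[i, i + 1L] <- leak
    }
  } else if (!identical(spec, "identity")) {
    stop("crosstalk must be 'default', 'identity' or a matrix")
  }
  dimnames(C) <- list(ch, ch)
  C
}

# Deterministic per-molecule substream seed from (master, i).
molecule_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 16807) %% 2147483647)
}
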