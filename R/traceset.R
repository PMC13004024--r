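#' Multichannel trace container
#'
#' A `trace_set` holds per-molecule, per-frame fluorescence intensities for a
#' single experiment: one matrix per molecule (frames x channels, channels
#' among `donor`, `transcription`, `acceptor_1..acceptor_3`), the camera frame
#' period, and the experiment metadata (channel-to-reporter map, probe
#' concentrations, reagent injection time, laser dead-time window).
#'
#' Frame `f` (0-based) covers time `[f * frame_period, (f + 1) * frame_period)`.
#'
#' @param traces Named list of numeric matrices with identical column sets;
#'   all channels of one molecule must have equal length.
#' @param frame_period Frame integration time in seconds (> 0).
#' @param metadata List with at least `channel_reporters` (named character,
#'   e.g. `c(acceptor_1 = "H30")`) covering every acceptor channel present;
#'   typically also `probe_concentrations`, `injection_time`, `dead_time`,
#'   `mode` and `schema_version`.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, frame_period, metadata = list()) {
  stopifnot(is.list(traces), is.numeric(frame_period), frame_period > 0)
  if (length(traces)) {
    if (is.null(names(traces)) || anyDuplicated(names(traces))) {
      stop("traces must be uniquely named by molecule id")
    }
    for (id in names(traces)) {
      m <- traces[[id]]
      if (!is.matrix(m) || is.null(colnames(m))) {
        stop("trace '", id, "' must be a matrix with channel column names")
      }
    }
    ch <- colnames(traces[[1]])
    same <- vapply(traces, function(m) identical(colnames(m), ch), logical(1))
    if (!all(same)) stop("all molecules must share the same channel set")
    acc <- grep("^acceptor_", ch, value = TRUE)
    covered <- acc %in% names(metadata$channel_reporters)
    if (!all(covered)) {
      stop("metadata$channel_reporters must cover every acceptor channel")
    }
  }
  if (is.null(metadata$schema_version)) metadata$schema_version <- 1L
  structure(list(traces = traces, frame_period = frame_period,
                 metadata = metadata),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  nf <- if (length(x$traces)) nrow(x$traces[[1]]) else 0L
  cat("trace_set:", length(x$traces), "molecules,", nf, "frames at",
      x$frame_period, "s/frame\n")
  if (length(x$traces)) {
    cat("  channels:", paste(colnames(x$traces[[1]]), collapse = ", "), "\n")
  }
  rep_map <- x$metadata$channel_reporters
  if (length(rep_map)) {
    cat("  reporters:",
        paste(sprintf("%s=%s", names(rep_map), rep_map), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.trace_set <- function(x) length(x$traces)

#' Molecule identifiers of a trace set
#' @param traces A `trace_set`.
#' @return Character vector of molecule ids.
#' @export
molecule_ids <- function(traces) names(traces$traces)

#' Subset a trace set by molecule
#' @param x A `trace_set`.
#' @param i Molecule ids or indices.
#' @param ... Unused.
#' @return A `trace_set` with the selected molecules.
#' @export
`[.trace_set` <- function(x, i, ...) {
  trace_set(x$traces[i], x$frame_period, x$metadata)
}

# Acceptor channel name of a reporter (inverse of channel_reporters).
reporter_channel <- function(traces, reporter) {
  map <- traces$metadata$channel_reporters
  ch <- names(map)[map == reporter]
  if (length(ch) != 1L) {
    stop("reporter '", reporter, "' is not mapped to a channel")
  }
  ch
}

# Frame times (left edges) for a trace set.
frame_times <- function(traces, n_frames) {
  (seq_len(n_frames) - 1L) * traces$frame_period
}

empty_events <- function() {
  data.frame(molecule_id = character(), reporter = character(),
             t_start = numeric(), t_end = numeric(),
             left_censored = logical(), right_censored = logical(),
             stringsAsFactors = FALSE)
}

#' Validate and canonicalize an event table
#'
#' An event table has one row per binding event: `molecule_id`, `reporter`,
#' `t_start`/`t_end` (seconds, half-open interval), and `left_censored` /
#' `right_censored` flags. Rows are sorted by molecule, reporter and start
#' time; intervals must be strictly positive and non-overlapping within one
#' molecule/reporter.
#'
#' @param events Event table `data.frame`.
#' @return The sorted, validated `data.frame`.
#' @export
validate_events <- function(events) {
  need <- c("molecule_id", "reporter", "t_start", "t_end",
            "left_censored", "right_censored")
  if (!all(need %in% names(events))) {
    stop("event table must have columns: ", paste(need, collapse = ", "))
  }
  events <- events[, need, drop = FALSE]
  if (nrow(events) == 0L) return(empty_events())
  if (any(events$t_end <= events$t_start)) {
    stop("event intervals must satisfy t_end > t_start")
  }
  o <- order(events$molecule_id, events$reporter, events$t_start)
  events <- events[o, , drop = FALSE]
  same <- events$molecule_id[-1] == events$molecule_id[-nrow(events)] &
    events$reporter[-1] == events$reporter[-nrow(events)]
  if (any(same & events$t_start[-1] < events$t_end[-nrow(events)] - 1e-9)) {
    stop("overlapping events within one molecule/reporter")
  }
  rownames(events) <- NULL
  events
}
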