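#' Write and read trace sets
#'
#' One experiment is stored as one directory: per-frame intensities in a
#' single wide TSV (`traces.tsv`: a `time_s` column plus one column per
#' molecule x channel, named `<molecule>.<channel>`) and a JSON metadata
#' sidecar (`metadata.json`) carrying the frame period, the channel-to-
#' reporter map and a `schema_version` field. The round trip is lossless:
#' times are written with enough digits to restore intensities bit-exactly.
#'
#' @param traces A [trace_set()].
#' @param path Directory to create/populate (for `write_traces`) or read.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns a
#'   `trace_set`.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- traces$metadata
  # named vectors must serialize as JSON objects, not unboxed scalars
  for (f in c("channel_reporters", "probe_concentrations")) {
    if (!is.null(meta[[f]])) meta[[f]] <- as.list(meta[[f]])
  }
  meta$frame_period <- traces$frame_period
  meta$molecule_ids <- as.list(molecule_ids(traces))
  meta$channels <- if (length(traces$traces))
    as.list(colnames(traces$traces[[1]])) else list()
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(traces$traces)) {
    n <- nrow(traces$traces[[1]])
    cols <- c(list(time_s = frame_times(traces, n)),
              unlist(lapply(molecule_ids(traces), function(id) {
                m <- traces$traces[[id]]
                stats::setNames(lapply(seq_len(ncol(m)), function(j) m[, j]),
                                paste0(id, ".", colnames(m)))
              }), recursive = FALSE))
    df <- as.data.frame(cols, check.names = FALSE)
  } else {
    df <- data.frame(time_s = numeric())
  }
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     file.path(path, "traces.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(meta_file)) {
    stop("format error: missing metadata sidecar in ", path)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L) {
    stop("format error: unknown schema version")
  }
  frame_period <- meta$frame_period
  ids <- as.character(meta$molecule_ids)
  channels <- as.character(meta$channels)
  df <- utils::read.table(file.path(path, "traces.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE)
  traces <- stats::setNames(lapply(ids, function(id) {
    want <- paste0(id, ".", channels)
    if (!all(want %in% names(df))) {
      stop("format error: missing channel columns for molecule ", id)
    }
    m <- as.matrix(df[, want, drop = FALSE])
    colnames(m) <- channels
    m
  }), ids)
  meta$frame_period <- NULL
  meta$molecule_ids <- NULL
  meta$channels <- NULL
  if (!is.null(meta$channel_reporters)) {
    meta$channel_reporters <- unlist(meta$channel_reporters)
  }
  if (!is.null(meta$probe_concentrations)) {
    meta$probe_concentrations <- unlist(meta$probe_concentrations)
  }
  trace_set(traces, frame_period = frame_period, metadata = meta)
}

#' Write and read event tables
#'
#' Events are stored as TSV with a mandatory header and columns
#' `molecule_id`, `reporter`, `t_start_s`, `t_end_s`, `left_censored`,
#' `right_censored`; times are in seconds with at least millisecond
#' precision, intervals half-open. Tables are canonicalized (sorted,
#' validated) on both write and read.
#'
#' @param events Event table (see [validate_events()]).
#' @param path TSV file path.
#' @return `write_events` returns `path` invisibly; `read_events` the table.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  out <- data.frame(molecule_id = events$molecule_id,
                    reporter = events$reporter,
                    t_start_s = sprintf("%.6f", events$t_start),
                    t_end_s = sprintf("%.6f", events$t_end),
                    left_censored = events$left_censored,
                    right_censored = events$right_censored)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric",
                                         "numeric", "logical", "logical"))
  names(df) <- sub("_s$", "", names(df))
  validate_events(df)
}
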