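#' FRET efficiency from apparent intensities
#'
#' `E = I_A / (I_A + I_D)`, the apparent FRET efficiency between the shared
#' donor and one acceptor reporter. Frames where the summed intensity falls
#' below `floor` (e.g. laser dead time, post-bleach) are flagged missing
#' (`NA`) rather than producing unstable ratios.
#'
#' @param i_a,i_d Apparent acceptor / donor intensity vectors (AU).
#' @param floor Minimum `i_a + i_d` for E to be defined.
#' @return Numeric vector of efficiencies with `NA` for missing frames.
#' @export
compute_fret <- function(i_a, i_d, floor = 0) {
  tot <- i_a + i_d
  e <- ifelse(tot >= floor & tot > 0, i_a / tot, NA_real_)
  e[!is.finite(i_a) | !is.finite(i_d)] <- NA_real_
  e
}

#' Estimate the two FRET states and the midpoint threshold
#'
#' Fits a two-component location model (1-D k-means with deterministic
#' quantile initialization) to FRET efficiencies pooled over molecules and
#' places the bound/unbound threshold at the midpoint of the two state means.
#' If the pool is effectively unimodal (component means closer than
#' `min_separation`) the configured fallback threshold is returned with a
#' warning.
#'
#' @param e Pooled FRET efficiencies (NAs dropped). At least 100 defined
#'   values are required.
#' @param min_separation Minimum distance between state means.
#' @param fallback Threshold used when the two states cannot be resolved.
#' @return List with `low_mean`, `high_mean`, `threshold`, `separated`.
#' @export
estimate_fret_states <- function(e, min_separation = 0.15, fallback = 0.5) {
  e <- e[!is.na(e)]
  if (length(e) < 100L) {
    stop("need at least 100 defined FRET values to estimate states")
  }
  # high quantile far out so sparsely-bound pools still seed the high state
  centers <- stats::quantile(e, c(0.1, 0.998), names = FALSE)
  if (diff(centers) < 1e-8) {
    warning("FRET pool is unimodal; using fallback threshold ", fallback)
    return(list(low_mean = mean(e), high_mean = mean(e),
                threshold = fallback, separated = FALSE))
  }
  km <- stats::kmeans(e, centers = matrix(centers, ncol = 1))
  mu <- unname(sort(km$centers[, 1]))
  if (diff(mu) < min_separation) {
    warning("FRET states closer than ", min_separation,
            "; using fallback threshold ", fallback)
    return(list(low_mean = mu[1], high_mean = mu[2],
                threshold = fallback, separated = FALSE))
  }
  list(low_mean = mu[1], high_mean = mu[2],
       threshold = mean(mu), separated = TRUE)
}

#' Donor-acceptor anticorrelation check for one candidate event
#'
#' Distinguishes genuine FRET binding events from fluorophore sticking: a
#' real event takes intensity out of the donor and puts it into the acceptor,
#' so the donor must dip while the acceptor rises (dip at least
#' `min_drop_ratio` of the rise) and the two channels must be negatively
#' correlated over the event extended by `margin_frames` on each side.
#' Candidates shorter than 2 frames are rejected outright.
#'
#' @param donor,acceptor Intensity vectors (full trace).
#' @param start_frame,end_frame First/last frame of the candidate (1-based,
#'   inclusive).
#' @param margin_frames Frames of context on each side.
#' @param cor_threshold Maximum allowed donor/acceptor correlation.
#' @param min_drop_ratio Minimum donor-dip : acceptor-rise ratio.
#' @param min_rise_sd Minimum significance of the acceptor rise, in standard
#'   errors of the in/out mean difference at the channel's frame-to-frame
#'   noise; suppresses noise excursions over spectral-crosstalk shelves.
#' @return `TRUE` for an anticorrelated (genuine) event.
#' @export
anticorrelation_check <- function(donor, acceptor, start_frame, end_frame,
                                  margin_frames = 5L, cor_threshold = -0.3,
                                  min_drop_ratio = 0.3, min_rise_sd = 5) {
  n <- length(donor)
  if (end_frame - start_frame + 1L < 2L) return(FALSE)
  lo <- max(1L, start_frame - margin_frames)
  hi <- min(n, end_frame + margin_frames)
  inside <- start_frame:end_frame
  outside <- setdiff(lo:hi, inside)
  outside <- outside[!is.na(donor[outside]) & !is.na(acceptor[outside])]
  inside <- inside[!is.na(donor[inside]) & !is.na(acceptor[inside])]
  if (!length(outside) || !length(inside)) return(FALSE)
  rise <- mean(acceptor[inside]) - mean(acceptor[outside])
  drop <- mean(donor[outside]) - mean(donor[inside])
  if (rise <= 0 || drop < min_drop_ratio * rise) return(FALSE)
  sigma <- noise_scale(acceptor[!is.na(acceptor)])
  if (sigma > 0) {
    se <- sigma * sqrt(1 / length(inside) + 1 / length(outside))
    if (rise < min_rise_sd * se) return(FALSE)
  }
  win <- lo:hi
  ok <- !is.na(donor[win]) & !is.na(acceptor[win])
  d <- donor[win][ok]; a <- acceptor[win][ok]
  if (stats::sd(d) == 0 || stats::sd(a) == 0) return(TRUE)
  stats::cor(d, a) <= cor_threshold
}

#' Frame-wise bound/unbound state assignment
#'
#' Assigns each frame to `bound` (E at or above the midpoint threshold),
#' `unbound`, or `missing`. Missing runs shorter than `missing_gap_frames`
#' flanked by the same state are bridged so they interrupt neither bound nor
#' unbound runs. When donor and acceptor traces are supplied, every candidate
#' bound run is screened by [anticorrelation_check()] and failing runs are
#' reassigned to `unbound`.
#'
#' @param e FRET efficiency vector (NA = missing).
#' @param threshold Bound/unbound threshold in (0, 1).
#' @param donor,acceptor Optional raw intensity vectors for the
#'   anticorrelation filter.
#' @param params [pipeline_params()] list.
#' @return Character vector of states (`"bound"`, `"unbound"`, `"missing"`).
#' @export
assign_states <- function(e, threshold, donor = NULL, acceptor = NULL,
                          params = pipeline_params()) {
  stopifnot(threshold > 0, threshold < 1)
  st <- ifelse(is.na(e), "missing",
               ifelse(e >= threshold, "bound", "unbound"))
  st <- bridge_missing(st, params$missing_gap_frames)
  ac <- params$anticorrelation
  if (ac$enabled && !is.null(donor) && !is.null(acceptor)) {
    # frames with undefined FRET (dead time, post-bleach) carry no donor /
    # acceptor information; mask them so they cannot corrupt the filter
    donor[is.na(e)] <- NA_real_
    acceptor[is.na(e)] <- NA_real_
    runs <- state_runs(st, "bound")
    for (i in seq_len(nrow(runs))) {
      ok <- anticorrelation_check(donor, acceptor, runs$start[i], runs$end[i],
                                  margin_frames = ac$margin_frames,
                                  cor_threshold = ac$cor_threshold,
                                  min_drop_ratio = ac$min_drop_ratio,
                                  min_rise_sd = ac$min_rise_sd)
      if (!ok) st[runs$start[i]:runs$end[i]] <- "unbound"
    }
  }
  st
}

# Reassign missing runs shorter than max_gap to the flanking state when both
# flanks agree; runs at the trace edges or between differing states stay
# missing.
bridge_missing <- function(st, max_gap) {
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] != "missing" || r$lengths[i] >= max_gap) next
    if (i == 1L || i == length(r$values)) next
    if (r$values[i - 1L] == r$values[i + 1L]) {
      st[starts[i]:ends[i]] <- r$values[i - 1L]
    }
  }
  st
}

# Maximal runs of one state: data.frame(start, end) of 1-based frame indices.
state_runs <- function(st, value) {
  r <- rle(st == value)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Extract binding events from a state series
#'
#' Maximal bound runs become events: runs separated by gaps of at most
#' `max_gap_frames` are merged, runs shorter than `min_event_frames` are
#' dropped, and events whose edges touch the trace start/end or a missing
#' block (laser dead time, donor bleach) receive censoring flags.
#'
#' @param states Character state vector from [assign_states()].
#' @param molecule_id,reporter Identifiers for the output rows.
#' @param frame_period Seconds per frame.
#' @param params [pipeline_params()] list.
#' @return Event-table `data.frame` (see [validate_events()]).
#' @export
extract_events <- function(states, molecule_id, reporter, frame_period,
                           params = pipeline_params()) {
  runs <- state_runs(states, "bound")
  if (nrow(runs) == 0L) return(empty_events())
  # merge across short gaps
  if (nrow(runs) > 1L) {
    gap <- runs$start[-1] - runs$end[-nrow(runs)] - 1L
    grp <- cumsum(c(TRUE, gap > params$max_gap_frames))
    runs <- data.frame(start = tapply(runs$start, grp, min),
                       end = tapply(runs$end, grp, max))
  }
  runs <- runs[runs$end - runs$start + 1L >= params$min_event_frames, ,
               drop = FALSE]
  if (nrow(runs) == 0L) return(empty_events())
  n <- length(states)
  edge_missing <- function(i) i < 1L || i > n || states[i] == "missing"
  out <- data.frame(
    molecule_id = molecule_id,
    reporter = reporter,
    t_start = (runs$start - 1L) * frame_period,
    t_end = runs$end * frame_period,
    left_censored = vapply(runs$start - 1L, edge_missing, logical(1)),
    right_censored = vapply(runs$end + 1L, edge_missing, logical(1)),
    stringsAsFactors = FALSE)
  validate_events(out)
}

#' Detect binding events across a trace set
#'
#' Full event-detection stage: computes per-reporter FRET efficiencies
#' against the shared donor, estimates the two FRET states and midpoint
#' threshold per reporter by pooling frames over the selected molecules,
#' assigns frame states with anticorrelation screening, and extracts the
#' event table. Frames after the donor photobleach and during the laser dead
#' time are treated as missing. Each acceptor is evaluated independently, so
#' concurrent occupancy of several reporters is detectable.
#'
#' @param traces A [trace_set()].
#' @param annotations Output of [select_molecules()]; only selected molecules
#'   are processed.
#' @param params [pipeline_params()] list.
#' @param threshold_override Optional named numeric vector of per-reporter
#'   thresholds that bypasses estimation, e.g. `c(H30 = 0.45)`.
#' @return List with `events` (event table) and `thresholds` (per-reporter
#'   state estimates).
#' @export
detect_events <- function(traces, annotations, params = pipeline_params(),
                          threshold_override = NULL) {
  stopifnot(inherits(traces, "trace_set"))
  ids <- annotations$molecule_id[annotations$selected]
  rep_map <- traces$metadata$channel_reporters
  reporters <- unname(rep_map)
  dead <- traces$metadata$dead_time
  if (is.null(dead)) dead <- c(0, 0)
  if (!length(ids)) {
    return(list(events = empty_events(), thresholds = list()))
  }
  n_frames <- nrow(traces$traces[[1]])
  dt <- traces$frame_period
  dead_mask <- dead_frames(n_frames, dt, dead)

  # per molecule x reporter FRET series (shared across threshold + detection)
  fret <- lapply(ids, function(id) {
    tr <- traces$traces[[id]]
    tb <- annotations$donor_bleach_time[annotations$molecule_id == id]
    live <- !dead_mask
    if (!is.na(tb)) live <- live & (seq_len(n_frames) - 1L) * dt < tb
    lapply(stats::setNames(names(rep_map), unname(rep_map)), function(ch) {
      tot <- tr[, ch] + tr[, "donor"]
      floor <- params$floor_frac * stats::median(tot[live])
      e <- compute_fret(tr[, ch], tr[, "donor"], floor = floor)
      e[!live] <- NA_real_
      e
    })
  })
  names(fret) <- ids

  thresholds <- lapply(stats::setNames(reporters, reporters), function(r) {
    if (!is.null(threshold_override) && r %in% names(threshold_override)) {
      th <- threshold_override[[r]]
      return(list(low_mean = NA_real_, high_mean = NA_real_,
                  threshold = th, separated = NA))
    }
    pool <- unlist(lapply(fret, `[[`, r), use.names = FALSE)
    pool <- pool[!is.na(pool)]
    if (length(pool) > params$pool_max_values) {
      stride <- ceiling(length(pool) / params$pool_max_values)
      pool <- pool[seq(1L, length(pool), by = stride)]
    }
    estimate_fret_states(pool, min_separation = params$min_separation,
                         fallback = params$default_threshold)
  })

  ev <- lapply(ids, function(id) {
    tr <- traces$traces[[id]]
    per_rep <- lapply(reporters, function(r) {
      ch <- names(rep_map)[rep_map == r]
      st <- assign_states(fret[[id]][[r]], thresholds[[r]]$threshold,
                          donor = tr[, "donor"], acceptor = tr[, ch],
                          params = params)
      extract_events(st, id, r, dt, params = params)
    })
    do.call(rbind, per_rep)
  })
  events <- do.call(rbind, ev)
  if (is.null(events) || nrow(events) == 0L) events <- empty_events()
  list(events = validate_events(events), thresholds = thresholds)
}
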