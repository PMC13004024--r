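#' Simulate a multicolor single-molecule trace ensemble
#'
#' Generates per-frame intensity traces with known ground truth, emulating a
#' cotranscriptional RNA accessibility probing experiment. Per molecule: a
#' folding class is drawn from `class_probabilities`; each reporter marked `+`
#' binds as a continuous-time alternating renewal process (pseudo-first-order
#' binding, exponential or mixture-of-exponentials dwells), optionally gated
#' by a two-state accessibility switch and blocked while an exclusive partner
#' is bound. Channels are rendered physically: the shared donor is quenched by
#' the bound acceptors (multi-acceptor FRET competition), occupancy is
#' integrated within each camera frame, the transcription reporter rises
#' exponentially until template dissociation then drops to background in one
#' frame, FRET signal is truncated at the donor photobleach, spectral
#' crosstalk mixes neighboring channels, Gaussian read noise is added, and all
#' channels read zero during the laser dead time.
#'
#' Simulation is deterministic for a fixed seed; molecule `i` uses a substream
#' seeded from `(seed, i)`, so individual molecules are reproducible
#' regardless of ensemble size.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `traces` (a [trace_set()]) and `truth`
#'   (a `sim_truth` object; see [truth_event_table()]).
#' @export
simulate_ensemble <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_molecules
  ids <- sprintf("mol_%04d", seq_len(n))
  channels <- sim_channels(config)
  C <- crosstalk_matrix(config)
  n_frames <- round(config$duration / config$frame_period)
  boundaries <- seq(0, by = config$frame_period, length.out = n_frames + 1L)

  labels <- names(config$class_probabilities)
  cum_p <- cumsum(config$class_probabilities)
  sign_table <- lapply(labels, parse_class_label)

  traces <- vector("list", n)
  classes <- character(n)
  diss <- rep(NA_real_, n)
  donor_bleach <- numeric(n)
  ev_list <- vector("list", n)
  art_list <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(molecule_seed(config$seed, i))
    cls <- findInterval(stats::runif(1), cum_p, left.open = TRUE) + 1L
    classes[i] <- labels[cls]
    signs <- sign_table[[cls]]

    # lifetime draws
    tb_donor <- min(stats::rexp(1, 1 / config$bleach$donor_mean),
                    config$duration *
                      stats::runif(1, config$bleach$forced_window[1],
                                   config$bleach$forced_window[2]))
    donor_bleach[i] <- tb_donor
    td <- NA_real_
    if (config$mode == "cotranscriptional") {
      td <- config$t0 + stats::rlnorm(
        1, meanlog = log(config$transcription$dissociation_median),
        sdlog = config$transcription$dissociation_sdlog)
      diss[i] <- td
    }

    events <- simulate_binding(config, signs)
    ev_list[[i]] <- events

    arts <- simulate_artifacts(config)
    art_list[i] <- list(arts)

    traces[[i]] <- render_molecule(config, events, td, tb_donor, arts,
                                   channels, C, boundaries)
  }
  names(traces) <- ids

  events_df <- do.call(rbind, lapply(seq_len(n), function(i) {
    ev <- ev_list[[i]]
    if (nrow(ev) == 0L) return(NULL)
    cbind(data.frame(molecule_id = ids[i], stringsAsFactors = FALSE), ev)
  }))
  if (is.null(events_df)) {
    events_df <- data.frame(molecule_id = character(), reporter = character(),
                            t_start = numeric(), t_end = numeric(),
                            stringsAsFactors = FALSE)
  }
  artifacts_df <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- art_list[[i]]
    if (is.null(a) || nrow(a) == 0L) return(NULL)
    cbind(data.frame(molecule_id = ids[i], stringsAsFactors = FALSE), a)
  }))

  reporters <- names(config$reporters)
  metadata <- list(
    schema_version = 1L,
    mode = config$mode,
    channel_reporters = stats::setNames(
      reporters, paste0("acceptor_", seq_along(reporters))),
    probe_concentrations = stats::setNames(
      vapply(config$reporters, `[[`, numeric(1), "probe_concentration"),
      reporters),
    injection_time = config$t0,
    dead_time = unname(config$dead_time),
    seed = config$seed)

  ts <- trace_set(traces, frame_period = config$frame_period,
                  metadata = metadata)
  truth <- structure(
    list(classes = data.frame(molecule_id = ids, class_label = classes,
                              stringsAsFactors = FALSE),
         events = events_df,
         times = data.frame(molecule_id = ids,
                            dissociation_time = diss,
                            donor_bleach_time = donor_bleach,
                            stringsAsFactors = FALSE),
         artifacts = artifacts_df,
         duration = config$duration,
         t0 = config$t0,
         frame_period = config$frame_period),
    class = "sim_truth")
  list(traces = ts, truth = truth)
}

# True binding intervals for one molecule: data.frame(reporter, t_start, t_end)
# on [t0, duration), sorted, non-overlapping per reporter.
simulate_binding <- function(config, signs) {
  active <- names(signs)[signs & vapply(
    names(signs), function(r) config$reporters[[r]]$pseudo_first_order_rate > 0,
    logical(1))]
  out <- list()
  if (length(active)) {
    excl <- Filter(function(p) all(p %in% active), config$exclusivity_pairs)
    gated <- vapply(active, function(r) !is.null(config$reporters[[r]]$gate),
                    logical(1))
    joint <- unique(unlist(excl))
    solo <- setdiff(active, joint)
    for (r in solo[!gated[match(solo, active)]]) {
      out[[r]] <- renewal_intervals(config$reporters[[r]], config$t0,
                                    config$duration)
    }
    hard <- c(intersect(solo, active[gated]), joint)
    if (length(hard)) {
      out <- c(out, gillespie_intervals(config, hard, excl))
    }
  }
  if (!length(out)) {
    return(data.frame(reporter = character(), t_start = numeric(),
                      t_end = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(names(out), function(r) {
    iv <- out[[r]]
    if (nrow(iv) == 0L) return(NULL)
    data.frame(reporter = r, t_start = iv[, 1], t_end = iv[, 2],
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(reporter = character(), t_start = numeric(),
                     t_end = numeric(), stringsAsFactors = FALSE)
  }
  df[order(df$reporter, df$t_start), , drop = FALSE]
}

# Vectorized alternating renewal process for an ungated, unblocked reporter.
renewal_intervals <- function(kin, t0, duration) {
  rate_on <- kin$pseudo_first_order_rate
  span <- duration - t0
  mean_cycle <- 1 / rate_on + sum(kin$dwell_weights / kin$dwell_rates)
  starts <- numeric(0); ends <- numeric(0)
  t <- t0
  repeat {
    m <- max(16L, ceiling(1.5 * (duration - t) / mean_cycle) + 8L)
    waits <- stats::rexp(m, rate_on)
    ph <- if (length(kin$dwell_rates) == 1L) rep(1L, m) else
      sample.int(length(kin$dwell_rates), m, replace = TRUE,
                 prob = kin$dwell_weights)
    dwells <- stats::rexp(m, kin$dwell_rates[ph])
    cum <- t + cumsum(as.vector(rbind(waits, dwells)))
    s <- cum[seq(1L, 2L * m, by = 2L)]
    e <- cum[seq(2L, 2L * m, by = 2L)]
    starts <- c(starts, s); ends <- c(ends, e)
    t <- ends[length(ends)]
    if (t >= duration) break
  }
  keep <- starts < duration
  starts <- starts[keep]; ends <- pmin(ends[keep], duration)
  cbind(starts, ends)
}

# Event-driven joint simulation for gated and/or mutually exclusive reporters.
gillespie_intervals <- function(config, reporters, excl_pairs) {
  k <- length(reporters)
  kin <- config$reporters[reporters]
  rate_on <- vapply(kin, `[[`, numeric(1), "pseudo_first_order_rate")
  gate <- lapply(kin, `[[`, "gate")
  has_gate <- !vapply(gate, is.null, logical(1))
  gate_on <- vapply(seq_len(k), function(j)
    if (has_gate[j]) gate[[j]][3] > 0 else TRUE, logical(1))
  partners <- lapply(reporters, function(r) {
    unique(unlist(lapply(excl_pairs, function(p) if (r %in% p) setdiff(p, r))))
  })
  partner_idx <- lapply(partners, function(p) match(p, reporters))

  bound <- rep(FALSE, k)
  off_rate <- rep(0, k)
  starts <- vector("list", k); ends <- vector("list", k)
  t <- config$t0
  repeat {
    blocked <- vapply(seq_len(k), function(j)
      any(bound[partner_idx[[j]]]), logical(1))
    r_bind <- ifelse(!bound & gate_on & !blocked, rate_on, 0)
    r_unbind <- ifelse(bound, off_rate, 0)
    r_gate <- vapply(seq_len(k), function(j) {
      if (!has_gate[j]) return(0)
      if (gate_on[j]) gate[[j]][2] else gate[[j]][1]
    }, numeric(1))
    rates <- c(r_bind, r_unbind, r_gate)
    total <- sum(rates)
    if (total <= 0) break
    t <- t + stats::rexp(1, total)
    if (t >= config$duration) break
    ev <- findInterval(stats::runif(1) * total, cumsum(rates),
                       left.open = TRUE) + 1L
    j <- (ev - 1L) %% k + 1L
    type <- (ev - 1L) %/% k + 1L
    if (type == 1L) {
      bound[j] <- TRUE
      ph <- if (length(kin[[j]]$dwell_rates) == 1L) 1L else
        sample.int(length(kin[[j]]$dwell_rates), 1L,
                   prob = kin[[j]]$dwell_weights)
      off_rate[j] <- kin[[j]]$dwell_rates[ph]
      starts[[j]] <- c(starts[[j]], t)
    } else if (type == 2L) {
      bound[j] <- FALSE
      ends[[j]] <- c(ends[[j]], t)
    } else {
      gate_on[j] <- !gate_on[j]
    }
  }
  out <- stats::setNames(vector("list", k), reporters)
  for (j in seq_len(k)) {
    s <- starts[[j]]
    e <- ends[[j]]
    if (is.null(s)) {
      out[[j]] <- cbind(starts = numeric(0), ends = numeric(0))
      next
    }
    if (length(s) > length(e)) e <- c(e, config$duration)
    out[[j]] <- cbind(starts = s, ends = e)
  }
  out
}

# Acceptor-only sticking pulses (no donor anticorrelation).
simulate_artifacts <- function(config) {
  ns <- config$nonspecific
  if (ns$rate <= 0) return(NULL)
  span <- config$duration - config$t0
  m <- stats::rpois(1, ns$rate * span)
  if (m == 0L) return(NULL)
  s <- sort(config$t0 + stats::runif(m) * span)
  e <- pmin(s + stats::rexp(m, 1 / ns$mean_duration), config$duration)
  data.frame(channel = paste0("acceptor_", ns$channel),
             t_start = s, t_end = e, stringsAsFactors = FALSE)
}

# Fractional per-frame coverage of a set of [start, end) intervals.
occupancy_frames <- function(starts, ends, boundaries) {
  if (!length(starts)) return(numeric(length(boundaries) - 1L))
  cum <- rowSums(vapply(seq_along(starts), function(j)
    pmax(0, pmin(boundaries, ends[j]) - pmin(boundaries, starts[j])),
    numeric(length(boundaries))))
  diff(cum) / diff(boundaries)
}

# Render one molecule's channel matrix (frames x channels).
render_molecule <- function(config, events, td, tb_donor, arts,
                            channels, C, boundaries) {
  ph <- config$photophysics
  dt <- config$frame_period
  n <- length(boundaries) - 1L
  reporters <- names(config$reporters)
  k <- length(reporters)

  # --- segment timeline of binding configurations (FRET channels) ---
  bp <- sort(unique(c(0, config$duration,
                      events$t_start, events$t_end,
                      if (tb_donor < config$duration) tb_donor)))
  m <- length(bp) - 1L
  mid <- (bp[-1] + bp[-length(bp)]) / 2
  occ <- matrix(FALSE, m, k, dimnames = list(NULL, reporters))
  for (r in unique(events$reporter)) {
    iv <- events[events$reporter == r, , drop = FALSE]
    idx <- findInterval(mid, iv$t_start)
    occ[, r] <- idx >= 1L & mid < iv$t_end[pmax(idx, 1L)]
  }
  eff <- vapply(config$reporters, `[[`, numeric(1), "fret_efficiency")
  eff <- pmin(eff, 0.9999)
  krel <- eff / (1 - eff)                      # transfer rate relative to donor
  denom <- 1 + as.numeric(occ %*% krel)
  e_seg <- sweep(occ, 2, krel, `*`) / denom    # m x k per-acceptor efficiency
  rates <- cbind(donor = ph$donor_baseline * (1 - rowSums(e_seg)),
                 ph$donor_baseline * e_seg)
  colnames(rates) <- c("donor", paste0("acceptor_", seq_len(k)))
  rates[bp[-length(bp)] >= tb_donor, ] <- 0    # donor bleach kills all FRET

  ideal <- frame_average(bp, rates, boundaries)

  # --- transcription reporter: exponential approach, one-frame drop ---
  if (config$mode == "cotranscriptional") {
    ideal <- cbind(ideal,
                   transcription = transcription_frames(config, td, boundaries))
  }
  ideal <- ideal[, channels, drop = FALSE]

  # --- sticking artifacts (acceptor-only, added before crosstalk) ---
  if (!is.null(arts) && nrow(arts)) {
    for (chn in unique(arts$channel)) {
      iv <- arts[arts$channel == chn, , drop = FALSE]
      ideal[, chn] <- ideal[, chn] + config$nonspecific$amplitude *
        occupancy_frames(iv$t_start, iv$t_end, boundaries)
    }
  }

  out <- ideal %*% C
  out <- out + ph$background
  if (ph$noise_sd > 0) {
    out <- out + stats::rnorm(length(out), sd = ph$noise_sd)
  }
  dead <- boundaries[-length(boundaries)] >= config$dead_time[1] &
    boundaries[-length(boundaries)] < config$dead_time[1] + config$dead_time[2]
  out[dead, ] <- 0
  dimnames(out) <- list(NULL, channels)
  out
}

# Average piecewise-constant rates (m x C, breakpoints bp) over camera frames.
frame_average <- function(bp, rates, boundaries) {
  w <- diff(bp)
  cum <- rbind(0, apply(rates * w, 2, cumsum))
  idx <- pmin(findInterval(boundaries, bp), nrow(rates))
  vals <- cum[idx, , drop = FALSE] +
    (boundaries - bp[idx]) * rates[idx, , drop = FALSE]
  apply(vals, 2, diff) / diff(boundaries)
}

# Frame-integrated transcription-channel intensity (before crosstalk/bg).
transcription_frames <- function(config, td, boundaries) {
  tr <- config$transcription
  t0 <- config$t0
  tau <- tr$rise_time_constant
  peak <- tr$peak
  if (is.na(td)) return(numeric(length(boundaries) - 1L))
  v0 <- peak * exp((t0 - td) / tau)
  cum_at <- function(t) {
    pre <- v0 * pmin(t, t0)
    mid <- ifelse(t > t0,
                  peak * tau * (exp((pmin(t, td) - td) / tau) -
                                  exp((t0 - td) / tau)),
                  0)
    pre + mid
  }
  diff(cum_at(boundaries)) / diff(boundaries)
}

#' Convert simulator ground truth to an event table
#'
#' Exposes the true bound intervals in the detected-event schema so that
#' detection output can be compared against ground truth. Intervals are
#' clipped to the observable window (trace start to donor photobleach) and
#' flagged as censored where they abut the window edges.
#'
#' @param truth A `sim_truth` object from [simulate_ensemble()].
#' @return An event table `data.frame` (see [validate_events()]).
#' @export
truth_event_table <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  ev <- truth$events
  if (nrow(ev) == 0L) return(empty_events())
  tb <- truth$times$donor_bleach_time[
    match(ev$molecule_id, truth$times$molecule_id)]
  lim <- pmin(tb, truth$duration)
  keep <- ev$t_start < lim
  ev <- ev[keep, , drop = FALSE]
  lim <- lim[keep]
  out <- data.frame(molecule_id = ev$molecule_id,
                    reporter = ev$reporter,
                    t_start = ev$t_start,
                    t_end = pmin(ev$t_end, lim),
                    left_censored = ev$t_start <= truth$t0,
                    right_censored = ev$t_end >= lim,
                    stringsAsFactors = FALSE)
  validate_events(out)
}
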