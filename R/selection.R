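# ---- step detection primitives ----------------------------------------------

# Optimal 2-segment piecewise-constant split of x by least squares.
# Returns split index s (segments 1..s, s+1..n), segment means, and SSEs of
# the 1- and 2-segment fits. O(n) via cumulative sums.
best_split <- function(x) {
  n <- length(x)
  if (n < 2L) return(list(split = NA_integer_, sse1 = 0, sse2 = 0))
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  tot <- cs[n]
  i <- seq_len(n - 1L)
  sse_left <- cs2[i] - cs[i]^2 / i
  sse_right <- (cs2[n] - cs2[i]) - (tot - cs[i])^2 / (n - i)
  sse <- sse_left + sse_right
  s <- which.min(sse)
  list(split = s,
       mean_left = cs[s] / s,
       mean_right = (tot - cs[s]) / (n - s),
       sse1 = cs2[n] - tot^2 / n,
       sse2 = sse[s])
}

# Boxcar-smoothed lag-w level difference: d[i] = mean(x[i+1..i+w]) -
# mean(x[i-w+1..i]). Steps appear as extreme values at the step position.
step_profile <- function(x, w) {
  n <- length(x)
  if (n < 2L * w + 1L) return(rep(0, n))
  cs <- c(0, cumsum(x))
  d <- rep(0, n)
  i <- w:(n - w)
  after <- (cs[i + w + 1L] - cs[i + 1L]) / w
  before <- (cs[i + 1L] - cs[i - w + 1L]) / w
  d[i] <- after - before
  d
}

# Largest downward steps of a trace: returns positions (frame index of the
# last frame before the drop) and sizes, merged within 2*w frames.
find_down_steps <- function(x, w, min_size) {
  d <- step_profile(x, w)
  cand <- which(d < -min_size)
  if (!length(cand)) {
    return(data.frame(pos = integer(), size = numeric()))
  }
  grp <- cumsum(c(TRUE, diff(cand) > 2L * w))
  pos <- vapply(split(cand, grp), function(ix) ix[which.min(d[ix])],
                integer(1))
  data.frame(pos = as.integer(pos), size = -d[pos])
}

# Robust noise scale of a trace from first differences.
noise_scale <- function(x) {
  stats::mad(diff(x)) / sqrt(2)
}

# ---- transcription detection ------------------------------------------------

#' Detect transcription elongation and template dissociation
#'
#' Searches the transcription-reporter channel for the characteristic
#' signature of a productive trace: a gradual (smoothed, rising) increase in
#' intensity followed by a single large downward step to background, marking
#' dissociation of the DNA template from the surface. Detection fails when
#' there is no rise, no step, more than one comparable step (the stepwise
#' photobleach pattern of a dead complex), or when dissociation falls more
#' than `max_dissociation` seconds after the reference time.
#'
#' The reference time for the dissociation window is the reagent-injection
#' time from the metadata (`t_ref = "injection"`, default) because
#' transcription restarts at NTP delivery; with `t_ref = "onset"` the
#' detected intensity-rise onset is used instead.
#'
#' @param trace Numeric matrix (frames x channels) with a `transcription`
#'   column.
#' @param frame_period Seconds per frame.
#' @param dead_time `c(start, length)` seconds; frames in this window are
#'   ignored.
#' @param injection_time Reagent-delivery time in seconds.
#' @param params Selection parameters, see [pipeline_params()].
#' @param t_ref `"injection"` or `"onset"`.
#' @return List with `detected`, `elongation_start` and `dissociation_time`
#'   (seconds; `NA` when not detected).
#' @export
detect_transcription <- function(trace, frame_period, dead_time = c(0, 0),
                                 injection_time = 0,
                                 params = pipeline_params()$selection,
                                 t_ref = c("injection", "onset")) {
  t_ref <- match.arg(t_ref)
  if (!"transcription" %in% colnames(trace)) {
    stop("transcription channel absent")
  }
  y <- trace[, "transcription"]
  if (all(is.na(y))) stop("input error: all-NaN transcription channel")
  keep <- !dead_frames(nrow(trace), frame_period, dead_time)
  idx <- which(keep)
  x <- y[idx]
  w <- params$smooth_frames
  sigma <- noise_scale(x)
  fail <- list(detected = FALSE, elongation_start = NA_real_,
               dissociation_time = NA_real_)

  rng <- max(x) - min(x)
  min_size <- max(params$min_step_sd * sigma, 0.25 * rng)
  steps <- find_down_steps(x, w, min_size)
  if (nrow(steps) == 0L) return(fail)
  main <- steps[which.max(steps$size), ]
  comparable <- steps$size >= params$comparable_frac * main$size
  if (sum(comparable) > 1L) return(fail)      # stepwise photobleach pattern

  i_step <- main$pos
  post <- x[(i_step + w):length(x)]
  if (length(post) < 2L) return(fail)
  bg <- stats::median(post)
  pre_level <- mean(x[max(1L, i_step - w):i_step])
  if (pre_level - bg < min_size * 0.8) return(fail)

  # gradual rise before the step: smoothed pre-step signal must trend upward
  inj_frame <- findInterval(injection_time, (idx - 1L) * frame_period)
  pre <- x[max(1L, inj_frame):i_step]
  if (length(pre) < 2L * w) return(fail)
  sm <- stats::filter(pre, rep(1 / w, w), sides = 2)
  sm <- sm[!is.na(sm)]
  rise_cor <- suppressWarnings(
    stats::cor(sm, seq_along(sm), method = "spearman"))
  if (is.na(rise_cor) || rise_cor < params$rise_cor_min) return(fail)

  diss_time <- idx[i_step] * frame_period     # first frame after the drop
  onset <- if (t_ref == "injection") {
    injection_time
  } else {
    above <- which(sm > bg + max(3 * sigma, 0.05 * (pre_level - bg)))
    if (!length(above)) return(fail)
    (idx[max(1L, inj_frame) + above[1] - 1L] - 1L) * frame_period
  }
  if (diss_time - onset > params$max_dissociation) return(fail)
  list(detected = TRUE, elongation_start = onset,
       dissociation_time = diss_time)
}

# ---- donor bleach detection -------------------------------------------------

#' Detect single-step donor photobleaching
#'
#' Works on the summed donor + acceptor intensity, which is insensitive to
#' FRET (energy leaving the donor reappears in an acceptor channel), so the
#' donor bleach is the only large step. A trace passes when there is exactly
#' one comparable downward step, the signal after it stays at background, and
#' the step falls inside the configured terminal window (fractions of the
#' total time; default last 20%, covering the deliberately induced bleaching
#' period).
#'
#' @param trace Numeric matrix (frames x channels) with a `donor` column.
#' @param frame_period Seconds per frame.
#' @param dead_time `c(start, length)` seconds.
#' @param window_fraction Length-2 fractions of total time, e.g. `c(0.8, 1)`.
#' @param params Selection parameters, see [pipeline_params()].
#' @return List with `ok` and `bleach_time` (seconds; `NA` when no single
#'   step is found).
#' @export
detect_donor_bleach <- function(trace, frame_period, dead_time = c(0, 0),
                                window_fraction = c(0.8, 1),
                                params = pipeline_params()$selection) {
  fret_ch <- intersect(colnames(trace),
                       c("donor", paste0("acceptor_", 1:3)))
  x_all <- rowSums(trace[, fret_ch, drop = FALSE])
  keep <- !dead_frames(nrow(trace), frame_period, dead_time)
  idx <- which(keep)
  x <- x_all[idx]
  w <- params$smooth_frames
  sigma <- noise_scale(x)
  rng <- max(x) - min(x)
  min_size <- max(params$min_step_sd * sigma, 0.25 * rng)
  steps <- find_down_steps(x, w, min_size)
  fail <- list(ok = FALSE, bleach_time = NA_real_)
  if (nrow(steps) == 0L) return(fail)
  main <- steps[which.max(steps$size), ]
  if (sum(steps$size >= params$comparable_frac * main$size) > 1L) {
    return(fail)                               # multi-molecule spot
  }
  i_step <- main$pos
  post <- x[(i_step + w):length(x)]
  if (length(post) >= 2L) {
    # after the bleach nothing but background may remain
    if (mean(x[max(1L, i_step - w):i_step]) - stats::median(post) <
        0.8 * min_size) {
      return(fail)
    }
  }
  bleach_time <- idx[i_step] * frame_period
  total <- nrow(trace) * frame_period
  ok <- bleach_time >= window_fraction[1] * total &&
    bleach_time <= window_fraction[2] * total
  list(ok = ok, bleach_time = bleach_time)
}

dead_frames <- function(n_frames, frame_period, dead_time) {
  tt <- (seq_len(n_frames) - 1L) * frame_period
  tt >= dead_time[1] & tt < dead_time[1] + dead_time[2]
}

# ---- molecule selection -----------------------------------------------------

#' Select analyzable molecules
#'
#' Applies the trace-selection criteria: in cotranscriptional mode a molecule
#' must show a gradual transcription-signal rise followed by a single-step
#' drop within the allowed window ([detect_transcription()]) and a
#' single-step donor photobleach in the terminal window
#' ([detect_donor_bleach()]); in immobilized-RNA mode only the photobleach
#' criterion applies. Every molecule is annotated with pass/fail and the
#' reasons for rejection; selection is a pure, order-independent function of
#' the traces and parameters.
#'
#' @param traces A [trace_set()].
#' @param mode `"cotranscriptional"` or `"immobilized_rna"`; default taken
#'   from the trace-set metadata.
#' @param params [pipeline_params()] list (the `selection` element is used).
#' @return A `data.frame` with one row per molecule: `molecule_id`,
#'   `selected`, `rejection_reasons`, `transcription_detected`,
#'   `elongation_start`, `dna_dissociation_time`, `donor_bleach_time`.
#' @export
select_molecules <- function(traces, mode = NULL, params = pipeline_params()) {
  stopifnot(inherits(traces, "trace_set"))
  if (is.null(mode)) mode <- traces$metadata$mode
  mode <- match.arg(mode, c("cotranscriptional", "immobilized_rna"))
  sel <- params$selection
  dead <- traces$metadata$dead_time
  if (is.null(dead)) dead <- c(0, 0)
  inj <- traces$metadata$injection_time
  if (is.null(inj)) inj <- 0
  ids <- molecule_ids(traces)
  out <- lapply(ids, function(id) {
    tr <- traces$traces[[id]]
    reasons <- character(0)
    tx <- list(detected = NA, elongation_start = NA_real_,
               dissociation_time = NA_real_)
    if (mode == "cotranscriptional") {
      tx <- detect_transcription(tr, traces$frame_period, dead, inj,
                                 params = sel)
      if (!tx$detected) reasons <- c(reasons, "no_valid_transcription")
    }
    bl <- detect_donor_bleach(tr, traces$frame_period, dead,
                              window_fraction = sel$terminal_window,
                              params = sel)
    if (!bl$ok) reasons <- c(reasons, "no_single_terminal_bleach")
    data.frame(molecule_id = id,
               selected = length(reasons) == 0L,
               rejection_reasons = paste(reasons, collapse = ";"),
               transcription_detected = tx$detected,
               elongation_start = tx$elongation_start,
               dna_dissociation_time = tx$dissociation_time,
               donor_bleach_time = bl$bleach_time,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(molecule_id = character(), selected = logical(),
                      rejection_reasons = character(),
                      transcription_detected = logical(),
                      elongation_start = numeric(),
                      dna_dissociation_time = numeric(),
                      donor_bleach_time = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
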