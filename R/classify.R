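#' Usable analysis window per molecule
#'
#' The window over which classification, accessibility and profiles are
#' evaluated: from `max(t0, elongation_start)` to the donor photobleach,
#' with the laser dead time excluded. Returns one row per selected molecule
#' with `window_start`, `window_end` and `usable_seconds`.
#'
#' @param annotations [select_molecules()] output.
#' @param t0 Reagent-delivery time, seconds.
#' @param dead_time `c(start, length)` seconds.
#' @param duration Trace duration, seconds (used when no bleach was found).
#' @return `data.frame` keyed by `molecule_id`.
#' @export
usable_windows <- function(annotations, t0, dead_time = c(0, 0),
                           duration = Inf) {
  ann <- annotations[annotations$selected, , drop = FALSE]
  start <- pmax(t0, ifelse(is.na(ann$elongation_start), t0,
                           ann$elongation_start))
  end <- ifelse(is.na(ann$donor_bleach_time), duration,
                ann$donor_bleach_time)
  dead_in <- pmax(0, pmin(end, dead_time[1] + dead_time[2]) -
                    pmax(start, dead_time[1]))
  data.frame(molecule_id = ann$molecule_id,
             window_start = start, window_end = end,
             usable_seconds = pmax(0, end - start - dead_in),
             stringsAsFactors = FALSE)
}

#' Assign folding classes from detected events
#'
#' A molecule is `+` for a reporter iff it shows at least one detected event
#' of that reporter overlapping its usable window (partial, censored events
#' count: an observed partial event is still evidence of accessibility).
#' With k reporters this yields the 2^k possible folding classes; labels are
#' canonical (S7 first, then probes 5' to 3', see
#' [canonical_reporter_order()]).
#'
#' @param events Event table.
#' @param annotations [select_molecules()] output.
#' @param reporters Character vector of reporter names to classify over.
#' @param t0,dead_time,duration Passed to [usable_windows()].
#' @return `data.frame` with `molecule_id`, one logical column per reporter,
#'   and `class_label`.
#' @export
classify_molecules <- function(events, annotations, reporters, t0 = 0,
                               dead_time = c(0, 0), duration = Inf) {
  if (!length(reporters)) stop("configuration error: no reporters declared")
  missing_rep <- setdiff(unique(events$reporter), reporters)
  win <- usable_windows(annotations, t0, dead_time, duration)
  if (nrow(win) == 0L) {
    out <- data.frame(molecule_id = character(), stringsAsFactors = FALSE)
    for (r in reporters) out[[r]] <- logical(0)
    out$class_label <- character(0)
    return(out)
  }
  signs <- vapply(reporters, function(r) {
    ev <- events[events$reporter == r, , drop = FALSE]
    vapply(seq_len(nrow(win)), function(i) {
      sub <- ev[ev$molecule_id == win$molecule_id[i], , drop = FALSE]
      interval_overlap(sub$t_start, sub$t_end,
                       c(win$window_start[i], win$window_end[i])) > 0
    }, logical(1))
  }, logical(nrow(win)))
  signs <- matrix(signs, nrow = nrow(win),
                  dimnames = list(NULL, reporters))
  out <- data.frame(molecule_id = win$molecule_id, stringsAsFactors = FALSE)
  for (r in reporters) out[[r]] <- signs[, r]
  out$class_label <- apply(signs, 1, function(s) make_class_label(s))
  out
}

#' Accessibility scores
#'
#' Per molecule, the fraction of its usable window spent probe-bound; the
#' ensemble accessibility score is the arithmetic mean of this fraction over
#' the selected molecules (optionally restricted to a folding class).
#'
#' @param events Event table.
#' @param annotations [select_molecules()] output.
#' @param reporter Reporter whose occupancy is scored.
#' @param t0,dead_time,duration Passed to [usable_windows()].
#' @param molecule_ids Optional subset (e.g. one folding class).
#' @return List with `per_molecule` (`data.frame`: `molecule_id`,
#'   `fraction_time_bound`) and `accessibility_score`.
#' @export
accessibility_scores <- function(events, annotations, reporter, t0 = 0,
                                 dead_time = c(0, 0), duration = Inf,
                                 molecule_ids = NULL) {
  win <- usable_windows(annotations, t0, dead_time, duration)
  if (!is.null(molecule_ids)) {
    win <- win[win$molecule_id %in% molecule_ids, , drop = FALSE]
  }
  if (any(win$usable_seconds <= 0)) stop("non-positive usable window")
  ev <- events[events$reporter == reporter, , drop = FALSE]
  frac <- vapply(seq_len(nrow(win)), function(i) {
    sub <- ev[ev$molecule_id == win$molecule_id[i], , drop = FALSE]
    interval_overlap(sub$t_start, sub$t_end,
                     c(win$window_start[i], win$window_end[i])) /
      win$usable_seconds[i]
  }, numeric(1))
  frac <- pmin(frac, 1)
  list(per_molecule = data.frame(molecule_id = win$molecule_id,
                                 fraction_time_bound = frac,
                                 stringsAsFactors = FALSE),
       accessibility_score = if (length(frac)) mean(frac) else NA_real_)
}

#' Folding-class fractions per condition
#'
#' Fractions of molecules per class label within each condition; fractions
#' of one condition sum to 1. Replicates are pooled by concatenating their
#' assignments (pass a `condition` vector to keep them apart).
#'
#' @param assignments [classify_molecules()] output, or several rbind-ed
#'   together.
#' @param condition Condition label(s), recycled over rows.
#' @return `data.frame` with `condition`, `class_label`, `n`, `fraction`.
#' @export
class_fractions <- function(assignments, condition = "all") {
  stopifnot(nrow(assignments) >= 1L)
  df <- data.frame(condition = rep_len(condition, nrow(assignments)),
                   class_label = assignments$class_label,
                   stringsAsFactors = FALSE)
  tab <- as.data.frame(table(df$condition, df$class_label),
                       stringsAsFactors = FALSE)
  names(tab) <- c("condition", "class_label", "n")
  tot <- tapply(tab$n, tab$condition, sum)
  tab$fraction <- tab$n / as.numeric(tot[tab$condition])
  tab[order(tab$condition, -tab$fraction), ]
}

#' Fold change between two class fractions
#'
#' Ratio between two fractions, annotated with its direction; the magnitude
#' is always >= 1 (`b/a` for an increase, `a/b` for a decrease). Full
#' precision is kept in `ratio`; `rounded` is the one-decimal reporting
#' value.
#'
#' @param fraction_a Fraction under the reference condition.
#' @param fraction_b Fraction under the comparison condition.
#' @return List with `ratio`, `rounded`, `direction`.
#' @export
fold_change <- function(fraction_a, fraction_b) {
  stopifnot(fraction_a > 0, fraction_b > 0)
  if (fraction_b >= fraction_a) {
    ratio <- fraction_b / fraction_a
    dir <- "increase"
  } else {
    ratio <- fraction_a / fraction_b
    dir <- "decrease"
  }
  list(ratio = ratio, rounded = round(ratio, 1), direction = dir)
}

#' Time-binned accessibility profile
#'
#' After aligning molecules to the reagent-delivery time `t0`, time is
#' binned (5-s bins by default) and, per bin and reporter, the percentage of
#' molecules having at least one event overlapping the bin is computed. The
#' median time the RNA stays associated with the transcription machinery
#' (template dissociation minus `t0`) is returned for overlay.
#'
#' @param events Event table.
#' @param annotations [select_molecules()] output.
#' @param reporters Reporters to profile.
#' @param t0 Alignment time, seconds.
#' @param bin_width Bin width, seconds.
#' @param molecule_ids Optional class filter.
#' @param duration Trace duration (defines the last bin when no bleach).
#' @return List with `profile` (`data.frame`: `bin_start`, `bin_end`,
#'   `reporter`, `percent`, `n`) and `median_tec_time` (seconds).
#' @export
time_profile <- function(events, annotations, reporters, t0,
                         bin_width = 5, molecule_ids = NULL,
                         duration = Inf) {
  ann <- annotations[annotations$selected, , drop = FALSE]
  if (!is.null(molecule_ids)) {
    ann <- ann[ann$molecule_id %in% molecule_ids, , drop = FALSE]
  }
  if (nrow(ann) == 0L) {
    return(list(profile = data.frame(bin_start = numeric(),
                                     bin_end = numeric(),
                                     reporter = character(),
                                     percent = numeric(), n = integer()),
                median_tec_time = NA_real_))
  }
  end <- ifelse(is.na(ann$donor_bleach_time), duration,
                ann$donor_bleach_time)
  max_t <- max(end - t0)
  edges <- seq(0, by = bin_width, length.out = ceiling(max_t / bin_width) + 1L)
  rows <- list()
  for (r in reporters) {
    ev <- events[events$reporter == r & events$molecule_id %in%
                   ann$molecule_id, , drop = FALSE]
    s <- ev$t_start - t0
    e <- ev$t_end - t0
    for (b in seq_len(length(edges) - 1L)) {
      in_bin <- unique(ev$molecule_id[s < edges[b + 1L] & e > edges[b]])
      alive <- ann$molecule_id[end - t0 > edges[b]]
      n <- length(alive)
      rows[[length(rows) + 1L]] <- data.frame(
        bin_start = edges[b] , bin_end = edges[b + 1L], reporter = r,
        percent = if (n) 100 * length(intersect(in_bin, alive)) / n else 0,
        n = n, stringsAsFactors = FALSE)
    }
  }
  med_tec <- stats::median(ann$dna_dissociation_time - t0, na.rm = TRUE)
  list(profile = do.call(rbind, rows), median_tec_time = med_tec)
}
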