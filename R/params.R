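#' Analysis pipeline parameters
#'
#' Central container for the tunable parameters of trace selection, event
#' detection and kinetics. Values are merged over the defaults, so callers
#' only specify what they change, e.g.
#' `pipeline_params(min_event_frames = 3)`.
#'
#' Defaults: events must last at least 2 frames (`min_event_frames`;
#' single-frame excursions are indistinguishable from shot noise at 100-ms
#' integration), bound runs separated by at most 1 frame are merged
#' (`max_gap_frames`), missing runs of up to `missing_gap_frames` frames
#' interrupt neither bound nor unbound runs, FRET is undefined where the
#' donor + acceptor sum falls below `floor_frac` of its per-molecule median
#' (a relative floor, so detection is invariant to intensity rescaling), and
#' the anticorrelation filter requires the donor dip to be at least
#' `min_drop_ratio` of the acceptor rise with donor/acceptor correlation
#' below `cor_threshold` over the event plus `margin_frames`.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A named list of parameters.
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    floor_frac = 0.3,
    default_threshold = 0.5,
    min_separation = 0.15,
    min_event_frames = 2L,
    max_gap_frames = 1L,
    missing_gap_frames = 5L,
    pool_max_values = 500000L,
    anticorrelation = list(enabled = TRUE, margin_frames = 5L,
                           cor_threshold = -0.3, min_drop_ratio = 0.3,
                           min_rise_sd = 5),
    selection = list(terminal_window = c(0.8, 1),
                     max_dissociation = 200,
                     comparable_frac = 0.5,
                     smooth_frames = 5L,
                     rise_cor_min = 0.5,
                     min_step_sd = 6),
    kd_window_start = 200,
    dead_time_correction = TRUE
  )
  utils::modifyList(defaults, list(...))
}

# Shortest dwell the frame-wise detector can register, in seconds: an event
# must put >= min_event_frames frames above the midpoint threshold, which at
# ~half-frame edge coverage truncates the dwell distribution at about
# (min_event_frames - 1/2) frames. Used by the missed-event corrections.
detection_dead_time <- function(frame_period,
                                min_event_frames = pipeline_params()$min_event_frames) {
  (min_event_frames - 0.5) * frame_period
}
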