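#' Rasterplot of binding events
#'
#' One row per molecule (ordered by the supplied leaf order, e.g. from
#' [cluster_molecules()] or sorted by folding class), with one colored bar
#' per binding event and reporter. Returns both the plot and the underlying
#' row-order table so the layout is testable without touching pixels.
#'
#' @param events Event table.
#' @param order Character vector of molecule ids, top row first.
#' @param reporters Reporters to draw (defaults to those present).
#' @param colors Optional named color vector per reporter.
#' @return List with `plot` (a ggplot) and `rows` (`data.frame` of
#'   `row`, `molecule_id`).
#' @export
render_rasterplot <- function(events, order, reporters = NULL,
                              colors = NULL) {
  if (is.null(reporters)) reporters <- sort(unique(events$reporter))
  rows <- data.frame(row = seq_along(order), molecule_id = order,
                     stringsAsFactors = FALSE)
  ev <- events[events$molecule_id %in% order &
                 events$reporter %in% reporters, , drop = FALSE]
  ev$row <- rows$row[match(ev$molecule_id, rows$molecule_id)]
  if (is.null(colors)) {
    pal <- c("#d62728", "#7b2d8b", "#e6a817", "#2ca02c", "#1f77b4")
    colors <- stats::setNames(rep_len(pal, length(reporters)), reporters)
  }
  p <- ggplot2::ggplot(ev) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$t_start, xmax = .data$t_end,
      ymin = .data$row - 0.45, ymax = .data$row + 0.45,
      fill = .data$reporter)) +
    ggplot2::scale_fill_manual(values = colors) +
    ggplot2::scale_y_reverse(limits = c(length(order) + 0.5, 0.5)) +
    ggplot2::labs(x = "time (s)", y = "molecule", fill = "reporter") +
    ggplot2::theme_minimal()
  list(plot = p, rows = rows)
}

#' Assemble a plain-text analysis report
#'
#' Collects the outputs of the pipeline stages into a single deterministic
#' markdown document: class fractions, fold changes, kinetics, accessibility
#' scores, profiles, the configuration actually used, and the seed. Stages
#' that were not run are marked absent rather than failing. The body carries
#' no timestamps, so identical inputs give byte-identical reports.
#'
#' @param sections Named list of stage outputs; recognized names:
#'   `class_fractions` (data.frame), `fold_changes` (named list of
#'   [fold_change()] results), `kinetics` (data.frame), `accessibility`
#'   (named numeric), `config` (list), `seed` (integer).
#' @return Character vector of report lines (class `sm_report`).
#' @export
build_report <- function(sections) {
  fmt_df <- function(df) {
    c(paste(names(df), collapse = "\t"),
      apply(df, 1, function(r) paste(trimws(format(r, digits = 6)),
                                     collapse = "\t")))
  }
  out <- c("# Single-molecule accessibility analysis report", "")
  sec <- function(title, name, body) {
    if (is.null(sections[[name]])) {
      c(paste0("## ", title), "(absent)", "")
    } else {
      c(paste0("## ", title), body(sections[[name]]), "")
    }
  }
  out <- c(out,
    sec("Folding-class fractions", "class_fractions", fmt_df),
    sec("Fold changes", "fold_changes", function(fc) {
      vapply(names(fc), function(nm) sprintf(
        "%s: %.1f-fold %s", nm, fc[[nm]]$rounded, fc[[nm]]$direction),
        character(1))
    }),
    sec("Kinetics", "kinetics", fmt_df),
    sec("Accessibility scores", "accessibility", function(a) {
      sprintf("%s: %.4f", names(a), a)
    }),
    sec("Configuration", "config", function(cfg) {
      paste0(names(unlist(cfg)), " = ", unlist(cfg))
    }),
    sec("Seed", "seed", function(s) as.character(s)),
    paste0("software: smaccess ",
           as.character(utils::packageVersion("smaccess"))))
  structure(out, class = c("sm_report", "character"))
}

#' @export
print.sm_report <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}
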