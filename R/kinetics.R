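#' Dwell samples
#'
#' A dwell sample is a set of positive durations (seconds) with right-censor
#' flags, of one of three kinds: `bound_lifetime` (event durations),
#' `arrival_time` (reagent delivery to first event) or `interarrival`.
#'
#' @param values Positive durations, seconds.
#' @param censored Logical right-censor flags (defaults to all observed).
#' @param kind One of `"bound_lifetime"`, `"arrival_time"`, `"interarrival"`.
#' @return An object of class `dwell_sample`.
#' @export
dwell_sample <- function(values,
                         censored = rep(FALSE, length(values)),
                         kind = c("bound_lifetime", "arrival_time",
                                  "interarrival")) {
  kind <- match.arg(kind)
  stopifnot(length(values) == length(censored))
  if (any(values <= 0, na.rm = TRUE)) stop("dwell values must be positive")
  structure(list(values = as.numeric(values), censored = as.logical(censored),
                 kind = kind),
            class = "dwell_sample")
}

#' @export
print.dwell_sample <- function(x, ...) {
  cat("dwell_sample (", x$kind, "): ", length(x$values), " values, ",
      sum(x$censored), " censored\n", sep = "")
  invisible(x)
}

#' Arrival times from reagent delivery to the first binding event
#'
#' Per molecule, the time from `t0` (reagent delivery; by default the end of
#' the laser dead time) to the start of the first event of the given
#' reporter. Molecules without any event contribute a right-censored value at
#' the end of their usable window, so event-free molecules are retained
#' rather than discarded.
#'
#' @param events Event table.
#' @param annotations [select_molecules()] output (defines the usable end:
#'   donor bleach). Only selected molecules contribute.
#' @param reporter Reporter name.
#' @param t0 Reagent-delivery time, seconds.
#' @return A `dwell_sample` of kind `arrival_time`.
#' @export
arrival_times <- function(events, annotations, reporter, t0) {
  ann <- annotations[annotations$selected, , drop = FALSE]
  usable_end <- ifelse(is.na(ann$donor_bleach_time), Inf,
                       ann$donor_bleach_time)
  if (any(usable_end <= t0)) stop("input error: t0 after usable trace end")
  ev <- events[events$reporter == reporter, , drop = FALSE]
  first <- if (nrow(ev)) tapply(ev$t_start, ev$molecule_id, min) else
    stats::setNames(numeric(0), character(0))
  f <- first[match(ann$molecule_id, names(first))]
  has <- !is.na(f) & f >= t0
  vals <- ifelse(has, f - t0, usable_end - t0)
  # an event already present in the first usable frame arrives "at" t0
  vals <- pmax(vals, 1e-9)
  dwell_sample(vals, censored = !has, kind = "arrival_time")
}

#' Bound lifetimes of individual binding events
#'
#' Event durations with censoring propagated: events truncated by the trace
#' edges, dead time or donor bleach are right-censored (their true dwell is
#' at least the observed one).
#'
#' @param events Event table.
#' @param reporter Optional reporter filter.
#' @return A `dwell_sample` of kind `bound_lifetime`.
#' @export
bound_lifetimes <- function(events, reporter = NULL) {
  if (!is.null(reporter)) {
    events <- events[events$reporter == reporter, , drop = FALSE]
  }
  dwell_sample(events$t_end - events$t_start,
               censored = events$left_censored | events$right_censored,
               kind = "bound_lifetime")
}

#' Median of a dwell sample
#'
#' Plain sample median of the uncensored values when censoring is light;
#' when more than `censor_tol` of the sample is censored the median is taken
#' from the Kaplan-Meier survival curve instead, which uses the censored
#' values correctly.
#'
#' For dwells measured by the frame-wise detector, brief events below the
#' detection limit are missed, which left-truncates the distribution and
#' biases the raw median upward. `dead_time` (seconds) applies the standard
#' missed-event correction for (memoryless) exponential dwells: median -
#' dead_time for bound lifetimes; for arrival times the median is multiplied
#' by the detected fraction `exp(-off_rate * dead_time)` (missed first
#' events postpone the first detected arrival), with `off_rate` estimated
#' from the corrected bound-lifetime median when not supplied.
#'
#' @param sample A `dwell_sample`.
#' @param dead_time Detection dead time in seconds (0 = no correction).
#' @param off_rate Unbinding rate used for the arrival-time correction.
#' @param censor_tol Censored fraction above which Kaplan-Meier is used.
#' @return Median in seconds.
#' @export
median_dwell <- function(sample, dead_time = 0, off_rate = NULL,
                         censor_tol = 0.05) {
  stopifnot(inherits(sample, "dwell_sample"))
  frac_cens <- mean(sample$censored)
  m <- if (frac_cens > censor_tol) {
    fit <- survival::survfit(
      survival::Surv(sample$values, !sample$censored) ~ 1)
    unname(stats::quantile(fit, probs = 0.5)$quantile)
  } else {
    stats::median(sample$values[!sample$censored])
  }
  if (dead_time > 0) {
    if (sample$kind == "bound_lifetime") {
      m <- max(0, m - dead_time)
    } else if (sample$kind == "arrival_time") {
      if (is.null(off_rate)) {
        stop("arrival-time correction needs 'off_rate'")
      }
      m <- m * exp(-off_rate * dead_time)
    }
  }
  m
}

#' Maximum-likelihood exponential fit with right censoring
#'
#' Fits a 1- or 2-component exponential dwell model by maximum likelihood.
#' Right-censored values contribute survival terms, so rates are recovered
#' correctly where the naive `1/mean(observed)` estimator is biased.
#' `truncation` handles detection-limited samples in which dwells shorter
#' than the detection dead time are absent: the fit is performed on the
#' excess over the truncation point (exact for exponentials by
#' memorylessness). Model preference between 1 and 2 components is reported
#' as a BIC difference (`bic_1 - bic_2`; positive prefers 2 components).
#'
#' @param sample A `dwell_sample`.
#' @param n_components 1 or 2.
#' @param truncation Left-truncation point, seconds.
#' @return An object of class `exp_fit`: `n_components`, `rates`, `weights`,
#'   `log_likelihood`, `model_preference`, `converged`.
#' @export
fit_exponential <- function(sample, n_components = 1, truncation = 0) {
  stopifnot(inherits(sample, "dwell_sample"), n_components %in% 1:2)
  t <- pmax(sample$values - truncation, 1e-9)
  d <- !sample$censored
  if (sum(d) < ifelse(n_components == 1, 10L, 50L)) {
    stop("too few uncensored dwells for a ", n_components, "-component fit")
  }
  fit1 <- list(rates = sum(d) / sum(t), weights = 1)
  fit1$loglik <- sum(d) * log(fit1$rates) - fit1$rates * sum(t)
  bic1 <- -2 * fit1$loglik + log(length(t))
  if (n_components == 1) {
    return(structure(list(n_components = 1L, rates = fit1$rates, weights = 1,
                          log_likelihood = fit1$loglik,
                          model_preference = NA_real_, converged = TRUE),
                     class = "exp_fit"))
  }
  nll <- function(par) {
    w <- stats::plogis(par[1])
    l1 <- exp(par[2]); l2 <- exp(par[3])
    dens <- w * l1 * exp(-l1 * t) + (1 - w) * l2 * exp(-l2 * t)
    surv <- w * exp(-l1 * t) + (1 - w) * exp(-l2 * t)
    -sum(log(ifelse(d, dens, surv)) )
  }
  # moment-flavored starts around the 1-component rate
  starts <- list(c(0, log(fit1$rates * 4), log(fit1$rates / 4)),
                 c(stats::qlogis(0.3), log(fit1$rates * 10),
                   log(fit1$rates / 2)),
                 c(0, log(fit1$rates * 2), log(fit1$rates / 8)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, nll, method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    return(structure(list(n_components = 2L, rates = rep(fit1$rates, 2),
                          weights = c(0.5, 0.5),
                          log_likelihood = fit1$loglik,
                          model_preference = NA_real_, converged = FALSE),
                     class = "exp_fit"))
  }
  w <- stats::plogis(best$par[1])
  rates <- exp(best$par[2:3])
  o <- order(rates, decreasing = TRUE)
  bic2 <- 2 * best$value + 3 * log(length(t))
  structure(list(n_components = 2L, rates = rates[o],
                 weights = c(w, 1 - w)[o],
                 log_likelihood = -best$value,
                 model_preference = bic1 - bic2,
                 converged = best$convergence == 0),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("exponential fit:", x$n_components, "component(s)\n")
  cat("  rates (s^-1):", signif(x$rates, 4), "\n")
  if (x$n_components > 1) {
    cat("  weights:", signif(x$weights, 4),
        " dBIC(1-2):", signif(x$model_preference, 4), "\n")
  }
  invisible(x)
}

#' Association rate constant from arrival rates at several concentrations
#'
#' Weighted linear fit of the pseudo-first-order arrival rate against probe
#' concentration; the slope is the association rate constant kon
#' (M^-1 s^-1). The intercept is fixed at zero by default (pseudo-first-order
#' kinetics); set `fit_intercept = TRUE` to allow a concentration-independent
#' component.
#'
#' @param rates Pseudo-first-order rates, s^-1 (one per concentration).
#' @param concentrations Molar concentrations.
#' @param weights Optional fit weights (e.g. number of molecules).
#' @param fit_intercept Allow a free intercept.
#' @return List with `kon`, `intercept`, `r_squared` and the `lm` fit.
#' @export
on_rate_vs_concentration <- function(rates, concentrations, weights = NULL,
                                     fit_intercept = FALSE) {
  stopifnot(length(rates) == length(concentrations),
            length(rates) >= 2L)
  df <- data.frame(rate = rates, conc = concentrations)
  fm <- if (fit_intercept) rate ~ conc else rate ~ conc + 0
  fit <- stats::lm(fm, data = df, weights = weights)
  co <- stats::coef(fit)
  list(kon = unname(co["conc"]),
       intercept = if (fit_intercept) unname(co["(Intercept)"]) else 0,
       r_squared = suppressWarnings(summary(fit)$r.squared),
       fit = fit)
}

#' Equilibrium dissociation constant from the bound-time fraction
#'
#' For a reporter in binding equilibrium with free concentration `[P] ~ P0`,
#' the fraction of time bound `Y = t_PR / (t_PR + t_R)` gives
#' `Kd = ((1 - Y) / Y) * P0`. `kd_single_molecule` evaluates one molecule
#' over its evaluation window (by default 200 s to donor bleach, with the
#' laser dead time excluded from both numerator and denominator);
#' `kd_from_times` is the raw arithmetic. Molecules with `Y = 0` get
#' `Kd = NA` with `defined = FALSE` (the formula diverges; such molecules
#' are excluded from per-molecule Kd distributions).
#'
#' @param t_pr Total protein-complexed (bound) time, seconds.
#' @param t_r Total free time, seconds.
#' @param p0 Total labeled protein concentration, molar.
#' @return List with `Y`, `t_pr`, `t_r`, `p0`, `kd`, `defined`, `scope`.
#' @export
kd_from_times <- function(t_pr, t_r, p0, scope = "single_molecule") {
  stopifnot(t_pr >= 0, t_r >= 0, p0 > 0)
  tot <- t_pr + t_r
  if (tot <= 0) stop("empty evaluation window")
  y <- t_pr / tot
  list(Y = y, t_pr = t_pr, t_r = t_r, p0 = p0,
       kd = if (y > 0) (1 - y) / y * p0 else NA_real_,
       defined = y > 0, scope = scope)
}

#' @rdname kd_from_times
#' @param events Event table.
#' @param molecule_id Molecule to evaluate.
#' @param reporter Reporter name.
#' @param window `c(start, end)` seconds; `NA` end means donor bleach.
#' @param dead_time `c(start, length)` seconds excluded from the window.
#' @param scope Label recorded in the result.
#' @export
kd_single_molecule <- function(events, molecule_id, reporter, window, p0,
                               dead_time = c(0, 0)) {
  if (is.na(window[2]) || window[2] <= window[1]) {
    stop("input error: evaluation window is empty")
  }
  ev <- events[events$molecule_id == molecule_id &
                 events$reporter == reporter, , drop = FALSE]
  t_pr <- interval_overlap(ev$t_start, ev$t_end, window)
  len <- window[2] - window[1] -
    interval_overlap(dead_time[1], dead_time[1] + dead_time[2], window)
  kd_from_times(t_pr, max(0, len - t_pr), p0, scope = "single_molecule")
}

#' Bulk Kd of a folding class
#'
#' Pools all molecules of a class into one virtual molecule: bound and free
#' times are summed across molecules, then the bound-fraction formula is
#' applied. `fold_change_kd` compares two bulk estimates as a ratio.
#'
#' @param events Event table.
#' @param annotations [select_molecules()] output.
#' @param molecule_ids Molecules of the class.
#' @param reporter Reporter name.
#' @param p0 Protein concentration, molar.
#' @param window_start Window start, seconds (end is each molecule's donor
#'   bleach).
#' @param dead_time `c(start, length)` seconds.
#' @return As [kd_from_times()], with `scope = "bulk_class"`.
#' @export
kd_bulk <- function(events, annotations, molecule_ids, reporter, p0,
                    window_start = 200, dead_time = c(0, 0)) {
  if (!length(molecule_ids)) stop("empty class")
  t_pr <- 0; t_r <- 0
  for (id in molecule_ids) {
    tb <- annotations$donor_bleach_time[annotations$molecule_id == id]
    win <- c(window_start, tb)
    if (is.na(win[2]) || win[2] <= win[1]) next
    k <- kd_single_molecule(events, id, reporter, win, p0, dead_time)
    t_pr <- t_pr + k$t_pr
    t_r <- t_r + k$t_r
  }
  kd_from_times(t_pr, t_r, p0, scope = "bulk_class")
}

# total overlap of [s, e) intervals with window [w1, w2)
interval_overlap <- function(s, e, window) {
  if (!length(s)) return(0)
  sum(pmax(0, pmin(e, window[2]) - pmax(s, window[1])))
}
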