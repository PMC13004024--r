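# FRET computation, state thresholding, anticorrelation, event extraction.

test_that("FRET efficiency follows I_A/(I_A+I_D) with a missing floor", {
  expect_equal(compute_fret(100, 0), 1.0)
  expect_equal(compute_fret(50, 50), 0.5)
  expect_true(is.na(compute_fret(0, 0)))
  expect_equal(compute_fret(c(10, 1), c(10, 1), floor = 5),
               c(0.5, NA_real_))
})

test_that("two-state threshold sits at the midpoint of the state means", {
  set.seed(4)
  pool <- c(stats::rnorm(3000, 0.1, 0.04), stats::rnorm(2000, 0.8, 0.05))
  est <- estimate_fret_states(pool)
  expect_true(est$separated)
  expect_lt(abs(est$threshold - 0.45), 0.02)

  sym <- c(stats::rnorm(2000, 0.2, 0.03), stats::rnorm(2000, 0.6, 0.03))
  expect_lt(abs(estimate_fret_states(sym)$threshold - 0.4), 0.02)

  flat <- stats::rnorm(500, 0.3, 0.02)
  expect_warning(est2 <- estimate_fret_states(flat), "fallback")
  expect_equal(est2$threshold, 0.5)
  expect_false(est2$separated)

  expect_error(estimate_fret_states(stats::runif(50)), "at least 100")
})

test_that("state assignment reproduces an alternating two-state series", {
  e <- rep(c(0.1, 0.8), 50)
  st <- assign_states(e, 0.45)
  expect_identical(st, rep(c("unbound", "bound"), 50))
  expect_identical(assign_states(rep(NA_real_, 10), 0.45),
                   rep("missing", 10))
})

test_that("short missing gaps interrupt neither bound nor unbound runs", {
  e <- c(rep(0.8, 10), rep(NA, 3), rep(0.8, 10))
  st <- assign_states(e, 0.45, params = pipeline_params(missing_gap_frames = 5L))
  expect_identical(unique(st), "bound")
  long <- c(rep(0.8, 10), rep(NA, 8), rep(0.8, 10))
  st2 <- assign_states(long, 0.45, params = pipeline_params(missing_gap_frames = 5L))
  expect_identical(st2[11:18], rep("missing", 8))
})

test_that("anticorrelation separates FRET events from sticking", {
  n <- 100
  donor <- rep(1000, n); acc <- rep(50, n)
  donor[41:60] <- 300; acc[41:60] <- 750        # genuine FRET event
  set.seed(9)
  donor <- donor + stats::rnorm(n, sd = 20); acc <- acc + stats::rnorm(n, sd = 20)
  expect_true(anticorrelation_check(donor, acc, 41, 60))
  # sticking: acceptor-only pulse, flat donor
  donor2 <- 1000 + stats::rnorm(n, sd = 20)
  expect_false(anticorrelation_check(donor2, acc, 41, 60))
  # single-frame candidates are always rejected
  expect_false(anticorrelation_check(donor, acc, 41, 41))
})

test_that("simulated sticking pulses are removed by the anticorrelation filter", {
  cfg <- sim_config(
    12, reporters = list(H30 = reporter_kinetics(0, 200e-9,
                                                 unbinding_rate = 0.433)),
    mode = "immobilized_rna", duration = 300,
    nonspecific = list(rate = 0.02, mean_duration = 1.5, amplitude = 1500),
    seed = 61)
  sim <- simulate_ensemble(cfg)
  # bypass selection (sticking also trips the bleach-step criterion): the
  # point here is the detector's anticorrelation screen
  ann <- data.frame(molecule_id = molecule_ids(sim$traces), selected = TRUE,
                    rejection_reasons = "", transcription_detected = NA,
                    elongation_start = NA_real_,
                    dna_dissociation_time = NA_real_,
                    donor_bleach_time = NA_real_, stringsAsFactors = FALSE)
  filt <- detect_events(sim$traces, ann,
                        params = pipeline_params(),
                        threshold_override = c(H30 = 0.45))
  raw <- detect_events(sim$traces, ann,
                       params = pipeline_params(
                         anticorrelation = list(enabled = FALSE,
                                                margin_frames = 5L,
                                                cor_threshold = -0.3,
                                                min_drop_ratio = 0.3)),
                       threshold_override = c(H30 = 0.45))
  expect_gt(nrow(raw$events), 0)          # sticking shows up unfiltered
  expect_lt(nrow(filt$events), 0.2 * nrow(raw$events))
})

test_that("event extraction merges short gaps, drops short runs, flags censoring", {
  st <- c(rep("unbound", 5), rep("bound", 7), rep("unbound", 10))
  ev <- extract_events(st, "m1", "H30", 0.1)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$t_end - ev$t_start, 0.7)
  expect_false(ev$left_censored); expect_false(ev$right_censored)

  gap <- c(rep("unbound", 5), rep("bound", 4), "unbound", rep("bound", 4),
           rep("unbound", 5))
  expect_identical(nrow(extract_events(gap, "m", "r", 0.1)), 1L)

  short <- c(rep("unbound", 5), "bound", rep("unbound", 5))
  expect_identical(nrow(extract_events(short, "m", "r", 0.1)), 0L)

  cens <- c(rep("unbound", 5), rep("bound", 5), rep("missing", 10))
  ev2 <- extract_events(cens, "m", "r", 0.1)
  expect_true(ev2$right_censored)
  lead <- c(rep("bound", 5), rep("unbound", 5))
  expect_true(extract_events(lead, "m", "r", 0.1)$left_censored)
})

test_that("noiseless detection matches ground truth to one frame with high precision/recall", {
  o <- oracle_sim()
  det <- o$pipe$events
  truth <- truth_event_table(o$sim$truth)
  sel <- o$pipe$annotations$molecule_id[o$pipe$annotations$selected]
  truth <- truth[truth$molecule_id %in% sel, ]
  # score on resolvable uncensored dwells of >= 3 frames
  tl <- truth[!truth$right_censored & !truth$left_censored &
                truth$t_end - truth$t_start >= 0.3, ]
  m <- match_events(det, tl, tol = 0.1 + 1e-9)
  recall <- mean(m$recall_hits)
  dl <- det[!det$right_censored & !det$left_censored &
              det$t_end - det$t_start >= 0.3, ]
  mp <- match_events(dl, truth, tol = 0.1 + 1e-9)
  precision <- mean(mp$precision_hits)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
})

test_that("event detection is invariant under intensity rescaling", {
  o <- ssrna_sim()
  ts <- o$sim$traces[1:15]
  ann <- select_molecules(ts)
  base <- detect_events(ts, ann)
  scaled <- ts
  scaled$traces <- lapply(scaled$traces, function(m) m * 3.7)
  ann2 <- select_molecules(scaled)
  up <- detect_events(scaled, ann2)
  expect_equal(base$events, up$events)
})

test_that("per-reporter events never overlap and stay within the trace", {
  o <- ssrna_sim()
  ev <- o$pipe$events
  expect_true(all(ev$t_end <= 600 + 1e-9))
  expect_true(all(ev$t_start >= 0))
  tot <- tapply(ev$t_end - ev$t_start, ev$molecule_id, sum)
  expect_true(all(tot <= 600))
  expect_silent(validate_events(ev))
})
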