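# Dwell/arrival statistics, censored exponential fitting, on-rates, Kd.

fake_annotations <- function(ids, bleach = 600) {
  data.frame(molecule_id = ids, selected = TRUE, rejection_reasons = "",
             transcription_detected = NA, elongation_start = NA_real_,
             dna_dissociation_time = NA_real_,
             donor_bleach_time = rep_len(bleach, length(ids)),
             stringsAsFactors = FALSE)
}

one_event <- function(id, start, end, reporter = "H30") {
  data.frame(molecule_id = id, reporter = reporter, t_start = start,
             t_end = end, left_censored = FALSE, right_censored = FALSE,
             stringsAsFactors = FALSE)
}

test_that("arrival times subtract t0 and censor event-free molecules", {
  ev <- one_event("m1", 18.2, 20)
  ann <- fake_annotations(c("m1", "m2"), bleach = 600)
  arr <- arrival_times(ev, ann, "H30", t0 = 15)
  expect_equal(arr$values, c(3.2, 585))
  expect_identical(arr$censored, c(FALSE, TRUE))
  expect_error(arrival_times(ev, fake_annotations("m1", bleach = 10), "H30",
                             t0 = 15), "input error")
})

test_that("bound lifetimes report medians and keep censored events for MLE", {
  ev <- rbind(one_event("m", 0, 1), one_event("m", 2, 4), one_event("m", 5, 9))
  s <- bound_lifetimes(ev)
  expect_equal(median_dwell(s), 2)
  ev$right_censored <- c(FALSE, FALSE, TRUE)
  s2 <- bound_lifetimes(ev)
  expect_equal(median_dwell(s2, censor_tol = 0.5), 1.5)  # censored excluded
  expect_identical(sum(s2$censored), 1L)
})

test_that("exponential MLE recovers the rate within 3% on uncensored draws", {
  set.seed(11)
  x <- stats::rexp(5000, 0.433)
  fit <- fit_exponential(dwell_sample(x), 1)
  expect_lt(abs(fit$rates / 0.433 - 1), 0.03)
  expect_lt(abs(fit$rates - 1 / mean(x)), 1e-12)   # closed-form oracle
})

test_that("censored MLE stays accurate at 30% censoring where the naive estimator fails", {
  set.seed(12)
  lam <- 0.433
  x <- stats::rexp(5000, lam)
  cutoff <- log(1 / 0.3) / lam
  cens <- x > cutoff
  obs <- pmin(x, cutoff)
  fit <- fit_exponential(dwell_sample(obs, cens), 1)
  expect_lt(abs(fit$rates / lam - 1), 0.05)
  naive <- 1 / mean(obs[!cens])
  expect_gt(abs(naive / lam - 1), 0.5)
})

test_that("two-component mixture rates are recovered within 15%", {
  set.seed(13)
  y <- c(stats::rexp(2500, 0.9), stats::rexp(2500, 0.06))
  fit <- fit_exponential(dwell_sample(y), 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$rates[1] / 0.9 - 1), 0.15)
  expect_lt(abs(fit$rates[2] / 0.06 - 1), 0.15)
  expect_lt(abs(fit$weights[1] - 0.5), 0.1)
  expect_gt(fit$model_preference, 0)   # BIC prefers two components
})

test_that("left-truncated fitting undoes the detection dead time", {
  set.seed(14)
  lam <- 0.433; td <- 0.15
  x <- stats::rexp(20000, lam)
  x <- x[x > td][1:5000]
  fit <- fit_exponential(dwell_sample(x), 1, truncation = td)
  expect_lt(abs(fit$rates / lam - 1), 0.05)
})

test_that("on-rate slope is exact on a line and recovered from arrival fits", {
  exact <- on_rate_vs_concentration(c(0.1, 0.4), c(100e-9, 400e-9))
  expect_equal(exact$kon, 1e6)
  set.seed(15)
  kon <- 1.08e6
  conc <- c(100e-9, 200e-9, 400e-9)
  rates <- vapply(conc, function(c0) {
    fit_exponential(dwell_sample(stats::rexp(2000, kon * c0)), 1)$rates
  }, numeric(1))
  est <- on_rate_vs_concentration(rates, conc, weights = rep(2000, 3))
  expect_lt(abs(est$kon / kon - 1), 0.05)
})

test_that("Kd follows the bound-fraction formula", {
  k <- kd_from_times(100, 300, 20e-9)
  expect_equal(k$Y, 0.25)
  expect_equal(k$kd, 60e-9)
  sym <- kd_from_times(50, 50, 20e-9)
  expect_equal(sym$kd, 20e-9)              # Y = 0.5 returns P0 itself
  expect_false(kd_from_times(0, 100, 20e-9)$defined)
  lim <- kd_from_times(100, 0, 20e-9)
  expect_equal(lim$kd, 0)                  # Y -> 1 drives Kd -> 0
})

test_that("Kd is monotone decreasing in Y at fixed P0", {
  y <- seq(0.05, 0.95, by = 0.05)
  kd <- vapply(y, function(yy) kd_from_times(yy, 1 - yy, 20e-9)$kd,
               numeric(1))
  expect_true(all(diff(kd) < 0))
})

test_that("bulk Kd pools molecules into one and matches hand arithmetic", {
  ev <- rbind(one_event("a", 210, 220), one_event("b", 250, 280))
  ann <- fake_annotations(c("a", "b"), bleach = c(300, 300))
  # windows of 100 s each: (t_pr, t_r) = (10, 90) and (30, 70)
  bulk <- kd_bulk(ev, ann, c("a", "b"), "H30", p0 = 20e-9,
                  window_start = 200)
  expect_equal(bulk$Y, 0.2)
  expect_equal(bulk$kd, 4 * 20e-9)
  single <- kd_single_molecule(ev, "a", "H30", c(200, 300), p0 = 20e-9)
  solo_bulk <- kd_bulk(ev, ann, "a", "H30", p0 = 20e-9, window_start = 200)
  expect_equal(solo_bulk$kd, single$kd)    # pooling invariance, n = 1
  # n identical molecules pool to the single-molecule Kd
  clones <- do.call(rbind, lapply(c("c1", "c2", "c3"), one_event,
                                  start = 210, end = 220))
  ann3 <- fake_annotations(c("c1", "c2", "c3"), bleach = 300)
  pooled <- kd_bulk(clones, ann3, c("c1", "c2", "c3"), "H30", p0 = 20e-9,
                    window_start = 200)
  expect_equal(pooled$kd, single$kd)
  expect_error(kd_single_molecule(ev, "a", "H30", c(300, 300), 20e-9),
               "input error")
})

test_that("arrival estimates are invariant to molecule relabeling", {
  o <- ssrna_sim()
  ev <- o$pipe$events
  ann <- o$pipe$annotations
  arr1 <- arrival_times(ev, ann, "H30", t0 = 25)
  perm <- stats::setNames(sample(unique(ann$molecule_id)),
                          unique(ann$molecule_id))
  ev2 <- ev; ev2$molecule_id <- unname(perm[ev$molecule_id])
  ann2 <- ann; ann2$molecule_id <- unname(perm[ann$molecule_id])
  arr2 <- arrival_times(ev2, ann2, "H30", t0 = 25)
  expect_equal(sort(arr1$values), sort(arr2$values))
  expect_equal(fit_exponential(arr1, 1)$rates, fit_exponential(arr2, 1)$rates)
})

test_that("Kaplan-Meier median engages under heavy censoring", {
  set.seed(16)
  x <- stats::rexp(1000, 1)
  cens <- x > 0.9
  s <- dwell_sample(pmin(x, 0.9), cens)
  km <- median_dwell(s)
  expect_lt(abs(km - log(2)), 0.06)
  plain <- stats::median(pmin(x, 0.9)[!cens])
  expect_gt(abs(plain - log(2)), 0.1)   # naive median is biased here
})
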