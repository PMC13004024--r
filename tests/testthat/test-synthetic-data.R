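# Trace simulator: determinism, kinetic law, rendering physics, ground truth.

test_that("same config and seed give bit-identical traces and truth", {
  cfg <- sim_config(6, reporters = list(H30 = reporter_preset("H30")),
                    duration = 60, seed = 42)
  a <- simulate_ensemble(cfg)
  b <- simulate_ensemble(cfg)
  expect_identical(a$traces$traces, b$traces$traces)
  expect_identical(a$truth, b$truth)
})

test_that("molecules are reproducible independent of ensemble size", {
  base <- list(reporters = list(H30 = reporter_preset("H30")),
               duration = 60, seed = 42)
  small <- simulate_ensemble(do.call(sim_config, c(list(3), base)))
  large <- simulate_ensemble(do.call(sim_config, c(list(6), base)))
  expect_identical(small$traces$traces[["mol_0002"]],
                   large$traces$traces[["mol_0002"]])
})

test_that("zero binding rate yields all-negative molecules and background-only acceptors", {
  cfg <- sim_config(
    5,
    reporters = list(H30 = reporter_kinetics(0, 200e-9,
                                             unbinding_rate = 0.433)),
    mode = "immobilized_rna", duration = 60,
    photophysics = list(crosstalk = "identity", background = 50,
                        noise_sd = 10),
    seed = 3)
  sim <- simulate_ensemble(cfg)
  expect_identical(nrow(sim$truth$events), 0L)
  acc <- unlist(lapply(sim$traces$traces, function(m) m[, "acceptor_1"]))
  live <- acc != 0                       # dead-time frames are zeroed
  expect_lt(abs(mean(acc[live]) - 50), 2)
  expect_lt(abs(stats::sd(acc[live]) - 10), 1)
})

test_that("simulated bound dwells follow the configured exponential law", {
  kin <- reporter_preset("H30")          # unbinding rate 0.433 /s
  set.seed(99)
  dwells <- numeric(0)
  while (length(dwells) < 1e5) {
    iv <- smaccess:::renewal_intervals(kin, 0, 2e5)
    dwells <- c(dwells, iv[, 2] - iv[, 1])
  }
  dwells <- dwells[seq_len(1e5)]
  expect_lt(abs(stats::median(dwells) / (log(2) / 0.433) - 1), 0.02)
})

test_that("arrival counts match kon*c*T*(fraction unbound)", {
  kin <- reporter_preset("H30")
  rate_on <- kin$pseudo_first_order_rate          # 0.2166 /s
  frac_unbound <- (1 / rate_on) / (1 / rate_on + 1 / 0.433)
  set.seed(7)
  n_mol <- 500; T_win <- 60
  counts <- vapply(seq_len(n_mol), function(i) {
    nrow(smaccess:::renewal_intervals(kin, 0, T_win))
  }, numeric(1))
  expected <- rate_on * frac_unbound * T_win
  expect_lt(abs(mean(counts) / expected - 1), 0.10)
})

test_that("empirical class frequencies match the configured probabilities", {
  cfg <- sim_config(400, reporters = list(H30 = reporter_preset("H30")),
                    class_probabilities = c("H30+" = 0.62, "H30-" = 0.38),
                    mode = "immobilized_rna", duration = 30, seed = 17)
  sim <- simulate_ensemble(cfg)
  p_hat <- mean(sim$truth$classes$class_label == "H30+")
  expect_lt(abs(p_hat - 0.62), 3 * sqrt(0.62 * 0.38 / 400))
})

test_that("truth intervals are sorted, positive, in range, and absent for '-' reporters", {
  sim <- ssrna_sim()$sim
  ev <- sim$truth$events
  expect_true(all(ev$t_end > ev$t_start))
  expect_true(all(ev$t_start >= sim$truth$t0))
  expect_true(all(ev$t_end <= sim$truth$duration))
  for (id in unique(ev$molecule_id)) {
    s <- ev[ev$molecule_id == id, ]
    expect_true(all(diff(s$t_start) > 0))
    expect_true(all(s$t_start[-1] >= s$t_end[-nrow(s)]))
  }
  neg <- sim$truth$classes$molecule_id[
    sim$truth$classes$class_label == "H30-"]
  expect_false(any(ev$molecule_id %in% neg))
})

test_that("exclusive reporters are never bound concurrently", {
  sim <- twocolor_sim()$sim
  ev <- sim$truth$events
  for (id in unique(ev$molecule_id)) {
    s <- ev[ev$molecule_id == id, ]
    s <- s[order(s$t_start), ]
    if (nrow(s) < 2L) next
    expect_true(all(s$t_start[-1] >= s$t_end[-nrow(s)] - 1e-9))
  }
})

test_that("a permanently closed accessibility gate blocks all binding", {
  cfg <- sim_config(
    5,
    reporters = list(H30 = reporter_preset("H30", gate = c(0, 0, 0))),
    mode = "immobilized_rna", duration = 60, seed = 5)
  sim <- simulate_ensemble(cfg)
  expect_identical(nrow(sim$truth$events), 0L)
})

test_that("noiseless rendered occupancy equals frame-integrated true occupancy", {
  cfg <- sim_config(
    3, reporters = list(H30 = reporter_preset("H30")),
    mode = "immobilized_rna", duration = 60,
    photophysics = list(noise_sd = 0, crosstalk = "identity",
                        background = 0),
    seed = 12)
  sim <- simulate_ensemble(cfg)
  b <- seq(0, 60, by = 0.1)
  for (id in molecule_ids(sim$traces)) {
    tb <- sim$truth$times$donor_bleach_time[
      sim$truth$times$molecule_id == id]
    ev <- sim$truth$events[sim$truth$events$molecule_id == id, ]
    occ_true <- smaccess:::occupancy_frames(ev$t_start,
                                            pmin(ev$t_end, tb), b)
    occ_rendered <- sim$traces$traces[[id]][, "acceptor_1"] / (1000 * 0.75)
    live <- b[-length(b)] < tb - 0.1 &
      !(b[-length(b)] >= 15 & b[-length(b)] < 25)
    expect_lt(max(abs(occ_true[live] - occ_rendered[live])), 1e-9)
  }
})

test_that("truth_event_table mirrors truth with censoring at window edges", {
  truth <- structure(list(
    classes = data.frame(molecule_id = "m1", class_label = "H30+"),
    events = data.frame(molecule_id = rep("m1", 3), reporter = "H30",
                        t_start = c(10, 50, 98), t_end = c(12, 60, 100),
                        stringsAsFactors = FALSE),
    times = data.frame(molecule_id = "m1", dissociation_time = NA_real_,
                       donor_bleach_time = 99),
    duration = 100, t0 = 5, frame_period = 0.1),
    class = "sim_truth")
  tab <- truth_event_table(truth)
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$t_end, c(12, 60, 99))
  expect_identical(tab$right_censored, c(FALSE, FALSE, TRUE))
  truth$events <- truth$events[0, ]
  expect_identical(nrow(truth_event_table(truth)), 0L)
})

test_that("malformed configurations are rejected", {
  rep1 <- list(H30 = reporter_preset("H30"))
  expect_error(sim_config(2, rep1,
                          class_probabilities = c("H30+" = 0.5)),
               "sum to 1")
  expect_error(sim_config(2, rep1,
                          class_probabilities = c("H31+" = 1)),
               "does not cover")
  expect_error(sim_config(2, rep1,
                          exclusivity_pairs = list(c("H30", "H99"))),
               "unknown reporter")
  expect_error(sim_config(2, rep1, duration = 10), "dead-time")
  expect_error(reporter_kinetics(1e6, 2e-7, dwell_rates = c(1, 2),
                                 dwell_weights = c(0.6, 0.6)),
               "sum to 1")
})
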