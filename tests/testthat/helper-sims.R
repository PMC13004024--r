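# Shared fixtures, built in code and memoised across test files.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, builder(), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# Sparse, noiseless single-probe ensemble for detector-oracle checks:
# binding slow enough that unbound gaps are resolvable at 100-ms frames.
oracle_sim <- function() {
  cached("oracle_sim", function() {
    cfg <- sim_config(
      60,
      reporters = list(H30 = reporter_preset("H30",
                                             binding_rate_constant = 5e4)),
      mode = "immobilized_rna",
      duration = 600,
      photophysics = list(noise_sd = 0),
      seed = 2024)
    sim <- simulate_ensemble(cfg)
    pipe <- run_pipeline(sim$traces)
    list(cfg = cfg, sim = sim, pipe = pipe)
  })
}

# Small noisy ssRNA ensemble (accessible + inaccessible classes).
ssrna_sim <- function() {
  cached("ssrna_sim", function() {
    cfg <- sim_config(
      80,
      reporters = list(H30 = reporter_preset("H30")),
      class_probabilities = c("H30+" = 0.9, "H30-" = 0.1),
      mode = "immobilized_rna",
      duration = 600,
      seed = 311)
    sim <- simulate_ensemble(cfg)
    pipe <- run_pipeline(sim$traces)
    list(cfg = cfg, sim = sim, pipe = pipe)
  })
}

# Noiseless two-reporter cotranscriptional ensemble over four classes.
twocolor_sim <- function() {
  cached("twocolor_sim", function() {
    cfg <- sim_config(
      50,
      reporters = list(S7 = reporter_preset("S7"),
                       H2829 = reporter_preset("H2829")),
      class_probabilities = c("S7+/H2829+" = 0.4, "S7+/H2829-" = 0.15,
                              "S7-/H2829+" = 0.3, "S7-/H2829-" = 0.15),
      exclusivity_pairs = list(c("S7", "H2829")),
      duration = 600,
      photophysics = list(noise_sd = 0),
      seed = 555)
    sim <- simulate_ensemble(cfg)
    pipe <- run_pipeline(sim$traces)
    list(cfg = cfg, sim = sim, pipe = pipe)
  })
}

# Match detected events to truth events 1:1 within a frame tolerance.
match_events <- function(detected, truth, tol) {
  used <- rep(FALSE, nrow(detected))
  hit <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    j <- which(!used &
                 detected$molecule_id == truth$molecule_id[i] &
                 detected$reporter == truth$reporter[i] &
                 abs(detected$t_start - truth$t_start[i]) <= tol &
                 abs(detected$t_end - truth$t_end[i]) <= tol)
    if (length(j)) {
      used[j[1]] <- TRUE
      hit[i] <- TRUE
    }
  }
  list(recall_hits = hit, precision_hits = used)
}

# Independent Spearman-distance oracle: Pearson correlation on ranks, with
# the constant-vector convention applied explicitly.
brute_spearman_dist <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ri <- rank(x[i, ]); rj <- rank(x[j, ])
      if (stats::sd(ri) == 0 || stats::sd(rj) == 0) {
        d[i, j] <- if (identical(x[i, ], x[j, ])) 0 else 2
      } else {
        r <- sum((ri - mean(ri)) * (rj - mean(rj))) /
          sqrt(sum((ri - mean(ri))^2) * sum((rj - mean(rj))^2))
        d[i, j] <- 1 - r
      }
    }
  }
  diag(d) <- 0
  d
}

# Hand-built trace matrix with optional channels; n frames of baseline with
# steps/segments applied, plus Gaussian noise.
flat_trace <- function(n, channels, level = 100, noise = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * length(channels), mean = level, sd = noise),
              nrow = n, dimnames = list(NULL, channels))
  m
}
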