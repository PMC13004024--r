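# Folding classes, accessibility scores, fold changes, time profiles.

cls_annotations <- function(ids, bleach = 600, elong = NA_real_) {
  data.frame(molecule_id = ids, selected = TRUE, rejection_reasons = "",
             transcription_detected = NA,
             elongation_start = rep_len(elong, length(ids)),
             dna_dissociation_time = NA_real_,
             donor_bleach_time = rep_len(bleach, length(ids)),
             stringsAsFactors = FALSE)
}

evrow <- function(id, reporter, start, end) {
  data.frame(molecule_id = id, reporter = reporter, t_start = start,
             t_end = end, left_censored = FALSE, right_censored = FALSE,
             stringsAsFactors = FALSE)
}

test_that("class labels follow the >=1-event rule in canonical order", {
  ev <- rbind(evrow("m1", "S7", 100, 110), evrow("m2", "H30", 50, 51))
  ann <- cls_annotations(c("m1", "m2", "m3"))
  cls <- classify_molecules(ev, ann, c("H30", "S7"))
  expect_identical(cls$class_label,
                   c("S7+/H30-", "S7-/H30+", "S7-/H30-"))
  # three reporters always land in one of the 8 labels
  cls3 <- classify_molecules(ev, ann, c("S7", "H2829", "H30"))
  all8 <- apply(expand.grid(s = c("+", "-"), a = c("+", "-"),
                            b = c("+", "-")), 1, function(x)
    sprintf("S7%s/H2829%s/H30%s", x[1], x[2], x[3]))
  expect_true(all(cls3$class_label %in% all8))
  expect_error(classify_molecules(ev, ann, character(0)), "configuration")
})

test_that("canonical label order puts S7 first, then probes 5' to 3'", {
  expect_identical(canonical_reporter_order(c("H32", "H30", "S7", "H2829")),
                   c("S7", "H2829", "H30", "H32"))
  expect_identical(make_class_label(c(H30 = TRUE, S7 = FALSE)),
                   "S7-/H30+")
})

test_that("events outside the usable window do not flip the class sign", {
  ev <- evrow("m1", "H30", 5, 10)          # before t0
  ann <- cls_annotations("m1")
  cls <- classify_molecules(ev, ann, "H30", t0 = 25)
  expect_identical(cls$class_label, "H30-")
})

test_that("accessibility score is the mean fraction of time bound", {
  ann <- cls_annotations(c("m1", "m2"), bleach = 125)
  # usable window [25, 125): m1 bound 20 s (0.2), m2 bound 40 s (0.4)
  ev <- rbind(evrow("m1", "H30", 30, 50), evrow("m2", "H30", 60, 100))
  acc <- accessibility_scores(ev, ann, "H30", t0 = 25)
  expect_equal(sort(acc$per_molecule$fraction_time_bound), c(0.2, 0.4))
  expect_equal(acc$accessibility_score, 0.3)
  # fully bound molecule scores 1
  full <- accessibility_scores(evrow("m1", "H30", 25, 125), ann, "H30",
                               t0 = 25, molecule_ids = "m1")
  expect_equal(full$accessibility_score, 1.0)
})

test_that("class fractions partition to 1 and respect conditions", {
  asg <- data.frame(molecule_id = sprintf("m%d", 1:10),
                    class_label = c(rep("S7+/H30-", 4), rep("S7-/H30-", 6)),
                    stringsAsFactors = FALSE)
  cf <- class_fractions(asg)
  expect_equal(sum(cf$fraction), 1)
  expect_equal(cf$fraction[cf$class_label == "S7+/H30-"], 0.4)
  two <- class_fractions(rbind(asg, asg), condition = rep(c("a", "b"), each = 10))
  expect_equal(as.numeric(tapply(two$fraction, two$condition, sum)), c(1, 1))
})

test_that("fold changes match worked examples and compose transitively", {
  dec <- fold_change(0.48, 0.23)
  expect_equal(dec$rounded, 2.1)
  expect_identical(dec$direction, "decrease")
  inc <- fold_change(0.09, 0.16)
  expect_equal(inc$rounded, 1.8)
  expect_identical(inc$direction, "increase")
  expect_equal(fold_change(0.3, 0.3)$ratio, 1.0)
  ab <- fold_change(0.1, 0.2); bc <- fold_change(0.2, 0.6)
  ac <- fold_change(0.1, 0.6)
  expect_equal(ab$ratio * bc$ratio, ac$ratio)
  expect_error(fold_change(0, 0.5))
})

test_that("time profile bins events into 5-s intervals from t0", {
  ann <- cls_annotations("m1", bleach = 60)
  ev <- evrow("m1", "H30", 25, 32)        # [0, 7) s after t0 = 25
  tp <- time_profile(ev, ann, "H30", t0 = 25)
  pr <- tp$profile
  expect_equal(pr$percent[pr$bin_start == 0], 100)
  expect_equal(pr$percent[pr$bin_start == 5], 100)
  expect_true(all(pr$percent[pr$bin_start >= 10] == 0))
  none <- time_profile(ev[0, ], ann, "H30", t0 = 25)
  expect_true(all(none$profile$percent == 0))
})

test_that("classification agrees with ground truth on noiseless simulations", {
  o <- twocolor_sim()
  truth_ev <- truth_event_table(o$sim$truth)
  ann <- o$pipe$annotations
  reporters <- c("S7", "H2829")
  from_truth <- classify_molecules(truth_ev, ann, reporters, t0 = 25,
                                   dead_time = c(15, 10), duration = 600)
  detected <- classify_molecules(o$pipe$events, ann, reporters, t0 = 25,
                                 dead_time = c(15, 10), duration = 600)
  agree <- mean(from_truth$class_label == detected$class_label)
  expect_gte(agree, 0.99)
  # and detected classes match the generating labels
  gen <- o$sim$truth$classes[match(detected$molecule_id,
                                   o$sim$truth$classes$molecule_id), ]
  expect_gte(mean(gen$class_label == detected$class_label), 0.95)
})

test_that("accessibility score is invariant to molecule and replicate order", {
  o <- ssrna_sim()
  ev <- o$pipe$events; ann <- o$pipe$annotations
  a1 <- accessibility_scores(ev, ann, "H30", t0 = 25)$accessibility_score
  perm <- sample(nrow(ann))
  a2 <- accessibility_scores(ev[sample(nrow(ev)), ], ann[perm, ], "H30",
                             t0 = 25)$accessibility_score
  expect_equal(a1, a2)
})
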