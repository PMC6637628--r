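make_fc_input <- function(values_by_tp, groups = "model", nr = 7) {
  # one species of interest plus a tiny constant species that pins the
  # table pseudocount to a negligible 5e-10
  tps <- names(values_by_tp)
  meta <- expand.grid(timepoint = tps, rat = seq_len(nr), group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$rat_id <- sprintf("%s_r%d", meta$group, meta$rat)
  meta$sample_id <- sprintf("%s_%s", meta$rat_id, meta$timepoint)
  prof <- matrix(1e-9, nrow(meta), 2,
                 dimnames = list(meta$sample_id, c("s__sp1", "s__tiny")))
  for (tp in tps)
    prof[meta$timepoint == tp, 1] <- values_by_tp[[tp]]
  list(profile = prof, meta = meta[, c("sample_id", "rat_id", "group",
                                       "timepoint")])
}

test_that("normalize_to_reference divides by the reference mean per TP", {
  meta <- grid_meta(groups = c("normal", "model"), nr = 2, nt = 2)
  # s__c pins the pseudocount to a negligible 5e-10
  prof <- matrix(1e-9, nrow(meta), 3,
                 dimnames = list(meta$sample_id, c("s__a", "s__b", "s__c")))
  prof[, "s__a"] <- c(4, 8, 6, 10, 5, 9, 5, 9)   # normal r1/r2, model r1/r2
  prof[, "s__b"] <- 1
  norm <- normalize_to_reference(prof, meta, "normal")
  # normal mean at TP1 for s__a is (4+6)/2 = 5; model rat value 5 -> ratio 1
  eps <- pseudocount(prof)
  expect_equal(norm["model_r1_TP1", "s__a"], (5 + eps) / (5 + eps))
  expect_equal(norm["model_r1_TP2", "s__a"], (9 + eps) / (9 + eps))
  expect_equal(norm["normal_r1_TP1", "s__b"], 1)

  # all-zero reference: denominator falls back to the pseudocount
  prof2 <- prof
  prof2[meta$group == "normal", "s__b"] <- 0
  n2 <- normalize_to_reference(prof2, meta, "normal")
  expect_true(all(is.finite(n2)))
  eps2 <- pseudocount(prof2)
  expect_equal(n2["model_r1_TP1", "s__b"], (1 + eps2) / eps2)

  # scale invariance: doubling one species everywhere cancels (up to eps)
  prof3 <- prof
  prof3[, "s__a"] <- prof3[, "s__a"] * 2
  n3 <- normalize_to_reference(prof3, meta, "normal")
  expect_equal(n3[, "s__a"], norm[, "s__a"], tolerance = 1e-3)
})

test_that("missing reference timepoint is an error naming it", {
  meta <- grid_meta(groups = c("normal", "model"), nr = 2, nt = 2)
  keep <- !(meta$group == "normal" & meta$timepoint == "TP2")
  meta2 <- meta[keep, ]
  prof <- matrix(1, nrow(meta2), 1,
                 dimnames = list(meta2$sample_id, "s__a"))
  expect_error(normalize_to_reference(prof, meta2, "normal"), "TP2")
})

test_that("log10 fold changes match hand arithmetic", {
  inp <- make_fc_input(list(TP1 = rep(1, 7),
                            TP2 = rep(16, 7),
                            TP3 = rep(0.1, 7),
                            TP4 = rep(1, 7)),
                       groups = c("normal", "model"))
  norm <- normalize_to_reference(inp$profile, inp$meta, "normal")
  fc <- log10_fc_vs_baseline(norm, inp$meta)
  expect_false("TP1" %in% fc$timepoint)
  # all rats had identical trajectories to the reference -> FC 0 everywhere
  expect_equal(fc$log10_fc, rep(0, nrow(fc)))

  # a 16-fold per-rat increase vs its own TP1 (model only)
  inp2 <- make_fc_input(list(TP1 = c(rep(1, 7), rep(1, 7)),
                             TP2 = c(rep(1, 7), rep(16, 7))),
                        groups = c("normal", "model"))
  norm2 <- normalize_to_reference(inp2$profile, inp2$meta, "normal")
  fc2 <- log10_fc_vs_baseline(norm2, inp2$meta)
  model_fc <- fc2$log10_fc[fc2$group == "model" & fc2$species == "s__sp1"]
  expect_equal(model_fc, rep(log10(16), 7), tolerance = 1e-3)
  expect_equal(round(log10(16), 2), 1.20)

  # a 10-fold decrease -> FC -1
  inp3 <- make_fc_input(list(TP1 = c(rep(1, 7), rep(10, 7)),
                             TP2 = c(rep(1, 7), rep(1, 7))),
                        groups = c("normal", "model"))
  norm3 <- normalize_to_reference(inp3$profile, inp3$meta, "normal")
  fc3 <- log10_fc_vs_baseline(norm3, inp3$meta)
  expect_equal(fc3$log10_fc[fc3$group == "model" & fc3$species == "s__sp1"],
               rep(-1, 7), tolerance = 1e-2)

  # a rat without a baseline sample is an error listing it
  meta_cut <- inp$meta[inp$meta$sample_id != "model_r3_TP1", ]
  expect_error(log10_fc_vs_baseline(norm[meta_cut$sample_id, , drop = FALSE],
                                    meta_cut), "model_r3")
})

test_that("fold change is antisymmetric under baseline swap", {
  sim <- small_cohort(seed = 5)
  norm <- normalize_to_reference(sim$profile, sim$metadata)
  fc <- log10_fc_vs_baseline(norm, sim$metadata)
  swapped <- sim$metadata
  swapped$timepoint[swapped$timepoint == "TP1"] <- "tmp"
  swapped$timepoint[swapped$timepoint == "TP3"] <- "TP1"
  swapped$timepoint[swapped$timepoint == "tmp"] <- "TP3"
  fc_sw <- log10_fc_vs_baseline(norm, swapped)
  a <- fc[fc$timepoint == "TP3", ]
  b <- fc_sw[fc_sw$timepoint == "TP3", ]
  b <- b[match(paste(a$rat_id, a$species), paste(b$rat_id, b$species)), ]
  expect_equal(a$log10_fc, -b$log10_fc)
})

test_that("the 16-fold / 80%-of-rats rule matches hand-computed calls", {
  fc_toy <- function(values) {
    data.frame(rat_id = sprintf("r%d", seq_along(values)), group = "model",
               species = "s__sp1", timepoint = "TP5", log10_fc = values,
               stringsAsFactors = FALSE)
  }
  # 6 of 7 rats above the cutoff: fraction 0.857 > 0.8 -> significant, +
  calls <- call_significant(fc_toy(c(rep(1.5, 6), 0)))
  expect_true(calls$significant)
  expect_equal(calls$direction, 1)
  expect_equal(calls$fraction_passing, 6 / 7, tolerance = 1e-12)

  # 5 of 7 rats: fraction 0.714 -> not significant
  expect_false(call_significant(fc_toy(c(rep(1.5, 5), 0, 0)))$significant)

  # all rats at 1.0 < log10(16): below threshold
  expect_false(call_significant(fc_toy(rep(1, 7)))$significant)

  # all rats pass but signs disagree: inconsistent -> not significant
  expect_false(call_significant(fc_toy(c(rep(1.5, 4), rep(-1.5, 3))))$significant)

  # downward change: direction -1
  dn <- call_significant(fc_toy(rep(-1.3, 7)))
  expect_true(dn$significant)
  expect_equal(dn$direction, -1)
})

test_that("significance calls are monotone in both thresholds", {
  set.seed(9)
  fc <- data.frame(rat_id = rep(sprintf("r%d", 1:7), times = 20),
                   group = "model",
                   species = rep(sprintf("s__sp%02d", 1:20), each = 7),
                   timepoint = "TP5",
                   log10_fc = rnorm(140, sd = 1.5),
                   stringsAsFactors = FALSE)
  base <- call_significant(fc, threshold_fold = 16, rat_fraction = 0.8)
  for (thr in c(20, 32)) {
    harder <- call_significant(fc, threshold_fold = thr, rat_fraction = 0.8)
    expect_true(all(harder$significant <= base$significant))
  }
  for (rf in c(0.9, 0.95)) {
    harder <- call_significant(fc, threshold_fold = 16, rat_fraction = rf)
    expect_true(all(harder$significant <= base$significant))
  }
})

test_that("planted strong shifts are called with the right direction", {
  # near-noiseless cohort with 64x planted drift in a small, roughly
  # direction-balanced subset of a large table, so the planted folds stay
  # well above the strict 16x cutoff after compositional closure: every
  # planted change must be called at TP5 in the model group
  sim <- simulate_cohort(sim_config(seed = 1, n_species = 200,
                                    n_signal_species = 1,
                                    n_drift_species = 6, noise_sd = 0.01,
                                    drift_magnitude = 1.8284,
                                    severity_sd = 0, response_sd = 0))
  norm <- normalize_to_reference(sim$profile, sim$metadata)
  fc <- log10_fc_vs_baseline(norm, sim$metadata)
  calls <- call_significant(fc[fc$group == "model" & fc$timepoint == "TP5", ])
  truth_dirs <- sim$ground_truth$drift_directions
  hits <- calls[calls$species %in% names(truth_dirs), ]
  expect_true(all(hits$significant))
  expect_equal(hits$direction,
               unname(truth_dirs[hits$species]))
})
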