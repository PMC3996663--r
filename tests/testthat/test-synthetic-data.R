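test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_up = 100, n_down = 100, n_lnc_true = 150), "n_up")
  expect_error(sim_config(true_fold_up = 0), "folds")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
  expect_error(sim_config(n_associated = 11, n_genes_cohort = 10), "n_associated")
})

test_that("empty catalog config yields an empty catalog", {
  cfg <- sim_config(n_lnc_true = 0, n_decoys_per_filter = 0, n_up = 0, n_down = 0)
  expect_equal(nrow(simulate_catalog(cfg)), 0)
})

test_that("generators are bit-for-bit reproducible under a fixed seed", {
  cfg <- sim_config(seed = 99, n_lnc_true = 40, n_decoys_per_filter = 3,
                    n_up = 4, n_down = 2, n_genes_cohort = 50,
                    n_samples_cohort = 12, n_associated = 5, k_extreme = 3)
  expect_identical(simulate_catalog(cfg), simulate_catalog(cfg))
  cat0 <- simulate_catalog(cfg)[, c("transcript_id", "length_nt")]
  expect_identical(simulate_paired_counts(cat0, cfg),
                   simulate_paired_counts(cat0, cfg))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_identical(simulate_sequence("noncoding", 500, seed = 5),
                   simulate_sequence("noncoding", 500, seed = 5))
  expect_false(identical(simulate_sequence("noncoding", 500, seed = 5),
                         simulate_sequence("noncoding", 500, seed = 6)))
})

test_that("per-transcript sub-streams make counts invariant to catalog order", {
  cfg <- sim_config(seed = 21, n_lnc_true = 30, n_up = 3, n_down = 2)
  cat0 <- simulate_catalog(cfg)[, c("transcript_id", "length_nt")]
  a <- simulate_paired_counts(cat0, cfg)
  b <- simulate_paired_counts(cat0[sample.int(nrow(cat0)), ], cfg)
  b <- b[match(a$transcript_id, b$transcript_id), ]
  expect_equal(a$met, b$met)
  expect_equal(a$nonmet, b$nonmet)
})

test_that("planting maps are exhaustive and disjoint", {
  cfg <- sim_config(seed = 2, n_lnc_true = 100, n_up = 20, n_down = 10)
  cts <- simulate_paired_counts(
    simulate_catalog(cfg)[, c("transcript_id", "length_nt")], cfg
  )
  expect_equal(sum(cts$truth == "up"), 20)
  expect_equal(sum(cts$truth == "down"), 10)
  expect_equal(sum(cts$truth == "null"), 70)
  expect_true(all(cts$truth %in% c("up", "down", "null")))
})

test_that("sequence generator honors length, alphabet and kind contracts", {
  s <- simulate_sequence("noncoding", 2598, seed = 1)
  expect_equal(nchar(s), 2598)
  expect_false(grepl("[^ACGT]", s))
  cd <- simulate_sequence("coding", 301, seed = 2)
  expect_equal(nchar(cd), 301)
  expect_equal(substr(cd, 1, 3), "ATG")
  expect_error(simulate_sequence("noncoding", 2), "length")
})

test_that("coding-biased and random sequences separate under TESTCODE", {
  seeds <- 1:40
  coding_calls <- vapply(seeds, function(sd) {
    fickett_testcode(simulate_sequence("coding", 900, seed = sd))$classification
  }, character(1))
  noncoding_calls <- vapply(seeds, function(sd) {
    fickett_testcode(simulate_sequence("noncoding", 2598, seed = sd))$classification
  }, character(1))
  expect_gte(mean(coding_calls == "coding"), 0.9)
  expect_gte(mean(noncoding_calls %in% c("noncoding", "no_opinion")), 0.9)
})

test_that("cohort generator plants the anchor association it reports", {
  cfg <- sim_config(seed = 8, n_genes_cohort = 200, n_samples_cohort = 40,
                    n_associated = 15, k_extreme = 5, assoc_effect_sd_units = 3)
  coh <- simulate_cohort(cfg)
  truth <- attr(coh, "truth")
  expect_equal(sum(truth$associated), 15)
  expect_false("ANCHOR" %in% truth$gene_id)
  labels <- dichotomize_by_anchor(coh, k = 5)
  hi <- labels$sample_id[labels$group == "high"]
  lo <- labels$sample_id[labels$group == "low"]
  mat <- as.matrix(coh[match(truth$gene_id, coh$gene_id), c(hi, lo)])
  diffs <- rowMeans(mat[, seq_along(hi)]) - rowMeans(mat[, length(hi) + seq_along(lo)])
  expect_gt(mean(diffs[truth$associated]), 2)   # ~3 SD planted
  expect_lt(abs(mean(diffs[!truth$associated])), 0.5)
})

test_that("zero-noise Ct tables invert exactly and noisy folds stay within propagated error", {
  ct <- simulate_ct_table(c(A = 2, B = 5.3), ct_noise_sd = 0)
  rel <- delta_delta_ct(ct, calibrator = "nonmet")
  val <- validate_candidates(rel)
  expect_equal(val$fold_change[match(c("A", "B"), val$gene_id)], c(2, 5.3))

  noise <- 0.1
  ct1 <- simulate_ct_table(c(A = 1), ct_noise_sd = noise, n_samples = 4,
                           n_replicates = 3, seed = 13)
  v <- validate_candidates(delta_delta_ct(ct1, calibrator = "nonmet"))
  # ddCt group-mean noise: replicate noise /3, target + half for the two
  # averaged references (x1.5), /4 samples, x2 for the two group means
  prop_sd <- noise * sqrt(2 * 1.5 / (3 * 4))
  expect_lt(abs(log2(v$fold_change)), 3 * prop_sd)
})
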