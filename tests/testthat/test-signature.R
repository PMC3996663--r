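test_that("dichotomization labels top/bottom k with deterministic tie-breaks", {
  cfg <- sim_config(seed = 1, n_genes_cohort = 50, n_samples_cohort = 131,
                    n_associated = 5, k_extreme = 20)
  labels <- dichotomize_by_anchor(simulate_cohort(cfg), k = 20)
  expect_equal(unname(table(labels$group)[c("high", "low", "unused")]),
               c(20L, 20L, 91L), ignore_attr = TRUE)

  # fully tied anchor: the split is lexicographic and still 20/20
  tied <- as_cohort(matrix(rnorm(10 * 44), 10), rep(1, 44))
  lt <- dichotomize_by_anchor(tied, k = 20)
  expect_equal(sum(lt$group == "high"), 20)
  expect_equal(sum(lt$group == "low"), 20)
  expect_equal(lt$sample_id[lt$group == "high"], sort(lt$sample_id)[1:20])

  two <- as_cohort(matrix(rnorm(4), 2), c(5, 1))
  l2 <- dichotomize_by_anchor(two, k = 1)
  expect_equal(l2$group[which.max(c(5, 1))], "high")
  expect_error(dichotomize_by_anchor(two, k = 2), "2k")
})

test_that("SAM q-values equal an exhaustive-permutation oracle on a 3v3 toy", {
  set.seed(42)
  X <- matrix(rnorm(10 * 6), nrow = 10)
  X[1:2, 1:3] <- X[1:2, 1:3] + 4   # two strongly shifted genes
  X[3, 4:6] <- X[3, 4:6] + 4       # one shifted the other way
  coh <- as_cohort(X, rep(0, 6))
  labels <- tibble::tibble(sample_id = sprintf("S%02d", 1:6),
                           group = rep(c("high", "low"), each = 3))
  fit <- sam_statistic(coh, labels, n_perm = 1000,
                       s0_method = "percentile", s0_percentile = 0.5,
                       seed = 7)
  expect_true(fit$full_enumeration)
  expect_equal(fit$n_perm, choose(6, 3))
  orc <- oracle_sam(X, 3, s0 = quantile(
    fit$stats$s, 0.5, names = FALSE))
  expect_equal(fit$stats$d, orc$d, tolerance = 1e-12)
  expect_equal(fit$stats$q, orc$q, tolerance = 1e-12)
})

test_that("full enumeration makes the fit seed-independent", {
  set.seed(5)
  coh <- as_cohort(matrix(rnorm(8 * 6), 8), rep(0, 6))
  labels <- tibble::tibble(sample_id = sprintf("S%02d", 1:6),
                           group = rep(c("high", "low"), each = 3))
  f1 <- sam_statistic(coh, labels, n_perm = 100, seed = 1)
  f2 <- sam_statistic(coh, labels, n_perm = 100, seed = 999)
  expect_equal(f1$stats, f2$stats)
})

test_that("d is antisymmetric under group swap and zero for equal group means", {
  set.seed(11)
  coh <- as_cohort(matrix(rnorm(20 * 10), 20), rep(0, 10))
  labels <- tibble::tibble(sample_id = sprintf("S%02d", 1:10),
                           group = rep(c("high", "low"), each = 5))
  swapped <- dplyr::mutate(labels, group = ifelse(group == "high", "low", "high"))
  f <- sam_statistic(coh, labels, n_perm = 300, seed = 3)
  g <- sam_statistic(coh, swapped, n_perm = 300, seed = 3)
  expect_equal(f$stats$d, -g$stats$d)

  flat <- as_cohort(rbind(c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1),
                          matrix(rnorm(5 * 10), 5)), rep(0, 10))
  ff <- sam_statistic(flat, labels, n_perm = 300, seed = 3)
  expect_equal(ff$stats$d[1], 0)
  expect_false("g001" %in% ff$positive_set)
})

test_that("q-values live in [0,1] and are monotone within the positive tail", {
  cfg <- sim_config(seed = 30, n_genes_cohort = 300, n_samples_cohort = 44,
                    n_associated = 25, k_extreme = 6)
  coh <- simulate_cohort(cfg)
  labels <- dichotomize_by_anchor(coh, k = 6)
  fit <- sam_statistic(coh, labels, n_perm = 400, seed = 30)
  expect_true(all(fit$stats$q >= 0 & fit$stats$q <= 1))
  pos <- dplyr::arrange(dplyr::filter(fit$stats, d > 0), dplyr::desc(d))
  expect_true(all(diff(pos$q) >= -1e-12))
  expect_true(all(fit$stats$d[match(fit$positive_set, fit$stats$gene_id)] > 0))
})

test_that("the anchor is excluded from candidates and the signature", {
  cfg <- sim_config(seed = 12, n_genes_cohort = 120, n_samples_cohort = 44,
                    n_associated = 10, k_extreme = 5)
  coh <- simulate_cohort(cfg)
  fit <- sam_statistic(coh, dichotomize_by_anchor(coh, k = 5),
                       n_perm = 200, seed = 12)
  expect_false("ANCHOR" %in% fit$stats$gene_id)
  expect_false("ANCHOR" %in% fit$positive_set)
})

test_that("planted associated genes are recovered with high recall at 3 SD", {
  cfg <- sim_config(seed = 77, n_genes_cohort = 800, n_samples_cohort = 60,
                    n_associated = 40, k_extreme = 10, assoc_effect_sd_units = 3)
  coh <- simulate_cohort(cfg)
  fit <- sam_statistic(coh, dichotomize_by_anchor(coh, k = 10),
                       n_perm = 500, seed = 77)
  truth <- attr(coh, "truth")
  planted <- truth$gene_id[truth$associated]
  expect_gte(mean(planted %in% fit$positive_set), 0.95)
  sig <- select_signature(fit)
  expect_equal(sig$gene_id, fit$positive_set)
  expect_true(all(diff(sig$d) <= 1e-12))
})

test_that("tidy and glance summarize a sam_fit", {
  set.seed(2)
  coh <- as_cohort(matrix(rnorm(6 * 8), 6), rep(0, 8))
  labels <- tibble::tibble(sample_id = sprintf("S%02d", 1:8),
                           group = rep(c("high", "low"), each = 4))
  fit <- sam_statistic(coh, labels, n_perm = 70, seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_true(all(c("gene_id", "d", "s", "q", "positive") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_genes, 6)
  expect_equal(gl$n_positive, length(fit$positive_set))
  expect_s3_class(autoplot(fit), "ggplot")
})
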