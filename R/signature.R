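#' Split cohort samples into high/low anchor-expression groups
#'
#' Labels the `k` samples with the highest anchor expression `high`, the
#' `k` lowest `low`, and the remainder `unused`. Ties at either boundary
#' are broken by sample-id lexicographic order, so the split is
#' deterministic.
#'
#' @param cohort Tibble `gene_id` plus one numeric column per sample
#'   (e.g. from [simulate_cohort()]).
#' @param anchor Anchor gene id; defaults to the cohort's `anchor`
#'   attribute.
#' @param k Samples per extreme group; default 20.
#' @return Tibble `sample_id`, `group` (`"high"`, `"low"`, `"unused"`).
#' @export
dichotomize_by_anchor <- function(cohort, anchor = NULL, k = 20) {
  cohort <- as_tibble(cohort)
  anchor <- anchor %||% attr(cohort, "anchor")
  if (is.null(anchor)) abort("`anchor` must be supplied")
  if (!anchor %in% cohort$gene_id) abort(sprintf("anchor gene %s not in cohort", anchor))
  smp <- sample_columns(cohort, exclude = character())
  if (length(smp) < 2 * k) abort("2k exceeds the number of samples")
  vals <- as.numeric(cohort[cohort$gene_id == anchor, smp][1, ])
  ord <- order(-vals, smp)  # descending anchor, sample id breaks ties
  group <- rep("unused", length(smp))
  group[ord[seq_len(k)]] <- "high"
  group[ord[(length(smp) - k + 1):length(smp)]] <- "low"
  tibble(sample_id = smp, group = group)
}

# pooled two-sample standard error of the mean difference
pooled_se <- function(ss1, ss2, n1, n2) {
  sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
}

# SAM s0 automation: the percentile of the s distribution minimizing the
# coefficient of variation of the d spread across s-percentile windows.
choose_s0 <- function(r, s) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- quantile(s, alphas, names = FALSE)
  breaks <- unique(quantile(s, seq(0, 1, length.out = 101), names = FALSE))
  win <- cut(s, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, mad)
    v <- v[!is.na(v) & v > 0]
    if (length(v) < 2) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

# counts of x >= cut (resp. <= cut) against a sorted vector, ties included
count_ge <- function(cuts, sorted_vals) {
  length(sorted_vals) - findInterval(cuts, sorted_vals, left.open = TRUE)
}
count_le <- function(cuts, sorted_vals) {
  findInterval(cuts, sorted_vals)
}

#' SAM permutation d-statistic with exceedance-based q-values
#'
#' For each gene, computes the SAM relative difference
#' `d = (mean_high - mean_low) / (s + s0)`, where `s` is the pooled
#' two-sample standard error of the mean difference and `s0` is the fudge
#' factor (by default chosen automatically as the percentile of the `s`
#' distribution minimizing the coefficient of variation of `d` across
#' `s`-percentile windows). The null distribution comes from label
#' permutations: all distinct high/low assignments are enumerated when
#' their number does not exceed `n_perm` (making the result
#' seed-independent), otherwise `n_perm` random assignments are drawn.
#'
#' Q-values use SAM's exceedance counting with a median-based FDR: at the
#' cut set by a gene's own `d`, the estimated FDR is the median across
#' permutations of the number of permuted `d` values at or beyond the cut
#' (same tail), divided by the number of genes called at that cut; a
#' gene's q-value is the minimum FDR over all cuts at which it is still
#' called, so q is monotone in the `|d|` ranking within each tail.
#'
#' The positively associated set contains the genes with `d > 0` and
#' `q <= q_threshold_pct / 100`; the anchor gene (and anything in
#' `exclude_genes`) is removed from the candidates before any statistic
#' is computed, so it can never enter its own signature.
#'
#' @param cohort Tibble `gene_id` plus sample columns.
#' @param labels Tibble `sample_id`, `group` from
#'   [dichotomize_by_anchor()] (groups `high`/`low`; `unused` dropped).
#' @param q_threshold_pct Q threshold, in percent; default 0.5 (Q < 0.5%).
#' @param n_perm Number of permutations; default 1000.
#' @param s0_method `"automatic"` or `"percentile"`.
#' @param s0_percentile Percentile of `s` used when
#'   `s0_method = "percentile"`.
#' @param seed Integer seed for sampled permutations.
#' @param exclude_genes Gene ids excluded from candidacy; defaults to the
#'   cohort's anchor attribute.
#' @return Object of class `sam_fit`: per-gene `stats` tibble
#'   (`gene_id`, `d`, `s`, `q`), `s0`, `n_perm` (used), `full_enumeration`,
#'   `seed`, `q_threshold_pct`, `positive_set` (gene ids, descending `d`)
#'   and `dbar` (mean sorted permuted `d`, for the SAM plot).
#' @export
sam_statistic <- function(cohort, labels, q_threshold_pct = 0.5,
                          n_perm = 1000, s0_method = c("automatic", "percentile"),
                          s0_percentile = 0.05, seed = 1L,
                          exclude_genes = NULL) {
  s0_method <- match.arg(s0_method)
  cohort <- as_tibble(cohort)
  exclude_genes <- exclude_genes %||% attr(cohort, "anchor")
  keep <- !cohort$gene_id %in% exclude_genes
  genes <- cohort$gene_id[keep]
  assert_unique_ids(genes, "gene_id")
  hi <- labels$sample_id[labels$group == "high"]
  lo <- labels$sample_id[labels$group == "low"]
  n1 <- length(hi); n2 <- length(lo)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 samples")
  X <- as.matrix(cohort[keep, c(hi, lo)])
  storage.mode(X) <- "double"
  n <- n1 + n2
  is_hi <- seq_len(n) <= n1

  X2 <- X^2
  rs <- rowSums(X); rs2 <- rowSums(X2)
  s1 <- rowSums(X[, is_hi, drop = FALSE]); q1 <- rowSums(X2[, is_hi, drop = FALSE])
  ss1 <- q1 - s1^2 / n1
  ss2 <- (rs2 - q1) - (rs - s1)^2 / n2
  r_obs <- s1 / n1 - (rs - s1) / n2
  s_obs <- pooled_se(pmax(ss1, 0), pmax(ss2, 0), n1, n2)
  s0 <- if (s0_method == "automatic") choose_s0(r_obs, s_obs)
  else quantile(s_obs, s0_percentile, names = FALSE)
  if (s0 == 0 && any(s_obs == 0)) s0 <- max(s0, 1e-8 * max(mean(s_obs), 1))
  d_obs <- r_obs / (s_obs + s0)

  # permutation set: columns give the samples assigned "high"
  n_all <- choose(n, n1)
  full <- n_all <= n_perm
  perm_idx <- if (full) {
    utils::combn(n, n1)
  } else {
    withr::with_seed(sub_seed(seed, "sam-perm"), {
      matrix(replicate(n_perm, sample.int(n, n1)), nrow = n1)
    })
  }
  B <- ncol(perm_idx)
  P <- matrix(0, nrow = n, ncol = B)
  P[cbind(as.vector(perm_idx), rep(seq_len(B), each = n1))] <- 1
  S1 <- X %*% P
  Q1 <- X2 %*% P
  M1 <- S1 / n1
  M2 <- (rs - S1) / n2
  SS1 <- Q1 - S1^2 / n1; SS1[SS1 < 0] <- 0
  SS2 <- (rs2 - Q1) - (rs - S1)^2 / n2; SS2[SS2 < 0] <- 0
  Dstar <- (M1 - M2) / (pooled_se(SS1, SS2, n1, n2) + s0)

  G <- length(d_obs)
  # per-permutation sorted d*, ascending (G x B)
  sorted_cols <- vapply(seq_len(B), function(b) sort.int(Dstar[, b]),
                        numeric(G))
  q <- rep(1, G)

  pos <- which(d_obs > 0)
  if (length(pos) > 0) {
    ordp <- pos[order(-d_obs[pos])]
    cuts <- d_obs[ordp]
    cnt <- vapply(seq_len(B), function(b) count_ge(cuts, sorted_cols[, b]),
                  numeric(length(cuts)))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = length(cuts))
    med_false <- apply(cnt, 1, median)
    called <- count_ge(cuts, sort(d_obs))
    # q = min FDR over all cuts at which the gene is still called
    # (cuts at or below its own d): suffix minimum in descending-d order
    fdr <- pmin(1, med_false / called)
    q[ordp] <- rev(cummin(rev(fdr)))
  }
  neg <- which(d_obs < 0)
  if (length(neg) > 0) {
    ordn <- neg[order(d_obs[neg])]
    cuts <- d_obs[ordn]
    cnt <- vapply(seq_len(B), function(b) count_le(cuts, sorted_cols[, b]),
                  numeric(length(cuts)))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = length(cuts))
    med_false <- apply(cnt, 1, median)
    called <- count_le(cuts, sort(d_obs))
    fdr <- pmin(1, med_false / called)
    q[ordn] <- rev(cummin(rev(fdr)))
  }

  stats_tbl <- tibble(gene_id = genes, d = d_obs, s = s_obs, q = q)
  pos_set <- stats_tbl$gene_id[stats_tbl$d > 0 &
                               stats_tbl$q <= q_threshold_pct / 100]
  pos_set <- pos_set[order(-stats_tbl$d[match(pos_set, stats_tbl$gene_id)])]
  structure(
    list(stats = stats_tbl, s0 = s0, n_perm = B, full_enumeration = full,
         seed = seed, q_threshold_pct = q_threshold_pct,
         positive_set = pos_set, dbar = rowMeans(sorted_cols),
         n_high = n1, n_low = n2),
    class = "sam_fit"
  )
}

#' @export
print.sam_fit <- function(x, ...) {
  cat(sprintf(
    "<sam_fit> %d genes, %d vs %d samples, %d permutations%s, s0 = %.4g\n",
    nrow(x$stats), x$n_high, x$n_low, x$n_perm,
    if (x$full_enumeration) " (full enumeration)" else "", x$s0))
  cat(sprintf("  positively associated at Q <= %.3g%%: %d genes\n",
              x$q_threshold_pct, length(x$positive_set)))
  invisible(x)
}

#' Tidy the per-gene SAM statistics
#'
#' @param x A `sam_fit`.
#' @param ... Unused.
#' @return Tibble `gene_id`, `d`, `s`, `q`, `positive` (in the positive
#'   set?).
#' @export
tidy.sam_fit <- function(x, ...) {
  dplyr::mutate(x$stats, positive = .data$gene_id %in% x$positive_set)
}

#' One-row summary of a SAM fit
#'
#' @param x A `sam_fit`.
#' @param ... Unused.
#' @return One-row tibble with the fudge factor, permutation settings and
#'   positive-set size.
#' @export
glance.sam_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$stats), n_high = x$n_high, n_low = x$n_low,
    s0 = x$s0, n_perm = x$n_perm, full_enumeration = x$full_enumeration,
    q_threshold_pct = x$q_threshold_pct,
    n_positive = length(x$positive_set)
  )
}

#' Extract the positively associated signature of a SAM fit
#'
#' @param fit A `sam_fit`.
#' @return Tibble `gene_id`, `d`, `q`, sorted by descending `d` (the
#'   positively associated expression signature).
#' @export
select_signature <- function(fit) {
  stopifnot(inherits(fit, "sam_fit"))
  out <- dplyr::filter(fit$stats, .data$gene_id %in% fit$positive_set)
  dplyr::select(dplyr::arrange(out, dplyr::desc(.data$d)),
                "gene_id", "d", "q")
}

#' SAM quantile plot of observed vs expected d
#'
#' Observed ordered d-scores against the mean ordered permuted d-scores,
#' with the positively associated genes highlighted.
#'
#' @param object A `sam_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sam_fit <- function(object, ...) {
  ord <- order(object$stats$d)
  df <- tibble(
    expected = object$dbar,
    observed = object$stats$d[ord],
    positive = object$stats$gene_id[ord] %in% object$positive_set
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed,
                                   colour = .data$positive)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "expected d (permutation mean)", y = "observed d",
                  colour = "positive set") +
    ggplot2::theme_minimal()
}
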