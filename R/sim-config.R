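#' Configuration for the synthetic-data generators
#'
#' Bundles and validates every knob of the synthetic-data module. The
#' defaults encode the study conditions the pipeline is exercised under:
#' a 1653-transcript lncRNA catalog with 153 transcripts planted
#' up-regulated at 4-fold and 77 down-regulated at 0.25-fold in a paired
#' two-sample design, and a 10,000-gene by 131-sample expression cohort
#' with 402 genes associated with the anchor transcript at a 3-SD
#' two-group effect.
#'
#' @param seed Integer seed; fixes every generated artifact bit-for-bit.
#' @param n_lnc_true Number of catalog entries passing all lncRNA filters.
#' @param n_decoys_per_filter Number of entries failing exactly one filter,
#'   per filter (coding biotype; excluded small-RNA class; length <= 200).
#' @param n_up,n_down Number of planted up-/down-regulated lncRNAs.
#' @param true_fold_up,true_fold_down Planted linear met/nonmet abundance
#'   ratios for up and down transcripts.
#' @param depth Mapped reads per sample (library size).
#' @param nb_dispersion Negative-binomial dispersion of simulated counts;
#'   0 gives the deterministic zero-noise limit (expected counts, possibly
#'   fractional, so planted ratios are exact).
#' @param n_genes_cohort,n_samples_cohort Cohort dimensions.
#' @param n_associated Number of cohort genes planted as positively
#'   associated with the anchor.
#' @param assoc_effect_sd_units Planted high-anchor vs low-anchor group
#'   mean difference, in within-group SD units.
#' @param k_extreme Number of samples per extreme (top/bottom) anchor group
#'   the association is planted on.
#' @param ct_noise_sd Replicate-level Ct noise SD (cycles) for simulated
#'   qPCR tables.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' sim_config(seed = 1, n_lnc_true = 100, n_up = 5, n_down = 3)
sim_config <- function(seed = 1L,
                       n_lnc_true = 1653L,
                       n_decoys_per_filter = 0L,
                       n_up = 153L,
                       n_down = 77L,
                       true_fold_up = 4,
                       true_fold_down = 0.25,
                       depth = 2e7,
                       nb_dispersion = 0.05,
                       n_genes_cohort = 10000L,
                       n_samples_cohort = 131L,
                       n_associated = 402L,
                       assoc_effect_sd_units = 3,
                       k_extreme = 20L,
                       ct_noise_sd = 0.15) {
  cfg <- list(
    seed = as.integer(seed),
    n_lnc_true = as.integer(n_lnc_true),
    n_decoys_per_filter = as.integer(n_decoys_per_filter),
    n_up = as.integer(n_up),
    n_down = as.integer(n_down),
    true_fold_up = true_fold_up,
    true_fold_down = true_fold_down,
    depth = depth,
    nb_dispersion = nb_dispersion,
    n_genes_cohort = as.integer(n_genes_cohort),
    n_samples_cohort = as.integer(n_samples_cohort),
    n_associated = as.integer(n_associated),
    assoc_effect_sd_units = assoc_effect_sd_units,
    k_extreme = as.integer(k_extreme),
    ct_noise_sd = ct_noise_sd
  )
  counts <- c("n_lnc_true", "n_decoys_per_filter", "n_up", "n_down",
              "n_genes_cohort", "n_samples_cohort", "n_associated", "k_extreme")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) abort(sprintf("`%s` must be a count >= 0", f))
  }
  if (cfg$true_fold_up <= 0 || cfg$true_fold_down <= 0) abort("planted folds must be > 0")
  if (cfg$depth <= 0) abort("`depth` must be > 0")
  if (cfg$nb_dispersion < 0) abort("`nb_dispersion` must be >= 0")
  if (cfg$ct_noise_sd < 0) abort("`ct_noise_sd` must be >= 0")
  if (cfg$n_up + cfg$n_down > cfg$n_lnc_true) {
    abort("n_up + n_down must not exceed n_lnc_true")
  }
  if (cfg$n_associated > cfg$n_genes_cohort) {
    abort("n_associated must not exceed n_genes_cohort")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
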