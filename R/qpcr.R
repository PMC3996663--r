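#' Relative expression by the 2^-ddCt method with dual reference genes
#'
#' Replicate Ct values are averaged per (sample, gene). For each target,
#' `dCt = Ct_target - mean(Ct_refs)` (the arithmetic mean of the
#' reference-gene Cts, equivalent to normalizing expression by their
#' geometric mean and symmetric in the two references),
#' `ddCt = dCt - mean(dCt over calibrator samples)` and
#' `fold_change = 2^-ddCt`, i.e. amplification efficiency fixed at 2.
#' Samples missing any reference measurement are dropped with a warning
#' record.
#'
#' @param cts Long tibble `sample_id`, `group`, `gene_id`, `ct` (one row
#'   per replicate), e.g. from [simulate_ct_table()]. Ct values must lie
#'   in (0, 45).
#' @param targets Target gene ids; defaults to every gene that is not a
#'   reference.
#' @param refs Reference gene ids; default `c("HPRT1", "GAPDH")`.
#' @param calibrator Calibrator group label (or sample id).
#' @return Tibble `sample_id`, `group`, `gene_id`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`, classed `relative_expression`;
#'   dropped samples recorded in the `dropped` attribute.
#' @export
#' @examples
#' ct <- simulate_ct_table(c(GOI = 4), ct_noise_sd = 0)
#' delta_delta_ct(ct, calibrator = "nonmet")$fold_change[1]  # 4
delta_delta_ct <- function(cts, targets = NULL, refs = c("HPRT1", "GAPDH"),
                           calibrator = NULL) {
  cts <- as_tibble(cts)
  stopifnot(all(c("sample_id", "group", "gene_id", "ct") %in% names(cts)))
  if (any(cts$ct <= 0 | cts$ct >= 45)) abort("Ct values must lie in (0, 45)")
  if (is.null(calibrator)) abort("`calibrator` (group label) must be supplied")
  if (!calibrator %in% cts$group) abort(sprintf("calibrator group %s not found", calibrator))
  targets <- targets %||% setdiff(unique(cts$gene_id), refs)
  if (!all(refs %in% cts$gene_id)) abort("reference gene(s) missing from the table")

  mean_ct <- dplyr::summarise(
    dplyr::group_by(cts, .data$sample_id, .data$group, .data$gene_id),
    ct = mean(.data$ct), .groups = "drop"
  )
  ref_ct <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(mean_ct, .data$gene_id %in% refs),
      .data$sample_id
    ),
    ref_ct = mean(.data$ct), n_refs = dplyr::n(), .groups = "drop"
  )
  complete <- ref_ct$sample_id[ref_ct$n_refs == length(refs)]
  dropped <- setdiff(unique(cts$sample_id), complete)
  if (length(dropped) > 0) {
    warn(sprintf("dropping sample(s) without complete reference measurements: %s",
                 paste(dropped, collapse = ", ")))
  }
  tgt <- dplyr::filter(mean_ct, .data$gene_id %in% targets,
                       .data$sample_id %in% complete)
  tgt <- dplyr::left_join(tgt, dplyr::select(ref_ct, "sample_id", "ref_ct"),
                          by = "sample_id")
  tgt <- dplyr::mutate(tgt, delta_ct = .data$ct - .data$ref_ct)
  cal <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(tgt, .data$group == calibrator),
      .data$gene_id
    ),
    cal_dct = mean(.data$delta_ct), .groups = "drop"
  )
  out <- dplyr::left_join(tgt, cal, by = "gene_id")
  if (any(is.na(out$cal_dct))) abort("calibrator measurements missing for some target(s)")
  out <- dplyr::mutate(out,
    delta_delta_ct = .data$delta_ct - .data$cal_dct,
    fold_change = 2^(-.data$delta_delta_ct)
  )
  out <- dplyr::select(out, "sample_id", "group", "gene_id",
                       "delta_ct", "delta_delta_ct", "fold_change")
  attr(out, "calibrator") <- calibrator
  attr(out, "refs") <- refs
  attr(out, "dropped") <- dropped
  class(out) <- c("relative_expression", class(out))
  out
}

#' Validate candidates against a strict fold-change criterion
#'
#' Per target gene, the group fold is `2^-mean(ddCt)` over the samples of
#' `group` (the non-calibrator group by default); a candidate passes iff
#' its fold strictly exceeds `fold_threshold` ("greater than
#' `fold_threshold`-fold"), so a fold of exactly 2 fails the default
#' criterion.
#'
#' @param rel A `relative_expression` tibble from [delta_delta_ct()].
#' @param group Group whose fold is assessed; defaults to the (single)
#'   non-calibrator group.
#' @param fold_threshold Strict threshold; default 2.
#' @return Tibble `gene_id`, `fold_change`, `passes`.
#' @export
validate_candidates <- function(rel, group = NULL, fold_threshold = 2) {
  stopifnot(inherits(rel, "relative_expression"))
  cal <- attr(rel, "calibrator")
  group <- group %||% setdiff(unique(rel$group), cal)
  if (length(group) != 1) abort("specify a single `group` to validate")
  out <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(as_tibble(rel), .data$group == !!group),
      .data$gene_id
    ),
    fold_change = 2^(-mean(.data$delta_delta_ct)), .groups = "drop"
  )
  dplyr::mutate(out, passes = .data$fold_change > fold_threshold)
}

#' Median-center values on the log2 fold scale
#'
#' Subtracts the overall median of `log2(fold_change)` from every value,
#' the shift-based centering used for "median-centered" group displays;
#' centering is idempotent.
#'
#' @param rel A `relative_expression` tibble (or any tibble with a
#'   `fold_change` column).
#' @return The input with an added `log2_fold_centered` column.
#' @export
median_center <- function(rel) {
  stopifnot("fold_change" %in% names(rel))
  lf <- log2(rel$fold_change)
  out <- dplyr::mutate(as_tibble(rel), log2_fold_centered = lf - median(lf))
  attr(out, "calibrator") <- attr(rel, "calibrator")
  class(out) <- unique(c("relative_expression", class(out)))
  out
}

#' Per-group minimum / median / maximum of centered values
#'
#' @param rel Output of [median_center()].
#' @return Tibble `group`, `min`, `median`, `max` of
#'   `log2_fold_centered`.
#' @export
group_range_summary <- function(rel) {
  stopifnot("log2_fold_centered" %in% names(rel))
  dplyr::summarise(
    dplyr::group_by(as_tibble(rel), .data$group),
    min = min(.data$log2_fold_centered),
    median = median(.data$log2_fold_centered),
    max = max(.data$log2_fold_centered),
    .groups = "drop"
  )
}

#' Plot median-centered relative expression by group
#'
#' Points with per-group min-max bars, the display convention of
#' median-centered qPCR group panels.
#'
#' @param object A `relative_expression` tibble (centered automatically
#'   if needed).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relative_expression <- function(object, ...) {
  if (!"log2_fold_centered" %in% names(object)) object <- median_center(object)
  rng <- group_range_summary(object)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$group, .data$log2_fold_centered)) +
    ggplot2::geom_errorbar(data = rng,
                           ggplot2::aes(x = .data$group, ymin = .data$min,
                                        ymax = .data$max),
                           inherit.aes = FALSE, width = 0.2) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.08),
                        alpha = 0.7) +
    ggplot2::facet_wrap(~gene_id) +
    ggplot2::labs(x = NULL, y = "median-centered log2 fold change") +
    ggplot2::theme_minimal()
}
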