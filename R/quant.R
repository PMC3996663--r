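#' Compute RPKM from raw counts
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `rpkm[i, s] = 1e9 * c[i, s] / (N[s] * L[i])`, with `N[s]` the
#' per-sample mapped-read total and `L[i]` the transcript length in nt.
#' `N` is taken from the input (library-size semantics), never recomputed
#' as a column sum, so partial catalogs keep their scale.
#'
#' @param counts Tibble with `transcript_id`, `length_nt` and one numeric
#'   column per sample (e.g. from [simulate_paired_counts()]).
#' @param mapped_total Named numeric vector of per-sample mapped-read
#'   totals; defaults to the `mapped_total` attribute of `counts`.
#' @return Tibble of the same shape with sample columns on the RPKM
#'   scale; attribute `stage = "rpkm"`.
#' @export
#' @examples
#' x <- tibble::tibble(transcript_id = "t1", length_nt = 2000, s1 = 1000)
#' compute_rpkm(x, mapped_total = c(s1 = 1e7))$s1  # 50
compute_rpkm <- function(counts, mapped_total = NULL) {
  counts <- as_tibble(counts)
  stopifnot(all(c("transcript_id", "length_nt") %in% names(counts)))
  mapped_total <- mapped_total %||% attr(counts, "mapped_total")
  if (is.null(mapped_total)) {
    abort("`mapped_total` must be supplied (or carried as an attribute)")
  }
  smp <- sample_columns(counts)
  if (!all(smp %in% names(mapped_total))) {
    abort(sprintf("mapped_total missing for sample(s): %s",
                  paste(setdiff(smp, names(mapped_total)), collapse = ", ")))
  }
  if (any(mapped_total[smp] <= 0)) {
    abort(sprintf("mapped total must be > 0 (sample %s)",
                  smp[which(mapped_total[smp] <= 0)[1]]))
  }
  if (any(counts$length_nt <= 0)) {
    abort(sprintf("zero or negative length for transcript %s",
                  counts$transcript_id[which(counts$length_nt <= 0)[1]]))
  }
  for (s in smp) {
    if (any(counts[[s]] < 0)) abort(sprintf("negative counts in sample %s", s))
    counts[[s]] <- 1e9 * counts[[s]] / (mapped_total[[s]] * counts$length_nt)
  }
  attr(counts, "mapped_total") <- mapped_total
  attr(counts, "stage") <- "rpkm"
  counts
}

#' Normalize each sample to unit root mean square
#'
#' Divides every sample column of an RPKM matrix by that column's root
#' mean square, `sqrt(mean(x^2))`, so each normalized column has RMS 1.
#' Scale-invariant per sample: multiplying a sample's raw counts and its
#' mapped total by the same factor leaves the output unchanged.
#'
#' @param expr An RPKM-stage tibble from [compute_rpkm()].
#' @return The tibble with sample columns rescaled;
#'   attribute `stage = "rms_normalized"`.
#' @export
rms_normalize <- function(expr) {
  expr <- as_tibble(expr)
  if (!identical(attr(expr, "stage"), "rpkm")) {
    abort("`expr` must be an RPKM-stage matrix (run compute_rpkm() first)")
  }
  for (s in sample_columns(expr)) {
    rms <- sqrt(mean(expr[[s]]^2))
    if (rms == 0) abort(sprintf("all-zero sample column %s: RMS undefined", s))
    expr[[s]] <- expr[[s]] / rms
  }
  attr(expr, "stage") <- "rms_normalized"
  expr
}

#' Call differential transcripts between two paired samples by fold change
#'
#' Per-transcript ratio `r = (x_met + pseudocount) / (x_nonmet +
#' pseudocount)` on the RMS-normalized scale, with inclusive threshold
#' calls: `up` iff `r >= fold_threshold`, `down` iff
#' `r <= 1/fold_threshold`, else `none`. With `pseudocount = 0`, a
#' transcript observed only in the met sample is called `up` with an
#' infinite, flagged ratio; a transcript absent from both gets call
#' `none` and an undefined, flagged ratio.
#'
#' @param expr RMS-normalized tibble from [rms_normalize()].
#' @param met,nonmet Sample column names.
#' @param fold_threshold Linear fold threshold (inclusive); default 2.
#' @param pseudocount Added to both values before the ratio; default 0.
#' @return Tibble `transcript_id`, `ratio`, `call`, `ratio_flag`
#'   (`"ok"`, `"infinite"` or `"undefined"`), classed `lnc_de_calls`.
#' @export
paired_fold_change <- function(expr, met = "met", nonmet = "nonmet",
                               fold_threshold = 2, pseudocount = 0) {
  expr <- as_tibble(expr)
  if (!identical(attr(expr, "stage"), "rms_normalized")) {
    abort("`expr` must be RMS-normalized (run rms_normalize() first)")
  }
  if (!all(c(met, nonmet) %in% names(expr))) {
    abort("both sample columns must be present")
  }
  if (fold_threshold <= 1) abort("`fold_threshold` must be > 1")
  a <- expr[[met]] + pseudocount
  b <- expr[[nonmet]] + pseudocount
  ratio <- a / b
  flag <- dplyr::case_when(
    a == 0 & b == 0 ~ "undefined",
    b == 0 ~ "infinite",
    TRUE ~ "ok"
  )
  call <- dplyr::case_when(
    flag == "undefined" ~ "none",
    flag == "infinite" ~ "up",
    ratio >= fold_threshold ~ "up",
    ratio <= 1 / fold_threshold ~ "down",
    TRUE ~ "none"
  )
  out <- tibble(
    transcript_id = expr$transcript_id,
    ratio = ifelse(flag == "undefined", NA_real_, ratio),
    call = call,
    ratio_flag = flag
  )
  if ("truth" %in% names(expr)) out$truth <- expr$truth
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("lnc_de_calls", class(out))
  out
}

#' Plot paired fold-change calls
#'
#' Ranked log2 ratio per transcript, colored by call, with the fold
#' thresholds drawn as horizontal lines.
#'
#' @param object An `lnc_de_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lnc_de_calls <- function(object, ...) {
  thr <- attr(object, "fold_threshold") %||% 2
  d <- dplyr::filter(as_tibble(object), .data$ratio_flag == "ok")
  d <- dplyr::arrange(d, .data$ratio)
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(.data$rank, log2(.data$ratio),
                                  colour = .data$call)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = c(log2(thr), -log2(thr)),
                        linetype = "dashed") +
    ggplot2::labs(x = "transcript rank", y = "log2 met/nonmet ratio",
                  colour = "call") +
    ggplot2::theme_minimal()
}
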