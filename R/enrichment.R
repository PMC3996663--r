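#' One-sided concept enrichment of a gene signature
#'
#' Tests over-representation of a signature in a concept gene set against
#' a stated universe via the 2x2 table
#' `a` (signature and concept), `b` (signature only), `c` (concept only),
#' `d` (neither). The one-sided p-value is the hypergeometric upper tail
#' `P(overlap >= a)`; the odds ratio is `(a*d)/(b*c)`, with the
#' Haldane-Anscombe correction (0.5 added to all four cells) applied only
#' when some cell is zero, and flagged. A concept passes when
#' `p < p_threshold` and `odds_ratio > or_threshold`.
#'
#' Concept members are intersected with the universe before counting; the
#' signature must be a subset of the universe.
#'
#' @param signature Character vector of signature gene ids (or the tibble
#'   from [select_signature()]).
#' @param concept Character vector of concept member gene ids.
#' @param universe Character vector of all eligible gene ids.
#' @param concept_name Optional concept label.
#' @param p_threshold,or_threshold Pass thresholds; defaults `1e-4` and 2.
#' @return One-row tibble `concept`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_one_sided`, `haldane_corrected`, `passes`.
#' @export
#' @examples
#' concept_enrichment(letters[1:5], letters[1:5], letters[1:20])$p_one_sided
#' # 1 / choose(20, 5)
concept_enrichment <- function(signature, concept, universe,
                               concept_name = NA_character_,
                               p_threshold = 1e-4, or_threshold = 2) {
  if (is.data.frame(signature)) signature <- signature$gene_id
  signature <- unique(signature)
  universe <- unique(universe)
  concept <- unique(concept)
  if (length(universe) == 0) abort("`universe` must be non-empty")
  if (length(signature) == 0) abort("`signature` must be non-empty")
  if (!all(signature %in% universe)) abort("signature must be a subset of the universe")
  concept <- intersect(concept, universe)
  a <- length(intersect(signature, concept))
  b <- length(signature) - a
  cc <- length(concept) - a
  d <- length(universe) - a - b - cc
  corrected <- any(c(a, b, cc, d) == 0)
  or <- if (corrected) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  # upper tail P(X >= a), X ~ Hypergeometric(concept, universe, signature)
  p <- phyper(a - 1, length(concept), length(universe) - length(concept),
              length(signature), lower.tail = FALSE)
  tibble(
    concept = concept_name,
    a = a, b = b, c = cc, d = d,
    odds_ratio = or,
    p_one_sided = p,
    haldane_corrected = corrected,
    passes = p < p_threshold & or > or_threshold
  )
}

#' Run a battery of concept enrichments
#'
#' Applies [concept_enrichment()] to every row of a concept table and
#' carries the concept annotations through.
#'
#' @param signature Character vector (or [select_signature()] tibble).
#' @param concepts Tibble with columns `concept` (name), `members`
#'   (list-column of gene-id vectors) and optionally `concept_type`,
#'   `direction` (`"up"`/`"down"`), `study`, `n_samples`.
#' @param universe Character vector of eligible gene ids.
#' @param p_threshold,or_threshold Pass thresholds.
#' @return Tibble with one enrichment row per concept, classed
#'   `enrichment_tbl`.
#' @export
enrich_battery <- function(signature, concepts, universe,
                           p_threshold = 1e-4, or_threshold = 2) {
  stopifnot(all(c("concept", "members") %in% names(concepts)))
  res <- purrr::map2_dfr(concepts$concept, concepts$members, function(nm, mem) {
    concept_enrichment(signature, mem, universe, concept_name = nm,
                       p_threshold = p_threshold, or_threshold = or_threshold)
  })
  extra <- dplyr::select(concepts, -"members")
  out <- dplyr::left_join(res, extra, by = "concept")
  class(out) <- c("enrichment_tbl", class(out))
  out
}

#' Summarize an enrichment battery by concept type
#'
#' One row per concept type: how many studies pass in each direction, the
#' p-value and odds-ratio ranges among passers, and the total sample
#' count, mirroring the layout of a concept-summary table
#' (e.g. "16/0  3.1E-116-1.7E-6  2.4-13.4  928"). Empty ranges are
#' rendered as an em dash.
#'
#' @param results An `enrichment_tbl` from [enrich_battery()] with
#'   `concept_type` and `direction` columns.
#' @return Tibble `concept_type`, `studies_up`, `studies_down`,
#'   `p_range`, `or_range`, `total_samples`.
#' @export
summarize_battery <- function(results) {
  stopifnot(all(c("concept_type", "direction") %in% names(results)))
  fmt_range <- function(x, fmt) {
    if (length(x) == 0) return("—")
    if (length(x) == 1 || min(x) == max(x)) return(sprintf(fmt, min(x)))
    paste0(sprintf(fmt, min(x)), "-", sprintf(fmt, max(x)))
  }
  dplyr::summarise(
    dplyr::group_by(as_tibble(results), .data$concept_type),
    studies_up = sum(.data$passes & .data$direction == "up"),
    studies_down = sum(.data$passes & .data$direction == "down"),
    p_range = fmt_range(.data$p_one_sided[.data$passes], "%.1E"),
    or_range = fmt_range(.data$odds_ratio[.data$passes], "%.1f"),
    total_samples = if ("n_samples" %in% names(results)) {
      sum(.data$n_samples)
    } else NA_integer_,
    .groups = "drop"
  )
}

#' Plot an enrichment battery
#'
#' Odds ratio (log scale) against -log10 p per concept, with the pass
#' thresholds drawn.
#'
#' @param object An `enrichment_tbl`.
#' @param p_threshold,or_threshold Thresholds to draw; defaults `1e-4`, 2.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_tbl <- function(object, p_threshold = 1e-4,
                                    or_threshold = 2, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$odds_ratio,
                                  -log10(.data$p_one_sided),
                                  colour = .data$passes,
                                  label = .data$concept)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = or_threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio", y = "-log10 one-sided p",
                  colour = "passes") +
    ggplot2::theme_minimal()
}

#' Read GMT-style concept sets
#'
#' One set per line: name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return Tibble `concept`, `description`, `members` (list-column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    concept = vapply(parts, `[`, character(1), 1),
    description = vapply(parts, function(p) if (length(p) > 1) p[2] else "", character(1)),
    members = purrr::map(parts, function(p) if (length(p) > 2) p[-(1:2)] else character())
  )
}

#' Write concept sets in GMT format
#'
#' @param concepts Tibble `concept`, `members` (list-column), optional
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(concepts, path) {
  desc <- if ("description" %in% names(concepts)) concepts$description else
    rep("", nrow(concepts))
  lines <- purrr::pmap_chr(
    list(concepts$concept, desc, concepts$members),
    function(nm, dd, mem) paste(c(nm, dd, mem), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
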