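#' Classify a transcript catalog into lncRNAs and excluded categories
#'
#' Applies the lncRNA filter chain to an annotated catalog: a transcript
#' passes iff its biotype is not protein-coding, is not one of the
#' excluded small-RNA classes, and its length is strictly greater than
#' `min_length_nt` (a length of exactly 200 nt fails the default filter).
#' A rejected transcript is labelled with the first failing filter, in the
#' fixed order coding, excluded class, too short. Pseudogenes are retained
#' as lncRNA candidates: the biotype is taken from the annotation, never
#' inferred from sequence, and coding-potential assessment is a separate
#' downstream step ([fickett_testcode()], [scan_orfs()]).
#'
#' @param records Tibble with columns `transcript_id`, `biotype`,
#'   `length_nt` (ids unique, lengths positive).
#' @param min_length_nt Minimum length, exclusive; default 200.
#' @param excluded_classes Biotypes excluded as known small-RNA classes;
#'   defaults to [excluded_small_rna_classes()].
#' @return The input tibble with added columns `passes` (logical) and
#'   `reject_reason` (`NA`, `"coding"`, `"excluded_class"` or
#'   `"too_short"`), classed `lnc_catalog`.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   transcript_id = c("a", "b", "c"),
#'   biotype = c("noncoding_other", "protein_coding", "miRNA"),
#'   length_nt = c(300L, 5000L, 22L)
#' )
#' classify_transcripts(recs)
classify_transcripts <- function(records, min_length_nt = 200,
                                 excluded_classes = excluded_small_rna_classes()) {
  records <- as_tibble(records)
  stopifnot(all(c("transcript_id", "biotype", "length_nt") %in% names(records)))
  assert_unique_ids(records$transcript_id)
  if (any(records$length_nt <= 0)) abort("transcript lengths must be positive")
  bad <- setdiff(unique(records$biotype), lnc_biotypes())
  if (length(bad) > 0) {
    abort(sprintf("unrecognized biotype(s): %s", paste(bad, collapse = ", ")))
  }
  reason <- dplyr::case_when(
    records$biotype == "protein_coding" ~ "coding",
    records$biotype %in% excluded_classes ~ "excluded_class",
    records$length_nt <= min_length_nt ~ "too_short",
    TRUE ~ NA_character_
  )
  out <- dplyr::mutate(records,
    passes = is.na(reason),
    reject_reason = reason
  )
  class(out) <- c("lnc_catalog", class(out))
  out
}

#' Summarize a classified catalog
#'
#' @param object An `lnc_catalog` from [classify_transcripts()].
#' @param ... Unused.
#' @return Tibble with one row per outcome (`pass` or a rejection reason)
#'   and its transcript count.
#' @export
summary.lnc_catalog <- function(object, ...) {
  out <- dplyr::count(
    as_tibble(object),
    outcome = ifelse(.data$passes, "pass", .data$reject_reason)
  )
  dplyr::arrange(out, dplyr::desc(.data$outcome == "pass"), .data$outcome)
}

#' Extract the passing lncRNA set of a classified catalog
#'
#' @param catalog An `lnc_catalog`.
#' @return Tibble of passing records (without the classification columns).
#' @export
passing_lncrnas <- function(catalog) {
  out <- dplyr::filter(as_tibble(catalog), .data$passes)
  dplyr::select(out, -"passes", -"reject_reason")
}
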