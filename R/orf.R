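check_dna <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence)) abort("`sequence` must be a single string")
  s <- toupper(sequence)
  if (grepl("[^ACGT]", s)) abort("sequence contains non-ACGT characters")
  s
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

# ORFs in one frame of one strand: start-anchored (first ATG after the
# previous in-frame stop) to the in-frame stop, stop codon included.
scan_frame <- function(s, frame, min_orf_len_nt, report_nested) {
  n <- nchar(s)
  if (frame + 1 > n - 2) return(NULL)
  starts <- seq(frame + 1, n - 2, by = 3)
  codons <- substring(s, starts, starts + 2)
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  is_atg <- codons == "ATG"
  res <- list()
  open <- integer(0)  # codon indices of pending ATGs
  for (i in seq_along(codons)) {
    if (is_stop[i]) {
      if (length(open) > 0) {
        anchors <- if (report_nested) open else open[1]
        for (a in anchors) {
          len <- (i - a + 1) * 3
          if (len >= min_orf_len_nt) {
            res[[length(res) + 1]] <- c(start = starts[a] - 1L,
                                        end = starts[i] + 2L, length_nt = len)
          }
        }
        open <- integer(0)
      }
    } else if (is_atg[i]) {
      if (report_nested || length(open) == 0) open <- c(open, i)
    }
  }
  if (length(res) == 0) return(NULL)
  out <- as_tibble(do.call(rbind, res))
  out$frame <- frame
  out
}

#' Six-frame open-reading-frame scan of a transcript
#'
#' An ORF is an ATG through the next in-frame stop codon (TAA/TAG/TGA),
#' stop included in the length; only maximal ORFs are reported (the first
#' ATG after the previous in-frame stop anchors each ORF) unless
#' `report_nested = TRUE`, which also reports ORFs anchored at internal
#' ATGs. With `both_strands = TRUE` all six reading frames are scanned;
#' minus-strand ORFs are reported in minus-strand coordinates (positions
#' along the reverse complement). Coordinates are 0-based, half-open.
#'
#' @param sequence Single A/C/G/T string (case-insensitive).
#' @param min_orf_len_nt Minimum ORF length in nt, stop included;
#'   default 75.
#' @param both_strands Scan the reverse complement too? Default `TRUE`.
#' @param report_nested Also report ORFs starting at internal ATGs?
#'   Default `FALSE`.
#' @return List of class `orf_scan` with elements `orfs` (tibble `strand`,
#'   `frame`, `start`, `end`, `length_nt`), `max_orf_len_nt`,
#'   `transcript_len` and `min_orf_len_nt`.
#' @export
#' @examples
#' scan_orfs("ATGAAATAA", min_orf_len_nt = 9)$max_orf_len_nt  # 9
scan_orfs <- function(sequence, min_orf_len_nt = 75, both_strands = TRUE,
                      report_nested = FALSE) {
  s <- check_dna(sequence)
  strands <- if (both_strands) c("+", "-") else "+"
  orfs <- purrr::map_dfr(strands, function(st) {
    seq_st <- if (st == "+") s else revcomp(s)
    out <- purrr::map_dfr(0:2, scan_frame, s = seq_st,
                          min_orf_len_nt = min_orf_len_nt,
                          report_nested = report_nested)
    if (nrow(out) > 0) out$strand <- st
    out
  })
  if (nrow(orfs) == 0) {
    orfs <- tibble(strand = character(), frame = integer(),
                   start = integer(), end = integer(), length_nt = integer())
  } else {
    orfs <- dplyr::select(orfs, "strand", "frame", "start", "end", "length_nt")
    orfs <- dplyr::arrange(orfs, dplyr::desc(.data$length_nt))
  }
  structure(
    list(orfs = orfs,
         max_orf_len_nt = if (nrow(orfs) > 0) max(orfs$length_nt) else 0L,
         transcript_len = nchar(s),
         min_orf_len_nt = min_orf_len_nt),
    class = "orf_scan"
  )
}

#' @export
print.orf_scan <- function(x, ...) {
  cat(sprintf("<orf_scan> %d nt transcript, %d ORF(s) >= %d nt, max %d nt\n",
              x$transcript_len, nrow(x$orfs), x$min_orf_len_nt,
              x$max_orf_len_nt))
  invisible(x)
}

#' Project a minus-strand interval onto plus-strand coordinates
#'
#' @param start,end 0-based half-open interval on the minus strand.
#' @param transcript_len Transcript length in nt.
#' @return Numeric vector `c(start, end)` on the plus strand.
#' @export
minus_to_plus <- function(start, end, transcript_len) {
  c(start = transcript_len - end, end = transcript_len - start)
}

#' Fraction of a transcript covered by any reported ORF
#'
#' Union semantics: every position covered by at least one ORF, on either
#' strand (minus-strand ORFs are projected onto plus-strand coordinates),
#' counted once, divided by the transcript length. Never exceeds 1 and is
#' monotone non-increasing in the minimum ORF length used by the scan.
#'
#' @param scan An `orf_scan` from [scan_orfs()].
#' @param transcript_len Transcript length; defaults to the scan's.
#' @return A real in `[0, 1]`.
#' @export
coding_fraction <- function(scan, transcript_len = scan$transcript_len) {
  stopifnot(inherits(scan, "orf_scan"))
  if (nrow(scan$orfs) == 0) return(0)
  covered <- logical(transcript_len)
  for (i in seq_len(nrow(scan$orfs))) {
    o <- scan$orfs[i, ]
    iv <- if (o$strand == "+") c(o$start, o$end) else {
      minus_to_plus(o$start, o$end, transcript_len)
    }
    covered[(iv[1] + 1):iv[2]] <- TRUE
  }
  sum(covered) / transcript_len
}

#' Coding-potential report for a set of sequences
#'
#' One row per record: transcript length, maximal ORF length and coding
#' fraction from the six-frame scan, and the Fickett TESTCODE score with
#' its classification.
#'
#' @param sequences Named character vector (e.g. from [read_fasta()]).
#' @param min_orf_len_nt Passed to [scan_orfs()].
#' @return Tibble `transcript_id`, `length_nt`, `max_orf_len_nt`,
#'   `coding_fraction`, `testcode_score`, `classification`.
#' @export
coding_potential_report <- function(sequences, min_orf_len_nt = 75) {
  purrr::imap_dfr(sequences, function(s, id) {
    sc <- scan_orfs(s, min_orf_len_nt = min_orf_len_nt)
    fk <- fickett_testcode(s)
    tibble(
      transcript_id = id,
      length_nt = nchar(s),
      max_orf_len_nt = sc$max_orf_len_nt,
      coding_fraction = coding_fraction(sc),
      testcode_score = fk$testcode_score,
      classification = fk$classification
    )
  })
}
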