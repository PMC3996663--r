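# Published TESTCODE lookup tables (Fickett 1982): probability-of-coding
# weights for the position and composition parameters of each base.
# Thresholds are descending; a parameter value >= threshold[k] (first
# match) selects probability k.

.fickett_position_thresholds <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
.fickett_content_thresholds  <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)

.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_content_weight  <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

fickett_lookup <- function(value, thresholds, probs) {
  probs[which(value >= thresholds)[1]]
}

#' Fickett TESTCODE coding-potential statistic
#'
#' Computes the eight TESTCODE parameters of a nucleotide sequence: for
#' each base, a position parameter
#' `max(n1, n2, n3) / (min(n1, n2, n3) + 1)` where `nk` counts the base
#' at sequence positions congruent to `k` modulo 3, and a composition
#' parameter (the base's overall frequency). Each parameter is converted
#' to a probability of coding through the published lookup tables and the
#' eight probabilities are combined with the published weights into the
#' TESTCODE score. Classification: score >= 0.95 is `coding`,
#' score <= 0.74 is `noncoding`, otherwise `no_opinion`. The statistic is
#' case-insensitive; sequences shorter than 200 nt are allowed but
#' flagged low-confidence.
#'
#' @param sequence Single A/C/G/T string.
#' @return List of class `fickett_score`: `position_parameter` and
#'   `composition_parameter` (named per base), `testcode_score`,
#'   `classification`, `low_confidence`.
#' @export
#' @examples
#' fickett_testcode(strrep("ACGT", 300))$classification
fickett_testcode <- function(sequence) {
  s <- check_dna(sequence)
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  bases <- c("A", "C", "G", "T")
  pos_class <- (seq_len(n) - 1L) %% 3L  # positions == 1, 2, 0 (mod 3)
  pos_par <- vapply(bases, function(b) {
    cnt <- vapply(0:2, function(k) sum(chars == b & pos_class == k), numeric(1))
    max(cnt) / (min(cnt) + 1)
  }, numeric(1))
  comp_par <- vapply(bases, function(b) sum(chars == b) / n, numeric(1))
  score <- 0
  for (b in bases) {
    score <- score +
      .fickett_position_weight[[b]] *
        fickett_lookup(pos_par[[b]], .fickett_position_thresholds,
                       .fickett_position_prob[[b]]) +
      .fickett_content_weight[[b]] *
        fickett_lookup(comp_par[[b]], .fickett_content_thresholds,
                       .fickett_content_prob[[b]])
  }
  classification <- if (score >= 0.95) "coding"
  else if (score <= 0.74) "noncoding"
  else "no_opinion"
  structure(
    list(position_parameter = pos_par,
         composition_parameter = comp_par,
         testcode_score = score,
         classification = classification,
         low_confidence = n < 200),
    class = "fickett_score"
  )
}

#' @export
print.fickett_score <- function(x, ...) {
  cat(sprintf("<fickett_score> %.3f (%s)%s\n", x$testcode_score,
              x$classification,
              if (x$low_confidence) " [low confidence: < 200 nt]" else ""))
  invisible(x)
}
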