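# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations (loops, enumeration, closed forms),
# kept separate from the package implementation they cross-check.

# brute-force maximal ORF length: walk every ATG position on both strands
# and step codon by codon to the first in-frame stop (stop included)
oracle_orf_max <- function(sequence, min_len = 75) {
  revcomp_chr <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  best <- 0L
  for (s in c(toupper(sequence), revcomp_chr(toupper(sequence)))) {
    n <- nchar(s)
    for (i in seq_len(max(n - 2, 0))) {
      if (substr(s, i, i + 2) == "ATG") {
        j <- i + 3
        while (j + 2 <= n) {
          cod <- substr(s, j, j + 2)
          if (cod %in% c("TAA", "TAG", "TGA")) {
            len <- j + 2 - i + 1
            if (len >= min_len && len > best) best <- len
            break
          }
          j <- j + 3
        }
      }
    }
  }
  best
}

# hypergeometric upper-tail P(overlap >= a) by direct summation of
# choose() terms
oracle_hyper_tail <- function(a, n_sig, n_con, n_uni) {
  ks <- a:min(n_sig, n_con)
  sum(choose(n_con, ks) * choose(n_uni - n_con, n_sig - ks)) /
    choose(n_uni, n_sig)
}

# spreadsheet-style RPKM recomputation, one cell at a time
oracle_rpkm <- function(counts_mat, lengths, totals) {
  out <- counts_mat
  for (i in seq_len(nrow(counts_mat))) {
    for (s in seq_len(ncol(counts_mat))) {
      out[i, s] <- 1e9 * counts_mat[i, s] / (totals[s] * lengths[i])
    }
  }
  out
}

# exhaustive SAM for small balanced designs: enumerate every distinct
# high-group assignment, recompute d for each, and apply the
# median-exceedance q-value definition with plain loops.
# X: genes x samples matrix, first n1 columns observed "high".
oracle_sam <- function(X, n1, s0) {
  n <- ncol(X)
  d_of <- function(hi_idx) {
    lo_idx <- setdiff(seq_len(n), hi_idx)
    apply(X, 1, function(x) {
      m1 <- mean(x[hi_idx]); m2 <- mean(x[lo_idx])
      ss <- sum((x[hi_idx] - m1)^2) + sum((x[lo_idx] - m2)^2)
      s <- sqrt((1 / length(hi_idx) + 1 / length(lo_idx)) * ss / (n - 2))
      (m1 - m2) / (s + s0)
    })
  }
  d_obs <- d_of(seq_len(n1))
  perms <- utils::combn(n, n1)
  dstar <- apply(perms, 2, d_of)  # genes x B
  q <- rep(1, length(d_obs))
  for (i in seq_along(d_obs)) {
    if (d_obs[i] == 0) next
    feas <- if (d_obs[i] > 0) which(d_obs > 0 & d_obs <= d_obs[i])
    else which(d_obs < 0 & d_obs >= d_obs[i])
    fdrs <- vapply(d_obs[feas], function(cut) {
      if (cut > 0) {
        false_b <- apply(dstar, 2, function(col) sum(col >= cut))
        called <- sum(d_obs >= cut)
      } else {
        false_b <- apply(dstar, 2, function(col) sum(col <= cut))
        called <- sum(d_obs <= cut)
      }
      min(1, median(false_b) / called)
    }, numeric(1))
    q[i] <- min(fdrs)
  }
  list(d = d_obs, q = q)
}

# small wide cohort tibble from a matrix, anchor in the first row
as_cohort <- function(mat, anchor_vals) {
  s <- ncol(mat)
  out <- tibble::as_tibble(
    stats::setNames(as.data.frame(rbind(anchor_vals, mat)),
                    sprintf("S%02d", seq_len(s)))
  )
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = c("ANCHOR", sprintf("g%03d", seq_len(nrow(mat))))),
    out
  )
  attr(out, "anchor") <- "ANCHOR"
  out
}

# rms-normalized two-sample expression tibble with the given met/nonmet
# ratios: symmetric construction so both columns share the same RMS
expr_with_ratios <- function(ratios, ids = sprintf("t%d", seq_along(ratios))) {
  out <- tibble::tibble(
    transcript_id = c(ids, paste0(ids, "_mirror")),
    length_nt = 1000L,
    met = c(ratios, rep(1, length(ratios))),
    nonmet = c(rep(1, length(ratios)), ratios)
  )
  attr(out, "mapped_total") <- c(met = 1e6, nonmet = 1e6)
  attr(out, "stage") <- "rpkm"
  rms_normalize(out)
}
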