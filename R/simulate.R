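#' @include sim-config.R
NULL

#' Transcript biotypes recognized by the catalog filter
#'
#' `lnc_biotypes()` returns every recognized biotype;
#' `excluded_small_rna_classes()` the non-coding classes excluded from
#' lncRNA candidacy (ribosomal, transfer, micro, small nucleolar and other
#' small RNAs). The excluded list is a documented superset that can be
#' extended through the `excluded_classes` argument of
#' [classify_transcripts()].
#'
#' @return Character vector of biotype names.
#' @export
lnc_biotypes <- function() {
  c("protein_coding", excluded_small_rna_classes(),
    "noncoding_other", "pseudogene")
}

#' @rdname lnc_biotypes
#' @export
excluded_small_rna_classes <- function() {
  c("rRNA", "tRNA", "miRNA", "snoRNA", "other_small_rna")
}

#' Simulate an annotated transcript catalog with planted filter outcomes
#'
#' Generates `n_lnc_true` transcripts that pass all three lncRNA filters
#' (non-coding biotype, not a small-RNA class, length strictly greater
#' than 200 nt) and, per filter, `n_decoys_per_filter` decoys that fail
#' exactly that one filter: a protein-coding biotype, an excluded
#' small-RNA biotype, or a length of at most 200 nt.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `transcript_id`, `biotype`, `length_nt`
#'   and `planted_class` (one of `"lncRNA"`, `"decoy_coding"`,
#'   `"decoy_small_rna"`, `"decoy_short"`).
#' @export
#' @examples
#' cat <- simulate_catalog(sim_config(seed = 1, n_lnc_true = 10,
#'                                    n_decoys_per_filter = 2,
#'                                    n_up = 0, n_down = 0))
#' table(cat$planted_class)
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_lnc_true
  d <- config$n_decoys_per_filter
  withr::with_seed(sub_seed(config$seed, "catalog"), {
    passing <- tibble(
      transcript_id = sprintf("LNC%05d", seq_len(n)),
      biotype = sample(c("noncoding_other", "pseudogene"), n,
                       replace = TRUE, prob = c(0.9, 0.1)),
      length_nt = sample(201:10000, n, replace = TRUE),
      planted_class = "lncRNA"
    )
    decoys <- dplyr::bind_rows(
      tibble(
        transcript_id = sprintf("PC%05d", seq_len(d)),
        biotype = "protein_coding",
        length_nt = sample(201:10000, d, replace = TRUE),
        planted_class = "decoy_coding"
      ),
      tibble(
        transcript_id = sprintf("SRNA%05d", seq_len(d)),
        biotype = sample(excluded_small_rna_classes(), d, replace = TRUE),
        length_nt = sample(201:10000, d, replace = TRUE),
        planted_class = "decoy_small_rna"
      ),
      tibble(
        transcript_id = sprintf("SHORT%05d", seq_len(d)),
        biotype = sample(c("noncoding_other", "pseudogene"), d, replace = TRUE),
        length_nt = sample(50:200, d, replace = TRUE),
        planted_class = "decoy_short"
      )
    )
    out <- dplyr::bind_rows(passing, decoys)
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

#' Simulate paired metastatic/non-metastatic counts with planted fold changes
#'
#' Draws one count per transcript for each of two samples (`met`,
#' `nonmet`) from a negative binomial around
#' `abundance x length_nt x depth / 1e9`, i.e. the expected count implied
#' by an RPKM-scale abundance. `n_up` transcripts are planted with a true
#' met/nonmet abundance ratio of `true_fold_up`, `n_down` with
#' `true_fold_down`; all other transcripts sit at ratio 1.
#'
#' Baseline abundances are log-uniform: planted differential transcripts
#' at 10-100 RPKM and the null background at 10-10^4 RPKM, so a stable
#' high-abundance background dominates each sample's root mean square and
#' anchors the normalization.
#'
#' Every transcript draws from its own random sub-stream keyed on
#' `(seed, transcript_id)`, so reordering the catalog cannot change any
#' transcript's counts. With `nb_dispersion = 0` the exact expected counts
#' (possibly fractional) are returned, so planted ratios survive the
#' pipeline exactly.
#'
#' @param catalog Tibble with `transcript_id` and `length_nt` (e.g. the
#'   passing set of [classify_transcripts()]).
#' @param config A [sim_config()]; uses `n_up`, `n_down`, folds, `depth`,
#'   `nb_dispersion`, `seed`.
#' @return A tibble `transcript_id`, `length_nt`, `truth` (`"up"`,
#'   `"down"`, `"null"`; the exhaustive, disjoint planting map), `met`,
#'   `nonmet`; attribute `mapped_total` holds the per-sample library
#'   sizes.
#' @export
simulate_paired_counts <- function(catalog, config) {
  stopifnot(inherits(config, "sim_config"))
  catalog <- as_tibble(catalog)
  stopifnot(all(c("transcript_id", "length_nt") %in% names(catalog)))
  assert_unique_ids(catalog$transcript_id)
  n <- nrow(catalog)
  if (config$n_up + config$n_down > n) {
    abort("n_up + n_down exceeds the number of catalog transcripts")
  }
  # planting is drawn over the id-sorted catalog, so the planted set (and
  # hence every transcript's draws) is invariant to catalog row order
  truth <- rep("null", n)
  ids_sorted <- sort(catalog$transcript_id)
  planted_ids <- withr::with_seed(
    sub_seed(config$seed, "planting"),
    ids_sorted[sample.int(n, config$n_up + config$n_down)]
  )
  truth[match(planted_ids[seq_len(config$n_up)], catalog$transcript_id)] <- "up"
  if (config$n_down > 0) {
    truth[match(planted_ids[config$n_up + seq_len(config$n_down)],
                catalog$transcript_id)] <- "down"
  }
  fold <- c(up = config$true_fold_up, down = config$true_fold_down, null = 1)[truth]

  base_seed <- sub_seed(config$seed, "counts")
  phi <- config$nb_dispersion
  draw_pair <- function(id, len, fld, is_null) {
    withr::with_seed(sub_seed(base_seed, id), {
      a <- if (is_null) 10^stats::runif(1, 1, 4) else 10^stats::runif(1, 1, 2)
      e_nonmet <- a * len * config$depth / 1e9
      e_met <- e_nonmet * fld
      if (phi == 0) {
        c(e_met, e_nonmet)
      } else {
        c(rnbinom(1, mu = e_met, size = 1 / phi),
          rnbinom(1, mu = e_nonmet, size = 1 / phi))
      }
    })
  }
  cts <- purrr::pmap(
    list(catalog$transcript_id, catalog$length_nt, fold, truth == "null"),
    draw_pair
  )
  out <- tibble(
    transcript_id = catalog$transcript_id,
    length_nt = catalog$length_nt,
    truth = truth,
    met = vapply(cts, `[`, numeric(1), 1),
    nonmet = vapply(cts, `[`, numeric(1), 2)
  )
  attr(out, "mapped_total") <- c(met = config$depth, nonmet = config$depth)
  attr(out, "stage") <- "counts"
  out
}

#' Simulate an expression cohort with a planted anchor-associated signature
#'
#' Builds a genes-by-samples expression tibble containing one designated
#' high-variance anchor gene plus `n_genes_cohort` candidate genes.
#' `n_associated` candidates are planted positively associated with the
#' anchor as a two-group mean shift: samples in the top-`k_extreme` anchor
#' group get `assoc_effect_sd_units` within-group SDs added, matching the
#' dichotomized design the signature stage analyzes. All other genes are
#' independent standard-normal noise.
#'
#' @param config A [sim_config()].
#' @return A tibble `gene_id` plus one numeric column per sample, with
#'   attributes `anchor` (the anchor gene id) and `truth` (tibble
#'   `gene_id`, `associated`). The anchor row itself is excluded from
#'   `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples_cohort < 2 * config$k_extreme) {
    abort("n_samples_cohort must be at least 2 * k_extreme")
  }
  g <- config$n_genes_cohort
  s <- config$n_samples_cohort
  withr::with_seed(sub_seed(config$seed, "cohort"), {
    sample_ids <- sprintf("S%03d", seq_len(s))
    anchor_expr <- rnorm(s, mean = 0, sd = 2)
    high <- order(anchor_expr, decreasing = TRUE)[seq_len(config$k_extreme)]
    mat <- matrix(rnorm(g * s), nrow = g, ncol = s)
    assoc <- sample.int(g, config$n_associated)
    mat[assoc, high] <- mat[assoc, high] + config$assoc_effect_sd_units
    gene_ids <- sprintf("G%05d", seq_len(g))
    out <- dplyr::bind_cols(
      tibble(gene_id = c("ANCHOR", gene_ids)),
      as_tibble(setNames(
        as.data.frame(rbind(anchor_expr, mat)),
        sample_ids
      ))
    )
    attr(out, "anchor") <- "ANCHOR"
    attr(out, "truth") <- tibble(
      gene_id = gene_ids,
      associated = seq_len(g) %in% assoc
    )
    out
  })
}

# strongly 3-periodic base preferences used for coding-biased sequences
.codon_pos_prefs <- list(
  c(A = 0.30, C = 0.15, G = 0.45, T = 0.10),
  c(A = 0.45, C = 0.25, G = 0.10, T = 0.20),
  c(A = 0.20, C = 0.30, G = 0.35, T = 0.15)
)

#' Simulate a nucleotide sequence, coding-biased or non-coding
#'
#' Non-coding sequences are i.i.d. uniform over A/C/G/T. Coding-biased
#' sequences are an ATG followed by codons sampled from a strongly
#' 3-periodic skewed base-usage table (stop codons excluded), a TAA stop,
#' and, when `length` is not a multiple of 3, a short uniform tail so the
#' returned string has exactly the requested length.
#'
#' @param kind `"coding"` or `"noncoding"`.
#' @param length Sequence length in nucleotides (>= 3; coding requires >= 9).
#' @param seed Integer seed.
#' @return A single uppercase character string over ACGT.
#' @export
#' @examples
#' nchar(simulate_sequence("noncoding", 2598, seed = 1))
simulate_sequence <- function(kind = c("noncoding", "coding"), length, seed = 1L) {
  kind <- match.arg(kind)
  if (length < 3) abort("`length` must be >= 3")
  bases <- c("A", "C", "G", "T")
  withr::with_seed(sub_seed(seed, paste0("seq-", kind)), {
    if (kind == "noncoding") {
      return(paste(sample(bases, length, replace = TRUE), collapse = ""))
    }
    if (length < 9) abort("coding-biased sequences need length >= 9")
    n_body <- (length - 6) %/% 3
    tail_n <- length - 6 - 3 * n_body
    codons <- replicate(n_body, {
      repeat {
        cod <- paste(vapply(.codon_pos_prefs, function(p) {
          sample(bases, 1, prob = p[bases])
        }, character(1)), collapse = "")
        if (!cod %in% c("TAA", "TAG", "TGA")) break
      }
      cod
    })
    paste0("ATG", paste(codons, collapse = ""), "TAA",
           paste(sample(bases, tail_n, replace = TRUE), collapse = ""))
  })
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Inverse model of the 2^-ddCt method: for each target gene,
#' `Ct = base_ct - log2(expression) + noise`, where expression is the
#' planted fold in the case group and 1 in the calibrator group. Two
#' reference genes have group-independent expression. With
#' `ct_noise_sd = 0`, [delta_delta_ct()] recovers each planted fold
#' exactly.
#'
#' @param planted_folds Named numeric vector (or tibble `gene_id`, `fold`)
#'   of planted linear fold changes, all > 0.
#' @param case_group,calibrator_group Group labels.
#' @param n_samples Samples per group.
#' @param n_replicates Technical Ct replicates per (sample, gene).
#' @param ct_noise_sd Replicate Ct noise SD in cycles.
#' @param ref_genes Named numeric vector of reference genes and their base
#'   Ct values.
#' @param base_ct Base Ct of every target gene at expression 1.
#' @param seed Integer seed.
#' @return Long tibble `sample_id`, `group`, `gene_id`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(planted_folds,
                              case_group = "met",
                              calibrator_group = "nonmet",
                              n_samples = 3L,
                              n_replicates = 3L,
                              ct_noise_sd = 0,
                              ref_genes = c(HPRT1 = 22, GAPDH = 20),
                              base_ct = 28,
                              seed = 1L) {
  if (is.data.frame(planted_folds)) {
    planted_folds <- setNames(planted_folds$fold, planted_folds$gene_id)
  }
  if (any(planted_folds <= 0)) abort("planted folds must be > 0")
  if (ct_noise_sd < 0) abort("`ct_noise_sd` must be >= 0")
  groups <- c(case_group, calibrator_group)
  grid <- tidyr::expand_grid(
    group = groups,
    sample = seq_len(n_samples),
    gene_id = c(names(planted_folds), names(ref_genes)),
    replicate = seq_len(n_replicates)
  )
  grid$sample_id <- sprintf("%s_%d", grid$group, grid$sample)
  expr <- ifelse(
    grid$gene_id %in% names(ref_genes), 1,
    ifelse(grid$group == case_group, planted_folds[grid$gene_id], 1)
  )
  base <- ifelse(grid$gene_id %in% names(ref_genes),
                 ref_genes[grid$gene_id], base_ct)
  ct <- withr::with_seed(
    sub_seed(seed, "ct"),
    base - log2(expr) + rnorm(nrow(grid), sd = ct_noise_sd)
  )
  tibble(
    sample_id = grid$sample_id,
    group = grid$group,
    gene_id = grid$gene_id,
    replicate = grid$replicate,
    ct = ct
  )
}

#' RNA-seq ratios of the qPCR validation candidate set
#'
#' Seven differentially modulated lncRNAs carried into qPCR validation:
#' the four most up-regulated transcripts plus three further selections,
#' every one with a paired RNA-seq ratio above 2. The figure these
#' candidates come from reports bar heights, not numbers, so the ratios
#' here are synthetic stand-ins chosen to respect the described ordering
#' (the anchor transcript among the most up-regulated, of similar
#' magnitude to H19 and PCGEM1) and the stated property that all seven
#' exceed 2-fold.
#'
#' @return Tibble `gene_id`, `rnaseq_ratio`.
#' @export
validated_candidate_folds <- function() {
  tibble(
    gene_id = c("PCAT18", "H19", "PCGEM1", "LINC461_1",
                "LINC461_3", "LNC_C6", "LNC_C7"),
    rnaseq_ratio = c(8.9, 8.1, 7.6, 6.2, 5.0, 3.4, 2.7)
  )
}

#' Write simulated sequences to FASTA
#'
#' @param sequences Named character vector of nucleotide strings.
#' @param path Output FASTA path (wrapped at 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Read a (multi-record) FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}
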