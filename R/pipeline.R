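#' Configuration for an end-to-end pipeline run
#'
#' Collects paths, stage toggles and every numeric knob of the pipeline.
#' Stages run in the fixed order simulate, classify, quantify, de,
#' codpot, signature, enrich, qpcr; later stages read the TSV/FASTA
#' outputs of earlier ones from `outdir`.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Global seed, fanned out to per-stage sub-seeds by stable
#'   hashing of the stage names, so adding or removing a stage never
#'   perturbs another stage's draws.
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param stages Character vector of stages to run.
#' @param min_length_nt,fold_threshold,min_orf_len_nt,k,q_threshold_pct,n_perm,p_threshold,or_threshold
#'   Stage knobs (see the stage functions).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = NULL,
                            stages = c("simulate", "classify", "quantify",
                                       "de", "codpot", "signature",
                                       "enrich", "qpcr"),
                            min_length_nt = 200, fold_threshold = 2,
                            min_orf_len_nt = 75, k = 20,
                            q_threshold_pct = 0.5, n_perm = 1000,
                            p_threshold = 1e-4, or_threshold = 2) {
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    sim = sim %||% sim_config(seed = seed),
    stages = stages,
    min_length_nt = min_length_nt, fold_threshold = fold_threshold,
    min_orf_len_nt = min_orf_len_nt, k = k,
    q_threshold_pct = q_threshold_pct, n_perm = n_perm,
    p_threshold = p_threshold, or_threshold = or_threshold
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  # hash the analysis parameters only, not where the outputs land
  x <- unclass(config)
  x$outdir <- NULL
  sub_seed(0L, paste(deparse(x), collapse = ""))
}

read_provenance_meta <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", hdr), ": ", fixed = TRUE)
  setNames(
    lapply(kv, function(x) paste(x[-1], collapse = ": ")),
    vapply(kv, `[`, character(1), 1)
  )
}

pipeline_path <- function(config, file) file.path(config$outdir, file)

require_input <- function(config, stage, file, produced_by) {
  p <- pipeline_path(config, file)
  if (!file.exists(p)) {
    abort(sprintf("stage '%s' requires %s (produced by stage '%s', which did not run)",
                  stage, file, produced_by))
  }
  p
}

#' Run the pipeline end-to-end
#'
#' Orchestrates the stages over a shared output directory. Every output
#' TSV carries a provenance header (tool version, config hash, stage
#' seed); given identical configuration and inputs the run is
#' deterministic and idempotent, so running twice produces byte-identical
#' outputs. A stage failure aborts the run, leaves a
#' `<stage>.failed` marker next to any partial outputs, and names the
#' stage in the error.
#'
#' @param config A [pipeline_config()].
#' @return A run report: list with per-stage record counts, outputs and
#'   status, also serialized to `run_report.yaml` in the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  meta0 <- list(config_hash = config_hash(config), seed = config$seed)
  report <- list(seed = config$seed, config_hash = config_hash(config),
                 stages = list())
  all_stages <- c("simulate", "classify", "quantify", "de", "codpot",
                  "signature", "enrich", "qpcr")
  for (stage in all_stages) {
    if (!stage %in% config$stages) {
      report$stages[[stage]] <- list(status = "skipped")
      next
    }
    seed_s <- sub_seed(config$seed, paste0("stage-", stage))
    meta <- c(meta0, list(stage_seed = seed_s))
    rec <- tryCatch(
      run_stage(stage, config, seed_s, meta),
      error = function(e) {
        file.create(pipeline_path(config, paste0(stage, ".failed")))
        abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
      }
    )
    report$stages[[stage]] <- c(list(status = "ok"), rec)
  }
  yaml::write_yaml(report, pipeline_path(config, "run_report.yaml"))
  invisible(report)
}

run_stage <- function(stage, config, seed_s, meta) {
  switch(stage,
    simulate = stage_simulate(config, seed_s, meta),
    classify = {
      p <- require_input(config, "classify", "catalog.tsv", "simulate")
      cat_tbl <- read_tsv_quiet(p)
      cls <- classify_transcripts(cat_tbl, min_length_nt = config$min_length_nt)
      write_tsv_provenance(as_tibble(cls), pipeline_path(config, "classified.tsv"), meta)
      list(n_records = nrow(cls), n_passing = sum(cls$passes),
           outputs = "classified.tsv")
    },
    quantify = {
      p <- require_input(config, "quantify", "counts.tsv", "simulate")
      m <- read_provenance_meta(p)
      counts <- read_tsv_quiet(p)
      attr(counts, "mapped_total") <- c(met = as.numeric(m$mapped_total_met),
                                        nonmet = as.numeric(m$mapped_total_nonmet))
      attr(counts, "stage") <- "counts"
      expr <- rms_normalize(compute_rpkm(counts))
      write_tsv_provenance(expr, pipeline_path(config, "expression.tsv"), meta)
      list(n_records = nrow(expr), outputs = "expression.tsv")
    },
    de = {
      p <- require_input(config, "de", "expression.tsv", "quantify")
      expr <- read_tsv_quiet(p)
      attr(expr, "stage") <- "rms_normalized"
      calls <- paired_fold_change(expr, fold_threshold = config$fold_threshold)
      write_tsv_provenance(as_tibble(calls), pipeline_path(config, "de_calls.tsv"), meta)
      list(n_records = nrow(calls),
           n_up = sum(calls$call == "up"), n_down = sum(calls$call == "down"),
           outputs = "de_calls.tsv")
    },
    codpot = {
      p <- require_input(config, "codpot", "transcripts.fa", "simulate")
      seqs <- read_fasta(p)
      rep_tbl <- coding_potential_report(seqs, min_orf_len_nt = config$min_orf_len_nt)
      write_tsv_provenance(rep_tbl, pipeline_path(config, "coding_potential.tsv"), meta)
      list(n_records = nrow(rep_tbl), outputs = "coding_potential.tsv")
    },
    signature = {
      p <- require_input(config, "signature", "cohort.tsv", "simulate")
      cohort <- read_tsv_quiet(p)
      attr(cohort, "anchor") <- "ANCHOR"
      labels <- dichotomize_by_anchor(cohort, k = config$k)
      fit <- sam_statistic(cohort, labels,
                           q_threshold_pct = config$q_threshold_pct,
                           n_perm = config$n_perm, seed = seed_s)
      sig <- select_signature(fit)
      write_tsv_provenance(tidy(fit), pipeline_path(config, "sam_stats.tsv"), meta)
      write_tsv_provenance(sig, pipeline_path(config, "signature.tsv"), meta)
      list(n_records = nrow(fit$stats), n_positive = nrow(sig),
           s0 = fit$s0, outputs = c("sam_stats.tsv", "signature.tsv"))
    },
    enrich = {
      ps <- require_input(config, "enrich", "signature.tsv", "signature")
      pg <- require_input(config, "enrich", "concepts.gmt", "simulate")
      pc <- require_input(config, "enrich", "cohort.tsv", "simulate")
      sig <- read_tsv_quiet(ps)$gene_id
      concepts <- read_gmt(pg)
      concepts$concept_type <- sub("_(up|down)_\\d+$", "", concepts$concept)
      concepts$direction <- ifelse(grepl("_down_", concepts$concept), "down", "up")
      universe <- setdiff(read_tsv_quiet(pc)$gene_id, "ANCHOR")
      if (length(sig) == 0) {
        res <- tibble(); smry <- tibble()
      } else {
        res <- enrich_battery(sig, concepts, universe,
                              p_threshold = config$p_threshold,
                              or_threshold = config$or_threshold)
        smry <- summarize_battery(res)
      }
      write_tsv_provenance(as_tibble(res), pipeline_path(config, "enrichment.tsv"), meta)
      write_tsv_provenance(smry, pipeline_path(config, "enrichment_summary.tsv"), meta)
      list(n_records = nrow(res), n_passing = sum(res$passes %||% logical()),
           outputs = c("enrichment.tsv", "enrichment_summary.tsv"))
    },
    qpcr = {
      p <- require_input(config, "qpcr", "ct.tsv", "simulate")
      cts <- read_tsv_quiet(p)
      rel <- delta_delta_ct(cts, calibrator = "nonmet")
      val <- validate_candidates(rel, fold_threshold = config$fold_threshold)
      write_tsv_provenance(as_tibble(rel), pipeline_path(config, "qpcr_folds.tsv"), meta)
      write_tsv_provenance(val, pipeline_path(config, "qpcr_validation.tsv"), meta)
      list(n_records = nrow(rel), n_validated = sum(val$passes),
           outputs = c("qpcr_folds.tsv", "qpcr_validation.tsv"))
    },
    abort(sprintf("unknown stage '%s'", stage))
  )
}

stage_simulate <- function(config, seed_s, meta) {
  sim <- config$sim
  catalog <- simulate_catalog(sim)
  write_tsv_provenance(catalog, pipeline_path(config, "catalog.tsv"), meta)

  lnc <- dplyr::filter(catalog, .data$planted_class == "lncRNA")
  counts <- simulate_paired_counts(
    dplyr::select(lnc, "transcript_id", "length_nt"), sim
  )
  mt <- attr(counts, "mapped_total")
  write_tsv_provenance(
    counts, pipeline_path(config, "counts.tsv"),
    c(meta, list(mapped_total_met = mt[["met"]],
                 mapped_total_nonmet = mt[["nonmet"]]))
  )

  seqs <- c(
    lnc_noncoding_1 = simulate_sequence("noncoding", 2598, seed = sub_seed(seed_s, "s1")),
    lnc_noncoding_2 = simulate_sequence("noncoding", 1200, seed = sub_seed(seed_s, "s2")),
    coding_control = simulate_sequence("coding", 1500, seed = sub_seed(seed_s, "s3"))
  )
  write_fasta(seqs, pipeline_path(config, "transcripts.fa"))

  cohort <- simulate_cohort(sim)
  write_tsv_provenance(cohort, pipeline_path(config, "cohort.tsv"), meta)
  truth <- attr(cohort, "truth")
  write_tsv_provenance(truth, pipeline_path(config, "cohort_truth.tsv"), meta)

  # concept battery with a planted pass pattern: concepts drawn mostly from
  # the associated set should pass, pure-noise concepts should not
  assoc <- truth$gene_id[truth$associated]
  nulls <- truth$gene_id[!truth$associated]
  concepts <- withr::with_seed(sub_seed(seed_s, "concepts"), tibble(
    concept = c("planted_up_1", "planted_up_2", "noise_up_1", "noise_down_1"),
    description = c("mostly planted-associated genes",
                    "mostly planted-associated genes",
                    "independent noise genes", "independent noise genes"),
    members = list(
      c(sample(assoc, min(150, length(assoc))), sample(nulls, 50)),
      c(sample(assoc, min(100, length(assoc))), sample(nulls, 100)),
      sample(nulls, 200),
      sample(nulls, 200)
    )
  ))
  write_gmt(concepts, pipeline_path(config, "concepts.gmt"))

  cts <- simulate_ct_table(
    setNames(validated_candidate_folds()$rnaseq_ratio,
             validated_candidate_folds()$gene_id),
    ct_noise_sd = sim$ct_noise_sd, seed = sub_seed(seed_s, "ct")
  )
  write_tsv_provenance(cts, pipeline_path(config, "ct.tsv"), meta)

  list(n_records = nrow(catalog),
       outputs = c("catalog.tsv", "counts.tsv", "transcripts.fa",
                   "cohort.tsv", "cohort_truth.tsv", "concepts.gmt", "ct.tsv"))
}
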