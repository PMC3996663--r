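#' Derive a reproducible sub-seed from a seed and a stream key
#'
#' Streams random-number use by component: a polynomial rolling hash of
#' `key` folded into `seed`, reduced modulo 2^31 - 1 so the result is a
#' valid R integer seed. Used to give every simulated transcript, stage and
#' acceptance target its own independent stream, so e.g. reordering a
#' catalog cannot change any transcript's draws.
#'
#' @param seed Integer base seed.
#' @param key Character or integer stream identifier.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' sub_seed(1, "counts") != sub_seed(1, "cohort")
sub_seed <- function(seed, key) {
  stopifnot(length(seed) == 1, is.finite(seed), length(key) == 1)
  m <- 2147483647
  h <- as.double(abs(as.integer(seed)) %% m)
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# value columns of a wide expression/count tibble: numeric columns that are
# not structural (length, truth labels are chr anyway)
sample_columns <- function(x, exclude = c("length_nt")) {
  nm <- names(x)[vapply(x, is.numeric, logical(1))]
  setdiff(nm, exclude)
}

assert_unique_ids <- function(ids, what = "transcript_id") {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate %s: %s", what, paste(head(dup, 5), collapse = ", ")))
  }
  invisible(ids)
}

# write a tibble as TSV with '#key: value' provenance header lines
write_tsv_provenance <- function(x, path, meta = list()) {
  meta <- c(list(tool = paste0("lncseek ", as.character(utils::packageVersion("lncseek")))), meta)
  hdr <- sprintf("#%s: %s", names(meta), vapply(meta, as.character, character(1)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  body <- readr::format_tsv(x)
  writeLines(sub("\n$", "", body), con)
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE, ...)
}
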