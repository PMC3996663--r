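test_that("minimal and degenerate ORF cases follow the definition", {
  s <- scan_orfs("ATGAAATAA", min_orf_len_nt = 9)
  expect_equal(s$max_orf_len_nt, 9)  # stop codon included in the length
  plus <- s$orfs[s$orfs$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(c(plus$start, plus$end), c(0, 9))

  expect_equal(scan_orfs("CCCCCCCCCCCC")$max_orf_len_nt, 0)  # no ATG
  expect_equal(nrow(scan_orfs("ATGAAACCC")$orfs), 0)         # no in-frame stop
  expect_equal(nrow(scan_orfs("AC", min_orf_len_nt = 3)$orfs), 0)
  expect_error(scan_orfs("ATGNNNTAA"), "non-ACGT")
  expect_equal(scan_orfs("atgaaataa", min_orf_len_nt = 9)$max_orf_len_nt, 9)
})

test_that("six-frame scan agrees with a position-by-position brute-force scanner", {
  for (sd in 1:20) {
    s <- simulate_sequence("noncoding", 2598, seed = sd)
    expect_equal(scan_orfs(s)$max_orf_len_nt, oracle_orf_max(s),
                 info = sprintf("seed %d", sd))
  }
})

test_that("minus-strand ORFs equal plus-strand ORFs of the reverse complement", {
  s <- simulate_sequence("noncoding", 900, seed = 3)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  minus <- scan_orfs(s)$orfs
  minus <- minus[minus$strand == "-", c("frame", "start", "end", "length_nt")]
  plus_of_rc <- scan_orfs(rc, both_strands = FALSE)$orfs
  plus_of_rc <- plus_of_rc[, c("frame", "start", "end", "length_nt")]
  expect_equal(dplyr::arrange(minus, start), dplyr::arrange(plus_of_rc, start))
})

test_that("coding fraction uses union coverage and reproduces the 267/2598 arithmetic", {
  expect_equal(coding_fraction(scan_orfs("CCCCCCCCC")), 0)

  # single 267-nt ORF in a 2598-nt transcript: 267/2598 ~ 0.1028
  body <- paste(rep("GCA", 87), collapse = "")           # 261 nt, no ATG/stop
  orf <- paste0("ATG", body, "TAA")                      # 267 nt
  pad_l <- paste(rep("C", 1200), collapse = "")
  pad_r <- paste(rep("C", 2598 - 1200 - 267), collapse = "")
  s <- paste0(pad_l, orf, pad_r)
  sc <- scan_orfs(s, both_strands = FALSE)
  expect_equal(sc$max_orf_len_nt, 267)
  expect_equal(coding_fraction(sc), 267 / 2598, tolerance = 1e-12)

  # overlapping ORFs on opposite strands are counted once
  s2 <- "ATGAAATAA"
  sc2 <- scan_orfs(s2, min_orf_len_nt = 6)
  fr <- coding_fraction(sc2)
  expect_lte(fr, 1)
  expect_equal(fr, length(unique(unlist(lapply(seq_len(nrow(sc2$orfs)), function(i) {
    o <- sc2$orfs[i, ]
    iv <- if (o$strand == "+") c(o$start, o$end) else minus_to_plus(o$start, o$end, 9)
    (iv[1] + 1):iv[2]
  })))) / 9)
})

test_that("coding fraction is monotone non-increasing in the minimum ORF length", {
  s <- simulate_sequence("noncoding", 1500, seed = 11)
  fr <- vapply(c(30, 75, 150, 300), function(ml) {
    coding_fraction(scan_orfs(s, min_orf_len_nt = ml))
  }, numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("TESTCODE parameters and score match a hand application of the definition", {
  fk <- fickett_testcode(strrep("ACGT", 300))
  # every base occurs 100 times in each frame: position parameter
  # 100 / (100 + 1); composition parameter 0.25 for all four bases
  expect_equal(unname(fk$position_parameter), rep(100 / 101, 4))
  expect_equal(unname(fk$composition_parameter), rep(0.25, 4))
  # table lookups: position value < 1.1 -> (0.22, 0.23, 0.08, 0.09);
  # content 0.25 -> (0.62, 0.59, 0.64, 0.55); weighted sum:
  expected <- sum(c(0.26, 0.18, 0.31, 0.33) * c(0.22, 0.23, 0.08, 0.09)) +
    sum(c(0.11, 0.12, 0.15, 0.14) * c(0.62, 0.59, 0.64, 0.55))
  expect_equal(fk$testcode_score, expected, tolerance = 1e-12)
  expect_equal(fk$classification, "noncoding")
})

test_that("TESTCODE is case-insensitive and applies the fixed cutoffs", {
  s <- simulate_sequence("noncoding", 600, seed = 4)
  expect_equal(fickett_testcode(tolower(s))$testcode_score,
               fickett_testcode(s)$testcode_score)
  expect_true(fickett_testcode("ACG")$low_confidence)
  expect_error(fickett_testcode("ACGU"), "non-ACGT")
})

test_that("coding potential report combines scan and score per record", {
  seqs <- c(nc = simulate_sequence("noncoding", 800, seed = 1),
            cod = simulate_sequence("coding", 801, seed = 1))
  rep_tbl <- coding_potential_report(seqs)
  expect_equal(rep_tbl$transcript_id, c("nc", "cod"))
  expect_equal(rep_tbl$length_nt, c(800, 801))
  expect_gte(rep_tbl$max_orf_len_nt[2], 750)  # planted single long ORF
  expect_equal(rep_tbl$classification[2], "coding")
})

test_that("FASTA round-trip preserves wrapped sequences", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(a = simulate_sequence("noncoding", 150, seed = 2),
            b = simulate_sequence("noncoding", 61, seed = 3))
  write_fasta(seqs, tmp)
  expect_identical(read_fasta(tmp), seqs)
})
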