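test_that("read_msa parses FASTA, normalises case and dots, checks shape", {
  path <- write_fasta(c("a", "b", "c"), c("MKV", "mrv", "MK."))
  aln <- read_msa(path)
  expect_s3_class(aln, "fsa_alignment")
  expect_equal(nrow(aln), 3L)
  expect_equal(alignment_width(aln), 3L)
  expect_equal(aln$seq, c("MKV", "MRV", "MK-"))
  expect_equal(reference_sequence(aln), "MKV")

  ragged <- write_fasta(c("a", "b"), c("MKV", "MKVA"))
  expect_error(read_msa(ragged), class = "fsa_width_error")
  expect_error(read_msa(ragged), "width 4")

  bad <- write_fasta(c("a", "b"), c("MKV", "MBV"))
  err <- expect_error(read_msa(bad), class = "fsa_alphabet_error")
  expect_match(conditionMessage(err), "'B'.*column 2")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_msa(empty), class = "fsa_empty_input_error")
})

test_that("alignment validates the reference index", {
  expect_error(alignment("a", "MKV", reference_index = 2),
               class = "fsa_input_error")
  expect_error(alignment(character(), character()),
               class = "fsa_empty_input_error")
})

test_that("design-dialect FASTA honours the chain policy", {
  path <- write_fasta(
    c("sample=1, score=1.2, seq_recovery=0.5", "sample=2, score=1.3"),
    c("AAAA/CCCC", "DDDD/EEEE")
  )
  first <- read_mpnn_fasta(path, chain_policy = "first_chain")
  expect_equal(first$seq, c("AAAA", "DDDD"))
  expect_equal(first$id, c("sample=1", "sample=2"))

  pooled <- read_mpnn_fasta(path, chain_policy = "pool_all_chains")
  expect_equal(pooled$seq, c("AAAA", "CCCC", "DDDD", "EEEE"))

  conc <- read_mpnn_fasta(path, chain_policy = "concatenate")
  expect_equal(conc$seq, c("AAAACCCC", "DDDDEEEE"))

  uneq <- write_fasta(c("x", "y"), c("AAAA/CC", "DDD/EE"))
  expect_error(read_mpnn_fasta(uneq, chain_policy = "first_chain"),
               class = "fsa_width_error")
})

test_that("pool_all_chains yields one row per chain over mixed chain counts", {
  path <- write_fasta(c("r1", "r2", "r3"), c("AAA/CCC/GGG", "TTT", "MMM/KKK"))
  pooled <- read_mpnn_fasta(path, chain_policy = "pool_all_chains")
  expect_equal(nrow(pooled), 3L + 1L + 2L)
})

test_that("a many-record design file keeps one row per record under first_chain", {
  n <- 1000L
  path <- write_fasta(
    paste0("sample=", seq_len(n), ", score=1.0"),
    rep("MKVL/MKVL", n)
  )
  aln <- read_mpnn_fasta(path, chain_policy = "first_chain")
  expect_equal(nrow(aln), n)
  expect_equal(alignment_width(aln), 4L)
})

test_that("the psiblast-dialect reader recovers the fixture numbers exactly", {
  pssm <- read_psiblast_pssm(example_pssm_path())
  expect_equal(pssm_length(pssm), 3L)
  expect_equal(pssm$query, c("M", "K", "V"))
  # position 1: all percentage mass on M
  expect_equal(pssm$freq[1, "M"], 1.0)
  expect_equal(sum(pssm$freq[1, ]), 1.0)
  expect_equal(pssm$logodds[1, "M"], 8)
  expect_equal(pssm$logodds[1, "D"], -5)
  # position 2 literal cells
  expect_equal(pssm$percent[2, c("R", "Q", "K", "S", "T")],
               c(R = 20, Q = 10, K = 50, S = 10, T = 10))
  expect_equal(pssm$freq[2, "K"], 0.5)
  expect_equal(pssm$info, c(4.32, 1.23, 0.87))
  expect_equal(pssm$weights, c(1.00, 0.95, 0.90))
  expect_true(all(abs(rowSums(pssm$freq) - 1) < 1e-6))
})

test_that("malformed PSSM files raise typed errors", {
  lines <- readLines(example_pssm_path())
  truncated <- tempfile()
  writeLines(lines[1:3], truncated)  # header present, no rows
  expect_error(read_psiblast_pssm(truncated), class = "fsa_format_error")

  # strip the percentage block from header and rows
  one_block <- tempfile()
  hdr <- "            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V"
  row <- "    1 M    -2  -3  -4  -5  -3  -2  -4  -5  -3   1   2  -3   8  -1  -5  -4  -2  -4  -3   0"
  writeLines(c("", "header", hdr, row), one_block)
  expect_error(read_psiblast_pssm(one_block), class = "fsa_format_error")

  corrupt <- tempfile()
  bad <- sub(" 100 ", " 1x0 ", lines)
  writeLines(bad, corrupt)
  err <- expect_error(read_psiblast_pssm(corrupt), class = "fsa_parse_error")
  expect_match(conditionMessage(err), "Line 4")
})

test_that("PSSM built from an alignment matches the closed-form frequencies", {
  # all-A column, no pseudocount: point mass, maximal information
  aln <- alignment(c("r", "a", "b"), c("AC", "AC", "AC"))
  pssm <- pssm_from_alignment(aln, pseudocount = 0)
  expect_equal(pssm$freq[1, "A"], 1)
  expect_equal(pssm$info[1], log2(20))

  # one residue of each kind: uniform column, zero information
  alphabet <- colnames(pssm$freq)
  aln20 <- alignment(paste0("s", 1:20), alphabet)
  p20 <- pssm_from_alignment(aln20, pseudocount = 0)
  expect_equal(p20$info[1], 0)

  # 5-sequence column (3 D, 2 E), pseudocount 1, uniform background:
  # p(D) = (3 + 1/20) / 6, p(E) = (2 + 1/20) / 6, others (1/20) / 6
  aln5 <- alignment(paste0("s", 1:5), c("D", "D", "D", "E", "E"))
  p5 <- pssm_from_alignment(aln5, pseudocount = 1)
  expect_equal(p5$freq[1, "D"], (3 + 0.05) / 6)
  expect_equal(p5$freq[1, "E"], (2 + 0.05) / 6)
  expect_equal(p5$freq[1, "A"], 0.05 / 6)
  expect_equal(p5$info[1], oracle_info(p5$freq[1, ]))
  expect_equal(p5$logodds[1, "D"], log2(p5$freq[1, "D"] * 20))
})

test_that("reference-gapped columns are dropped and empty columns error", {
  aln <- alignment(c("r", "s"), c("M-V", "MKV"))
  pssm <- pssm_from_alignment(aln)
  expect_equal(pssm_length(pssm), 2L)
  expect_equal(pssm$query, c("M", "V"))

  bad <- alignment(c("r", "s"), c("MX", "MX"))
  expect_error(pssm_from_alignment(bad), class = "fsa_undefined_column_error")
  expect_error(pssm_from_alignment(bad), "position\\(s\\) 2")
})

test_that("low-coverage columns are flagged but still computed", {
  aln <- alignment(c("r", "s1", "s2", "s3"), c("MK", "M-", "M-", "M-"))
  pssm <- pssm_from_alignment(aln)
  expect_equal(pssm$low_coverage, c(FALSE, TRUE))
  expect_equal(sum(pssm$freq[2, ]), 1)
})

test_that("frequency rows sum to one for any positive pseudocount", {
  for (seed in 1:5) {
    aln <- random_alignment(n = 8, L = 12, gap_prob = 0.15, seed = seed)
    for (pc in c(0.1, 1, 5)) {
      pssm <- pssm_from_alignment(aln, pseudocount = pc)
      expect_true(all(abs(rowSums(pssm$freq) - 1) < 1e-9))
    }
  }
})

test_that("information content decreases monotonically toward the uniform column", {
  p0 <- c(0.7, 0.2, 0.1, rep(0, 17))
  u <- rep(1 / 20, 20)
  lambdas <- seq(0, 1, by = 0.1)
  infos <- vapply(lambdas, function(l) oracle_info((1 - l) * p0 + l * u), numeric(1))
  expect_true(all(diff(infos) <= 1e-12))
  # and the package computes the same quantity from a synthetic alignment
  aln <- alignment(paste0("s", 1:10), c(rep("A", 7), rep("C", 2), "D"))
  pssm <- pssm_from_alignment(aln, pseudocount = 0)
  expect_equal(pssm$info[1], oracle_info(c(0.7, 0.2, 0.1)))
})

test_that("tidy and glance views of a PSSM are consistent", {
  pssm <- read_psiblast_pssm(example_pssm_path())
  td <- tidy(pssm)
  expect_equal(nrow(td), 3L * 20L)
  expect_equal(td$freq[td$position == 1 & td$aa == "M"], 1.0)
  gl <- glance(pssm)
  expect_equal(gl$n_positions, 3L)
  expect_equal(gl$source, "psiblast_file")
})
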