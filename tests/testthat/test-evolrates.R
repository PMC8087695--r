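test_that("global alignment reproduces hand-checked scores", {
  a <- globalAlign("ACGT", "ACGT")
  expect_equal(a$score, 4)
  expect_equal(a$aligned_a, "ACGT")
  expect_equal(a$aligned_b, "ACGT")

  a <- globalAlign("ACGTACGT", "ACGAACGT")
  expect_equal(a$score, 6)  # 7 matches - 1 mismatch, no gaps
  expect_false(grepl("-", a$aligned_a, fixed = TRUE))

  a <- globalAlign("AAAA", "AA")
  expect_equal(a$score, 2 - 2 - 0.5)  # two matches, one 2-bp gap
  expect_equal(nchar(a$aligned_a), 4)

  expect_error(globalAlign("", "ACGT"), "non-empty")
})

test_that("alignment ungaps back to its inputs and score matches columns", {
  set.seed(11)
  for (i in 1:20) {
    a <- randDna(sample(5:40, 1)); b <- randDna(sample(5:40, 1))
    al <- globalAlign(a, b)
    expect_identical(gsub("-", "", al$aligned_a, fixed = TRUE), a)
    expect_identical(gsub("-", "", al$aligned_b, fixed = TRUE), b)
    ca <- strsplit(al$aligned_a, "")[[1]]; cb <- strsplit(al$aligned_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
  }
})

test_that("Gotoh score equals exhaustive enumeration on short pairs", {
  set.seed(42)
  for (i in 1:60) {
    a <- randDna(sample(1:8, 1)); b <- randDna(sample(1:8, 1))
    expect_equal(globalAlign(a, b)$score, oracleAlignScore(a, b),
                 info = paste(a, b))
  }
})

test_that("Gotoh score agrees with Biostrings pairwiseAlignment", {
  # Biostrings charges gapOpening + L * gapExtension; ours charges
  # gap_open + (L-1) * gap_extend, so opening 1.5 / extension 0.5 matches
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  set.seed(7)
  for (i in 1:15) {
    a <- randDna(sample(20:120, 1)); b <- randDna(sample(20:120, 1))
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
      substitutionMatrix = mat, gapOpening = 1.5, gapExtension = 0.5)
    expect_equal(globalAlign(a, b)$score, Biostrings::score(ref))
  }
})

test_that("similarity counts identical columns after terminal-gap trimming", {
  expect_equal(alignSimilarity(globalAlign("ACGT", "ACGT")), 1)
  expect_equal(alignSimilarity(globalAlign("ACGTACGT", "ACGAACGT")), 7 / 8)
  aln <- list(aligned_a = "--ACGT", aligned_b = "TTACGT")
  expect_equal(alignSimilarity(aln), 1)
  swapped <- list(aligned_a = "TTACGT", aligned_b = "--ACGT")
  expect_equal(alignSimilarity(swapped), 1)
  expect_error(alignSimilarity(list(aligned_a = "--", aligned_b = "TT")),
               "no columns")
})

test_that("codon alignment threads protein gaps onto codons", {
  id <- codonAlign("ATGAAAGGG", "ATGAAAGGG")
  expect_identical(id$aligned_a, id$aligned_b)
  expect_false(grepl("-", id$aligned_a, fixed = TRUE))

  ins <- codonAlign("ATGGGG", "ATGAAAGGG")
  gaps <- gregexpr("-+", ins$aligned_a)[[1]]
  expect_equal(attr(gaps, "match.length"), 3L)  # one 3-nt gap

  expect_error(codonAlign(randDna(100), randDna(99)), "divisible by 3")
  expect_error(codonAlign("ATGTAAAAA", "ATGAAAAAA"), "stop codon")
})

test_that("NG86 handles identity, synonymous and mixed codon pairs", {
  id <- kaksNG86(list(aligned_a = "ATGAAA", aligned_b = "ATGAAA"))
  expect_equal(id$ka, 0); expect_equal(id$ks, 0)
  expect_true(is.na(id$ratio)); expect_equal(id$flag, "identical")

  syn <- kaksNG86(list(aligned_a = "AAA", aligned_b = "AAG"))
  expect_equal(syn$nd, 0); expect_equal(syn$sd, 1)
  expect_equal(syn$ka, 0); expect_equal(syn$ratio, 0)

  mix <- kaksNG86(list(aligned_a = "ATGAAA", aligned_b = "ATGAGA"))
  o <- oracleNG86("AAA", "AGA")
  om <- oracleNG86("ATG", "ATG")
  expect_equal(mix$nd, o$nd + om$nd)
  expect_equal(mix$sd, o$sd + om$sd)
  expect_equal(mix$s_sites, o$s_sites + om$s_sites)
})

test_that("NG86 is symmetric and conserves site totals", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    ca <- paste(sample(SENSE_CODONS_TEST, n, TRUE), collapse = "")
    cb <- paste(sample(SENSE_CODONS_TEST, n, TRUE), collapse = "")
    f <- kaksNG86(list(aligned_a = ca, aligned_b = cb))
    r <- kaksNG86(list(aligned_a = cb, aligned_b = ca))
    for (fld in c("ka", "ks", "ratio", "n_sites", "s_sites", "nd", "sd"))
      expect_equal(f[[fld]], r[[fld]], tolerance = 1e-12)
    expect_equal(f$n_sites + f$s_sites, 3 * n)
  }
})

test_that("gapped codon columns are dropped from NG86 counting", {
  aln <- list(aligned_a = "ATG---AAA", aligned_b = "ATGCCCAAA")
  res <- kaksNG86(aln)
  expect_equal(res$n_sites + res$s_sites, 6)  # 2 ungapped codons
  expect_equal(res$nd + res$sd, 0)
})
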