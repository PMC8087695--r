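test_that("exact substring CDS placement recovers the true interval", {
  set.seed(41)
  bg <- randDna(10000)
  cds <- randDna(900)
  ref <- c(chr1 = paste0(substr(bg, 1, 5000), cds, substr(bg, 5001, 10000)))
  pl <- placeOnReference(c(g1 = cds), ref, k = 21)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$ref_chrom, "chr1")
  expect_equal(pl$ref_start, 5000L)
  expect_equal(pl$ref_end, 5900L)
  expect_equal(pl$identity, 1.0)
})

test_that("diverged and reverse-complemented copies still place", {
  set.seed(42)
  bg <- randDna(8000)
  cds <- randDna(600)
  mut <- strsplit(cds, "")[[1]]
  subs <- sample(600, 6)  # 1% substitutions
  for (p in subs) mut[p] <- sample(setdiff(c("A", "C", "G", "T"), mut[p]), 1)
  ref <- c(chr1 = paste0(substr(bg, 1, 3000), paste(mut, collapse = ""),
                         substr(bg, 3001, 8000)))
  pl <- placeOnReference(c(g1 = cds), ref, k = 21)
  expect_equal(nrow(pl), 1L)
  expect_lte(abs(pl$ref_start - 3000L), 21L)
  expect_lte(abs(pl$ref_end - 3600L), 21L)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  ref2 <- c(chr1 = paste0(substr(bg, 1, 3000), rc, substr(bg, 3001, 8000)))
  pl2 <- placeOnReference(c(g1 = cds), ref2, k = 21)
  expect_equal(pl2$strand, "-")
  expect_equal(pl2$ref_start, 3000L)
})

test_that("a CDS absent from the reference gets no placement", {
  set.seed(43)
  ref <- c(chr1 = randDna(5000))
  expect_message(pl <- placeOnReference(c(g1 = randDna(500)), ref),
                 "no placement")
  expect_equal(nrow(pl), 0L)
})

test_that("coordinate overlap pairing uses a strict shorter-length rule", {
  plA <- data.frame(gene_id = "gA", ref_chrom = "chr1",
                    ref_start = 100L, ref_end = 200L, identity = 1)
  mk <- function(s, e, chrom = "chr1")
    data.frame(gene_id = "gB", ref_chrom = chrom, ref_start = s,
               ref_end = e, identity = 1)
  # overlap 50 on min length 100: 50 > 50 is FALSE
  expect_equal(nrow(coordinateOverlapPairs(plA, mk(150L, 250L))), 0L)
  # overlap 60 > 50
  expect_equal(nrow(coordinateOverlapPairs(plA, mk(140L, 240L))), 1L)
  # different chromosome never pairs
  expect_equal(nrow(coordinateOverlapPairs(plA, mk(100L, 200L, "chr2"))), 0L)
  expect_error(coordinateOverlapPairs(plA, mk(1L, 2L), min_frac = 0),
               "config error")
})

test_that("the similarity rule is strict at its threshold", {
  pairs <- data.frame(geneA = paste0("A", 1:4), geneB = paste0("B", 1:4),
                      similarity = c(1.0, 0.875, 0.7, 0.69))
  out <- filterBySimilarity(pairs, threshold = 0.7)
  expect_identical(out$status,
                   c("same_allele", "allele", "rejected", "rejected"))
})

test_that("multi-hit resolution orders by similarity with lexical ties", {
  pairs <- data.frame(
    geneA = c("A1", "A1"), geneB = c("B1", "B2"),
    similarity = c(0.95, 0.88), source = "placement")
  pairs <- filterBySimilarity(pairs)
  res <- resolveMultiHits(pairs)
  expect_equal(res$primary$geneB, "B1")
  expect_equal(res$paralog$geneB, "B2")

  low <- filterBySimilarity(data.frame(
    geneA = c("A1", "A1"), geneB = c("B1", "B2"),
    similarity = c(0.95, 0.65), source = "placement"))
  res <- resolveMultiHits(low)
  expect_equal(nrow(res$paralog), 0L)
  expect_equal(res$rejected$geneB, "B2")

  tie <- filterBySimilarity(data.frame(
    geneA = c("A1", "A1"), geneB = c("B2", "B1"),
    similarity = c(0.9, 0.9), source = "placement"))
  res <- resolveMultiHits(tie)
  expect_equal(res$primary$geneB, "B1")  # lexicographically smaller
})

test_that("allele table bookkeeping separates classes and audits rejects", {
  cand <- filterBySimilarity(data.frame(
    geneA = paste0("HA.", 1:4), geneB = paste0("HB.", 1:4),
    source = "synteny", similarity = c(0.9, 0.95, 0.99, 0.5)))
  placements <- data.frame(gene_id = c(paste0("HA.", 1:4),
                                       paste0("HB.", 1:4)),
                           ref_chrom = "chr1", ref_start = 0L,
                           ref_end = 10L, identity = 1)
  atab <- buildAlleleTable(cand, placements,
    genesA = data.frame(gene_id = paste0("HA.", 1:4)),
    genesB = data.frame(gene_id = paste0("HB.", 1:4)))
  loci <- alleleLoci(atab)
  expect_equal(sum(loci$class == "two_allele"), 3L)
  # the rejected pair's genes become one_allele loci (placement evidence)
  expect_equal(sum(loci$class == "one_allele"), 2L)
  expect_equal(nrow(atab@audit), 4L)
  genes <- c(unlist(strsplit(loci$genesA, ",")),
             unlist(strsplit(loci$genesB, ",")))
  expect_false(anyDuplicated(genes[nzchar(genes)]) > 0)
})

test_that("all-identical input produces a zero substitution count", {
  cand <- filterBySimilarity(data.frame(
    geneA = paste0("HA.", 1:3), geneB = paste0("HB.", 1:3),
    source = "synteny", similarity = 1.0))
  atab <- buildAlleleTable(cand)
  s <- alleleSummary(atab)
  expect_equal(s$genes_with_substitution, 0L)
  expect_true(all(allelePairs(atab)$status == "same_allele"))
})

test_that("selection flags follow the Ka/Ks > 1 rule with a Ks=0 guard", {
  pairs <- data.frame(geneA = 1:3, geneB = 1:3,
                      ka = c(0.02, 0, 0.05), ks = c(0.01, 0.03, 0),
                      kaks = c(2, 0, NA),
                      kaks_flag = c("ok", "ok", "ratio_undefined"))
  out <- classifySelection(pairs)
  expect_identical(out$selection,
                   c("positive_selection", "none", "ratio_undefined"))
})

test_that("pair Ka/Ks excludes broken CDS instead of failing", {
  cds_a <- c(p1 = "ATGAAAGGGTTT", p2 = "ATGTAAGGGTTT")  # p2 internal stop
  cds_b <- c(q1 = "ATGAAAGGGTTC", q2 = "ATGAAAGGGTTT")
  pairs <- data.frame(geneA = c("p1", "p2"), geneB = c("q1", "q2"))
  out <- pairKaks(pairs, cds_a, cds_b)
  expect_false(is.na(out$ks[1]))
  expect_true(is.na(out$ka[2]))
  expect_equal(out$kaks_flag[2], "excluded")
})
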