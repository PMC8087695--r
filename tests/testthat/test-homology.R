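test_that("identical CDS pair yields one perfect hit", {
  set.seed(21)
  s <- randDna(300)
  hits <- scoreGenePairs(c(a1 = s), c(b1 = s))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$score, 300)
})

test_that("genes sharing no 12-mers are never paired", {
  set.seed(22)
  repeat {  # draw until the pair genuinely shares no 12-mer (oracle check)
    a <- randDna(300); b <- randDna(300)
    ka <- substring(a, 1:289, 12:300)
    kb <- substring(b, 1:289, 12:300)
    if (length(intersect(ka, kb)) == 0) break
  }
  hits <- scoreGenePairs(c(a1 = a), c(b1 = b))
  expect_equal(nrow(hits), 0L)
})

test_that("exact duplicate partners keep equal-scoring hits", {
  set.seed(23)
  s <- randDna(240)
  hits <- scoreGenePairs(c(a1 = s), c(b1 = s, b2 = s))
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$score[1], hits$score[2])
})

test_that("empty gene sets give an empty hit table", {
  hits <- scoreGenePairs(character(0), c(b = randDna(100)))
  expect_equal(nrow(hits), 0L)
})

test_that("cscore matches brute-force maxima over the hit table", {
  hits <- data.frame(geneA = c("A1", "A1", "A2"),
                     geneB = c("B1", "B2", "B2"),
                     score = c(100, 95, 95))
  kept <- cscoreFilter(hits, c = 0.99)
  expect_setequal(paste(kept$geneA, kept$geneB), c("A1 B1", "A2 B2"))
  expect_equal(kept$cscore[kept$geneA == "A2"], 1.0)
  # brute-force oracle over the table
  best <- function(g) max(hits$score[hits$geneA == g | hits$geneB == g])
  cs <- mapply(function(a, b, s) s / max(best(a), best(b)),
               hits$geneA, hits$geneB, hits$score)
  expect_equal(unname(cs), c(1, 95 / 100, 1))
  relaxed <- cscoreFilter(hits, c = 0.5)
  expect_equal(nrow(relaxed), 3L)
  expect_error(cscoreFilter(hits, c = 0), "config error")
  expect_error(cscoreFilter(hits, c = 1.2), "config error")
})

test_that("reciprocal-best pairs have cscore exactly 1", {
  hits <- data.frame(geneA = "A1", geneB = "B1", score = 57.5)
  out <- cscoreFilter(hits, c = 0.99)
  expect_equal(out$cscore, 1.0)
})

.mkGenes <- function(prefix, chrom, n) {
  data.frame(gene_id = paste0(prefix, seq_len(n)), chrom = chrom,
             start = seq_len(n) * 1000L)
}

test_that("perfectly collinear and inverted anchors chain into one block", {
  gA <- .mkGenes("A", "c1", 4); gB <- .mkGenes("B", "c1", 4)
  same <- data.frame(geneA = paste0("A", 1:4), geneB = paste0("B", 1:4),
                     score = 10)
  ch <- chainBlocks(same, gA, gB, min_anchors = 4)
  expect_equal(nrow(ch$blocks), 1L)
  expect_equal(ch$blocks$orientation, "same")
  expect_equal(ch$blocks$n_anchors, 4L)

  inv <- data.frame(geneA = paste0("A", 1:4), geneB = paste0("B", 4:1),
                    score = 10)
  ch <- chainBlocks(inv, gA, gB, min_anchors = 4)
  expect_equal(nrow(ch$blocks), 1L)
  expect_equal(ch$blocks$orientation, "inverted")
})

test_that("anchors displaced beyond the rank gap stay unassigned", {
  gA <- .mkGenes("A", "c1", 60); gB <- .mkGenes("B", "c1", 60)
  anchors <- data.frame(
    geneA = paste0("A", c(1:5, 10)), geneB = paste0("B", c(1:5, 50)),
    score = 10)
  ch <- chainBlocks(anchors, gA, gB, min_anchors = 4, max_rank_gap = 25)
  expect_equal(nrow(ch$blocks), 1L)
  expect_equal(ch$blocks$n_anchors, 5L)
  expect_false("A10" %in% ch$anchors$geneA)
})

test_that("chaining agrees with exhaustive enumeration on small sets", {
  bruteBest <- function(ra, rb, max_gap) {
    n <- length(ra); best <- 0
    idx <- seq_len(n)
    for (k in n:1) {
      combs <- utils::combn(idx, k, simplify = FALSE)
      for (sub in combs) {
        o <- order(ra[sub])
        s <- sub[o]
        rbo <- rb[s]
        okS <- all(diff(rb[s]) > 0) && all(diff(ra[s]) <= max_gap) &&
               all(abs(diff(rb[s])) <= max_gap) && !anyDuplicated(ra[s])
        okI <- all(diff(rb[s]) < 0) && all(diff(ra[s]) <= max_gap) &&
               all(abs(diff(rb[s])) <= max_gap) && !anyDuplicated(ra[s])
        if ((okS || okI) && all(diff(ra[s]) > 0)) return(k)
      }
    }
    0
  }
  set.seed(31)
  for (trial in 1:25) {
    n <- sample(3:6, 1)
    ra <- sample(1:10, n); rb <- sample(1:10, n)
    gA <- .mkGenes("A", "c1", 10); gB <- .mkGenes("B", "c1", 10)
    anchors <- data.frame(geneA = paste0("A", ra), geneB = paste0("B", rb),
                          score = 1)
    ch <- chainBlocks(anchors, gA, gB, min_anchors = 1, max_rank_gap = 25)
    got <- if (nrow(ch$blocks)) max(ch$blocks$n_anchors) else 0
    expect_equal(got, bruteBest(ra, rb, 25), info = paste(ra, rb,
                 collapse = ";"))
  }
})

test_that("synteny candidates partition genes against leftovers", {
  gA <- .mkGenes("A", "c1", 5); gB <- .mkGenes("B", "c1", 5)
  hits <- data.frame(geneA = paste0("A", 1:4), geneB = paste0("B", 1:4),
                     score = 10)
  ch <- chainBlocks(hits, gA, gB, min_anchors = 4)
  out <- syntenyAlleleCandidates(ch, gA, gB)
  expect_equal(nrow(out$pairs), 4L)
  expect_true(all(out$pairs$source == "synteny"))
  expect_identical(out$leftover$A, "A5")
  expect_identical(out$leftover$B, "B5")

  empty <- chainBlocks(hits[0, ], gA, gB)
  all_left <- syntenyAlleleCandidates(empty, gA, gB)
  expect_equal(nrow(all_left$pairs), 0L)
  expect_equal(sort(all_left$leftover$A), sort(gA$gene_id))
})

test_that("planted two-allele pairs are recovered as synteny candidates", {
  b <- smallBundle()
  hits <- scoreGenePairs(cdsSeqs(b, "A"), cdsSeqs(b, "B"))
  filt <- cscoreFilter(hits, 0.99)
  ch <- chainBlocks(filt, geneModels(b, "A"), geneModels(b, "B"))
  out <- syntenyAlleleCandidates(ch, geneModels(b, "A"), geneModels(b, "B"))
  at <- truthSet(b)$allele_truth
  two <- at[at$class == "two_allele", ]
  keys <- paste(two$geneA, two$geneB)
  got <- paste(out$pairs$geneA, out$pairs$geneB)
  expect_gte(mean(keys %in% got), 0.95)
})
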