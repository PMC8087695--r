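test_that("identical sequences align into one full-cover block", {
  set.seed(51)
  s <- randDna(10000)
  bl <- anchorAlign(s, s)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$ref_start, 0L); expect_equal(bl$ref_end, 10000L)
  expect_equal(bl$qry_start, 0L); expect_equal(bl$qry_end, 10000L)
  cp <- callPointVariants(bl, s, s)
  expect_equal(nrow(cp$variants), 0L)
})

test_that("a homopolymer has no unique anchors", {
  s <- strrep("A", 2000)
  expect_warning(bl <- anchorAlign(s, s), "no unique anchors")
  expect_equal(nrow(bl), 0L)
})

test_that("the desk-scale guard rejects oversized input", {
  expect_error(anchorAlign(strrep("A", 30), strrep("A", 30), max_len = 10),
               "PAF")
})

test_that("a planted insertion produces two blocks and one insertion SV", {
  set.seed(52)
  a <- randDna(6000)
  ins <- randDna(300)
  b <- paste0(substr(a, 1, 3000), ins, substr(a, 3001, 6000))
  bl <- anchorAlign(a, b)
  jn <- haplotab:::.junctions(bl)
  expect_equal(nrow(bl), 2L)
  expect_equal(jn$g_qry - jn$g_ref, 300L)
  cp <- callPointVariants(bl, a, b)
  sv <- classifySvs(bl, cp$deferred, a, b)
  expect_equal(nrow(sv), 1L)
  expect_equal(sv$category, "insertion")
  expect_equal(sv$size, 300L)
  expect_equal(sv$size_bin, "50-500")
})

test_that("isolated SNPs and small indels are called at planted positions", {
  set.seed(53)
  a <- randDna(20000)
  av <- strsplit(a, "")[[1]]
  pos <- sort(sample(500:19500, 100))
  pos <- pos[c(TRUE, diff(pos) > 60)]  # isolated
  bv <- av
  for (p in pos) bv[p] <- sample(setdiff(c("A", "C", "G", "T"), av[p]), 1)
  b <- paste(bv, collapse = "")
  bl <- anchorAlign(a, b)
  cp <- callPointVariants(bl, a, b)
  snps <- cp$variants[cp$variants$kind == "snp", ]
  expect_equal(sort(snps$ref_pos), pos - 1L)
  expect_identical(av[snps$ref_pos + 1L], snps$ref_base)

  # 5-bp deletion
  b2 <- paste0(substr(a, 1, 9999), substr(a, 10005, 20000))
  bl2 <- anchorAlign(a, b2)
  cp2 <- callPointVariants(bl2, a, b2)
  del <- cp2$variants[cp2$variants$kind == "small_deletion", ]
  expect_equal(nrow(del), 1L)
  expect_equal(del$size, 5L)
})

test_that("tandem and repeat copy-number changes carry their signatures", {
  set.seed(54)
  x <- randDna(4000); y <- randDna(4000)
  s <- randDna(200)
  # contraction: reference has two adjacent copies, query one
  a <- paste0(x, s, s, y); b <- paste0(x, s, y)
  bl <- anchorAlign(a, b)
  sv <- classifySvs(bl, callPointVariants(bl, a, b)$deferred, a, b)
  expect_equal(sv$category, "tandem_contraction")
  expect_equal(sv$size, 200L)
  # expansion: query gains a copy
  a2 <- paste0(x, s, y); b2 <- paste0(x, s, s, y)
  bl2 <- anchorAlign(a2, b2)
  sv2 <- classifySvs(bl2, callPointVariants(bl2, a2, b2)$deferred, a2, b2)
  expect_equal(sv2$category, "tandem_expansion")
  expect_equal(sv2$size, 200L)
  # repeat array copy-number gain: m^4 -> m^6
  m <- randDna(60)
  a3 <- paste0(x, strrep(m, 4), y); b3 <- paste0(x, strrep(m, 6), y)
  bl3 <- anchorAlign(a3, b3)
  sv3 <- classifySvs(bl3, callPointVariants(bl3, a3, b3)$deferred, a3, b3)
  expect_equal(sv3$category, "repeat_expansion")
  expect_equal(sv3$size, 120L)
})

test_that("events below the SV floor are never emitted as SVs", {
  set.seed(55)
  a <- randDna(5000)
  b <- paste0(substr(a, 1, 2500), randDna(30), substr(a, 2501, 5000))
  bl <- anchorAlign(a, b)
  cp <- callPointVariants(bl, a, b)
  sv <- classifySvs(bl, cp$deferred, a, b)
  expect_equal(nrow(sv), 0L)
  expect_equal(cp$variants$kind, "small_insertion")
  expect_equal(cp$variants$size, 30L)
})

test_that("SV size boundary: 49 is a small indel, 50 an SV", {
  set.seed(56)
  a <- randDna(5000)
  mk <- function(n) paste0(substr(a, 1, 2500), randDna(n),
                           substr(a, 2501, 5000))
  for (n in c(49L, 50L)) {
    b <- mk(n)
    bl <- anchorAlign(a, b)
    cp <- callPointVariants(bl, a, b)
    sv <- classifySvs(bl, cp$deferred, a, b)
    if (n < 50) {
      expect_equal(nrow(sv), 0L)
      expect_equal(cp$variants$size, n)
    } else {
      expect_equal(nrow(sv), 1L)
      expect_equal(sv$size, 50L)
      expect_equal(sv$size_bin, "50-500")
    }
  }
})

test_that("SV gene annotation uses 1-bp interval overlap", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(1000L, 2000L, 9000L),
                      end = c(1900L, 2900L, 9500L))
  svs <- data.frame(chrom = "chr1", ref_pos = c(1100L, 1850L, 5000L),
                    ref_start = c(1100L, 1850L, 5000L),
                    ref_end = c(1200L, 2100L, 5100L),
                    size = 100L, category = "deletion",
                    size_bin = "50-500")
  out <- annotateSvGenes(svs, genes)
  expect_equal(out$genes_hit, c("g1", "g1,g2", ""))
  expect_equal(out$n_genes_hit, c(1L, 2L, 0L))
})

test_that("applying zero calls returns the reference unchanged", {
  s <- randDna(500)
  expect_identical(applyVariants(s, data.frame(ref_start = integer(0),
    ref_end = integer(0), alt = character(0))), s)
  expect_error(applyVariants(s, data.frame(ref_start = c(10L, 15L),
    ref_end = c(20L, 25L), alt = "")), "overlap")
})

test_that("reconstruction round-trips a simulated chromosome exactly", {
  b <- smallBundle()
  a <- as.character(haplotypeSeq(b, "A"))[[1]]
  q <- as.character(haplotypeSeq(b, "B"))[[1]]
  hv <- compareHaplotypes(haplotypeSeq(b, "A"), haplotypeSeq(b, "B"))
  calls <- rbind(variantCalls(hv)[, c("ref_start", "ref_end", "alt")],
                 svCalls(hv)[, c("ref_start", "ref_end", "alt")])
  v <- verifyReconstruction(a, q, alignmentBlocks(hv), calls)
  expect_true(v$match)
  # a deliberately dropped call must surface as a mismatch
  v2 <- verifyReconstruction(a, q, alignmentBlocks(hv),
                             calls[-1, , drop = FALSE])
  expect_false(v2$match)
  expect_false(is.na(v2$first_mismatch))
})

test_that("SV summaries tally categories, bins and totals", {
  svs <- data.frame(chrom = "chr1",
                    category = c("insertion", "deletion"),
                    size = c(60L, 600L),
                    size_bin = svSizeBin(c(60L, 600L)))
  s <- summarizeSvs(svs)
  expect_equal(s$total_count, 2L)
  expect_equal(s$per_size_bin[["50-500"]], 1L)
  expect_equal(s$per_size_bin[["500-10000"]], 1L)
  expect_equal(s$total_size_mb, 660 / 1e6)
  empty <- summarizeSvs(data.frame(category = character(0),
                                   size = integer(0),
                                   size_bin = character(0)))
  expect_equal(empty$total_count, 0L)
  expect_true(all(unlist(empty$per_category) == 0L))
})
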