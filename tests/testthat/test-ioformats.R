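test_that("FASTA round-trips and normalises case", {
  d <- withr::local_tempdir()
  p <- file.path(d, "x.fa")
  seqs <- c(chr1 = randDna(137), chr2 = randDna(61), chr3 = randDna(60))
  writeFasta(seqs, p)
  back <- readFasta(p)
  expect_identical(names(back), names(seqs))
  expect_identical(unname(as.character(back)), unname(seqs))

  writeLines(c(">a desc", "acgtACGT", ">b", "ttTT"), p)
  mixed <- readFasta(p)
  expect_identical(unname(as.character(mixed)), c("ACGTACGT", "TTTT"))
  expect_identical(names(mixed), c("a", "b"))

  writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), p)
  expect_error(readFasta(p), "duplicate")
  expect_error(writeFasta(c(a = "ACGT", a = "GG"), p), "duplicate")
})

test_that("GFF3 round-trips coordinates, strands and ranks exactly", {
  d <- withr::local_tempdir()
  p <- file.path(d, "g.gff3")
  # gene at GFF3 columns 101..200 must become internal [100, 200)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 100L, end = 200L)
  exons <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = c(100L, 160L), end = c(130L, 200L),
                      exon_rank = 1:2)
  writeGff3(genes, exons, p)
  txt <- readLines(p)
  expect_true(any(grepl("\tgene\t101\t200\t", txt)))
  back <- readGff3(p)
  expect_equal(back$genes$start, 100L)
  expect_equal(back$genes$end, 200L)

  b <- smallBundle()
  writeGff3(b@genesA, b@exonsA, p)
  back <- readGff3(p)
  ga <- b@genesA[order(b@genesA$chrom, b@genesA$start), ]
  rownames(ga) <- NULL
  expect_equal(back$genes[, names(ga)], ga)
  ea <- b@exonsA[order(b@exonsA$gene_id, b@exonsA$exon_rank), ]
  ba <- back$exons[order(back$exons$gene_id, back$exons$exon_rank), ]
  rownames(ea) <- NULL; rownames(ba) <- NULL
  expect_equal(ba[, c("gene_id", "start", "end", "exon_rank")],
               ea[, c("gene_id", "start", "end", "exon_rank")])
})

test_that("multi-isoform GFF3 input is refused with guidance", {
  d <- withr::local_tempdir()
  p <- file.path(d, "iso.gff3")
  writeLines(c("##gff-version 3",
    "chr1\tx\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t1\t300\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tx\tmRNA\t1\t250\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\tx\texon\t1\t300\t.\t+\t.\tID=e1;Parent=g1.t1"), p)
  expect_error(readGff3(p), "isoform")
})

test_that("PAF round-trips and rejects malformed lines", {
  d <- withr::local_tempdir()
  p <- file.path(d, "x.paf")
  df <- data.frame(qname = c("q1", "q2"), qlen = c(500L, 300L),
                   qstart = c(0L, 10L), qend = c(400L, 250L),
                   strand = c("+", "-"),
                   tname = c("chr1", "chr2"), tlen = c(10000L, 8000L),
                   tstart = c(100L, 2000L), tend = c(500L, 2240L),
                   nmatch = c(390L, 230L), alen = c(400L, 240L),
                   mapq = c(60L, 60L))
  writePaf(df, p)
  back <- readPaf(p)
  expect_equal(back, df)
  expect_identical(back$strand[2], "-")

  writeLines(paste(rep("x", 11), collapse = "\t"), p)
  expect_error(readPaf(p), "line 1")
})

test_that("VCF writing follows the 1-based convention and sorts records", {
  d <- withr::local_tempdir()
  p <- file.path(d, "v.vcf")
  snps <- data.frame(chrom = "chr1", pos = 99L, ref = "A", alt = "T")
  writeVariantsVcf(p, snps)
  txt <- readLines(p)
  expect_identical(txt[1], "##fileformat=VCFv4.2")
  expect_true(any(grepl("^chr1\t100\t\\.\tA\tT", txt)))

  ref <- c(chr1 = paste0(strrep("A", 49), "CGTTT", strrep("G", 50)))
  indels <- data.frame(chrom = "chr1", pos = 50L, size = 2L,
                       kind = "small_deletion", seq = "GT")
  writeVariantsVcf(p, snps, indels, ref)
  txt <- readLines(p)
  expect_true(any(grepl("^chr1\t50\t\\.\tCGT\tC", txt)))
})

test_that("SV size bins follow the published bin edges", {
  expect_identical(svSizeBin(c(300, 600, 20000, 60000)),
                   c("50-500", "500-10000", "10000-50000", "50000-100000"))
  expect_identical(svSizeBin(c(49, 50, 499, 500, 100000, 100001)),
                   c(NA, "50-500", "50-500", "500-10000", "50000-100000",
                     NA))
})

test_that("allele table TSV carries the same_allele convention", {
  cand <- data.frame(geneA = c("HA.1", "HA.2"), geneB = c("HB.1", "HB.2"),
                     source = "synteny",
                     similarity = c(1, 0.9))
  cand <- filterBySimilarity(cand)
  atab <- buildAlleleTable(cand)
  d <- withr::local_tempdir()
  p <- file.path(d, "at.tsv")
  writeAlleleTable(p, atab)
  tab <- utils::read.delim(p)
  same <- tab[tab$status == "same_allele", ]
  expect_equal(nrow(same), 1L)
  expect_equal(same$similarity, 1.0)
})

test_that("count tables round-trip", {
  m <- matrix(rpois(15, 40), 3, 5,
              dimnames = list(paste0("g", 1:3), c("R", "S", "B", "YL", "ML")))
  d <- withr::local_tempdir()
  p <- file.path(d, "c.tsv")
  writeCountsTsv(m, p)
  back <- readCountsTsv(p)
  expect_equal(back, m)
})
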