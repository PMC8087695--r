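test_that("the bundle is a pure function of its configuration", {
  cfg <- simConfig(n_chromosomes = 1L, chrom_length = 60000L, n_genes = 8L,
                   seed = 1L, sv_counts = noSv)
  b1 <- simulateDiploid(cfg); b2 <- simulateDiploid(cfg)
  expect_identical(as.character(haplotypeSeq(b1, "A")),
                   as.character(haplotypeSeq(b2, "A")))
  expect_identical(as.character(haplotypeSeq(b1, "B")),
                   as.character(haplotypeSeq(b2, "B")))
  expect_identical(exprCounts(b1), exprCounts(b2))
  expect_identical(truthSet(b1)$planted_snps, truthSet(b2)$planted_snps)
})

test_that("repeat_fraction 0 leaves no long motif duplicated", {
  cfg <- simConfig(n_chromosomes = 1L, chrom_length = 50000L, n_genes = 3L,
                   repeat_fraction = 0, sv_counts = noSv, seed = 2L)
  mono <- generateMonoploid(cfg)
  s <- mono$seqs[[1]]
  n <- nchar(s) - 19L
  kmers <- substring(s, 1:n, 20:(n + 19L))
  expect_equal(max(table(kmers)), 1L)  # exhaustive 20-mer census
})

test_that("zero genes yields a valid genome with empty annotation", {
  cfg <- simConfig(n_chromosomes = 2L, chrom_length = 20000L, n_genes = 0L,
                   sv_counts = noSv, seed = 3L)
  mono <- generateMonoploid(cfg)
  expect_equal(nrow(mono$genes), 0L)
  expect_true(all(nchar(mono$seqs) == 20000L))
  expect_true(all(strsplit(paste(mono$seqs, collapse = ""), "")[[1]] %in%
                  c("A", "C", "G", "T")))
})

test_that("gene models are well-formed coding sequences", {
  b <- smallBundle()
  cds <- as.character(cdsSeqs(b, "A"))
  expect_true(all(nchar(cds) %% 3 == 0))
  aas <- vapply(cds, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s))), "")
  expect_false(any(grepl("*", aas, fixed = TRUE)))
  # CDS extracted from the genome equals the recorded CDS (strand handling)
  expect_true(all(nchar(as.character(cdsSeqs(b, "B"))) %% 3 == 0))
})

test_that("null mutation settings leave the haplotypes identical", {
  cfg <- simConfig(n_chromosomes = 1L, chrom_length = 30000L, n_genes = 4L,
                   snp_rate = 0, small_indel_rate = 0, sv_counts = noSv,
                   allele_class_mix = c(two_allele = 0, multi_allele = 0,
                                        unpaired = 0, identical = 1),
                   seed = 4L)
  b <- simulateDiploid(cfg)
  expect_identical(as.character(haplotypeSeq(b, "A")),
                   as.character(haplotypeSeq(b, "B")))
  expect_equal(nrow(truthSet(b)$planted_snps), 0L)
})

test_that("planted SNP records equal the mismatch columns of the pair", {
  cfg <- simConfig(n_chromosomes = 1L, chrom_length = 100000L, n_genes = 0L,
                   snp_rate = 0.008, small_indel_rate = 0, sv_counts = noSv,
                   repeat_fraction = 0, seed = 7L)
  b <- simulateDiploid(cfg)
  a <- strsplit(as.character(haplotypeSeq(b, "A"))[[1]], "")[[1]]
  q <- strsplit(as.character(haplotypeSeq(b, "B"))[[1]], "")[[1]]
  expect_equal(length(a), length(q))  # substitutions only
  mism <- which(a != q)
  ts <- truthSet(b)$planted_snps
  expect_equal(nrow(ts), length(mism))
  expect_equal(sort(ts$pos), mism - 1L)
  expect_identical(q[ts$pos + 1L], ts$alt)
})

test_that("length difference equals the signed sum of planted events", {
  b <- smallBundle()
  tr <- truthSet(b)
  dB <- sum(Biostrings::width(haplotypeSeq(b, "B")))
  dA <- sum(Biostrings::width(haplotypeSeq(b, "A")))
  ind <- tr$planted_indels; sv <- tr$planted_svs
  gains <- c("insertion", "tandem_expansion", "repeat_expansion")
  signed <- sum(ifelse(ind$kind == "small_insertion", ind$size, -ind$size)) +
    sum(ifelse(sv$category %in% gains, sv$size, -sv$size)) +
    sum(tr$paralog_insertions$size)
  expect_identical(dB - dA, signed)
})

test_that("one planted tandem expansion adds exactly its size to B", {
  sv <- noSv; sv["tandem_expansion"] <- 1L
  cfg <- simConfig(n_chromosomes = 1L, chrom_length = 30000L, n_genes = 0L,
                   snp_rate = 0, small_indel_rate = 0, sv_counts = sv,
                   sv_size_range = c(200, 200), seed = 8L)
  b <- simulateDiploid(cfg)
  expect_equal(sum(Biostrings::width(haplotypeSeq(b, "B"))) -
               sum(Biostrings::width(haplotypeSeq(b, "A"))), 200L)
  expect_equal(truthSet(b)$planted_svs$size, 200L)
})

test_that("allele classes are apportioned by largest remainder", {
  cfg <- simConfig(seed = 3L)
  genes <- data.frame(gene_id = sprintf("G%04d", 1:1000))
  cls <- assignAlleleClasses(genes, cfg)
  counts <- table(cls$class)
  # independent largest-remainder computation
  props <- cfg@allele_class_mix
  raw <- props * 1000
  base <- floor(raw)
  rem <- 1000 - sum(base)
  frac <- raw - base
  add <- names(sort(frac, decreasing = TRUE))[seq_len(rem)]
  base[add] <- base[add] + 1
  for (cl in names(props))
    expect_equal(unname(counts[cl]), unname(base[cl]), info = cl)
})

test_that("degenerate class mixtures produce the promised structure", {
  cfg2 <- simConfig(n_chromosomes = 1L, chrom_length = 80000L, n_genes = 10L,
    allele_class_mix = c(two_allele = 1, multi_allele = 0, unpaired = 0,
                         identical = 0), sv_counts = noSv, seed = 9L)
  b2 <- simulateDiploid(cfg2)
  at <- truthSet(b2)$allele_truth
  expect_equal(nrow(at), 10L)
  expect_true(all(at$class == "two_allele"))
  # every pair carries at least one CDS substitution
  for (i in seq_len(nrow(at)))
    expect_false(identical(
      as.character(cdsSeqs(b2, "A")[[at$geneA[i]]]),
      as.character(cdsSeqs(b2, "B")[[at$geneB[i]]])))

  cfgu <- simConfig(n_chromosomes = 1L, chrom_length = 80000L, n_genes = 10L,
    allele_class_mix = c(two_allele = 0, multi_allele = 0, unpaired = 1,
                         identical = 0), sv_counts = noSv, seed = 10L)
  bu <- simulateDiploid(cfgu)
  atu <- truthSet(bu)$allele_truth
  expect_true(all(xor(is.na(atu$geneA), is.na(atu$geneB))))
})

test_that("identical-class loci carry no planted CDS change", {
  b <- smallBundle()
  at <- truthSet(b)$allele_truth
  id <- at[at$class == "identical", ]
  for (i in seq_len(nrow(id)))
    expect_identical(as.character(cdsSeqs(b, "A")[[id$geneA[i]]]),
                     as.character(cdsSeqs(b, "B")[[id$geneB[i]]]))
})

test_that("expression simulation respects its null limits", {
  at <- data.frame(locus_id = sprintf("L%04d", 1:300),
                   geneA = sprintf("HA.G%04d", 1:300),
                   geneB = sprintf("HB.G%04d", 1:300),
                   class = "two_allele", paralogB = NA_character_)
  eff <- stats::setNames(rep(900L, 600), c(at$geneA, at$geneB))
  cfg <- simConfig(allele_effect_sd = 0, nb_dispersion = 0,
                   tissue_effect_sd = 0, seed = 12L)
  ex <- simulateExpression(at, eff, cfg)
  # exchangeable tissues: column means agree within sampling error
  cm <- colMeans(ex$counts)
  expect_true(max(abs(cm - mean(cm))) / mean(cm) < 0.05)
  # null ASE: aggregate A/B ratio near 1
  asum <- sum(ex$counts[at$geneA, ]); bsum <- sum(ex$counts[at$geneB, ])
  expect_lt(abs(asum / bsum - 1), 0.05)
  expect_true(all(ex$ase_truth$log_ratio == 0))
  # determinism
  ex2 <- simulateExpression(at, eff, cfg)
  expect_identical(ex$counts, ex2$counts)
})

test_that("infeasible sizing fails loudly", {
  expect_error(generateMonoploid(
    simConfig(n_chromosomes = 1L, chrom_length = 10000L, n_genes = 50L,
              sv_counts = noSv, seed = 1L)), "sizing error")
  expect_error(simConfig(snp_rate = 1.5), "rates")
  expect_error(simConfig(allele_class_mix = c(two_allele = 0.5,
    multi_allele = 0.2, unpaired = 0.2, identical = 0.2)), "sum to 1")
  expect_error(simConfig(sv_size_range = c(10, 100)), "sv_size_range")
})
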