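#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib haplotab, .registration = TRUE
NULL

#' Configuration for the synthetic diploid generator
#'
#' A \code{SimConfig} fully determines a synthetic diploid bundle: the same
#' configuration (including its seed) always regenerates byte-identical
#' sequences, annotations, truth records and count tables.
#'
#' @slot n_chromosomes Number of chromosomes in the monoploid reference.
#' @slot chrom_length Length of each chromosome in bp.
#' @slot n_genes Total number of gene loci across the genome.
#' @slot snp_rate Substitution rate per bp planted between the haplotypes.
#' @slot small_indel_rate Small-indel event rate per bp (sizes 1-49 bp).
#' @slot sv_counts Named integer vector of planted structural variants per
#'   category (\code{insertion}, \code{deletion}, \code{tandem_expansion},
#'   \code{tandem_contraction}, \code{repeat_expansion},
#'   \code{repeat_contraction}).
#' @slot sv_size_range Two-element numeric, SV size interval in bp; must lie
#'   within [50, 100000].
#' @slot allele_class_mix Named proportions over \code{two_allele},
#'   \code{multi_allele}, \code{unpaired}, \code{identical}; must sum to 1.
#' @slot repeat_fraction Fraction of background sequence built from repeated
#'   motifs.
#' @slot tissues Character vector of tissue labels.
#' @slot expr_mean_log Baseline log expression mean.
#' @slot tissue_effect_sd SD of the per-locus per-tissue log effect (shared
#'   by the two alleles of a pair).
#' @slot allele_effect_sd SD of the per-locus allelic log-ratio.
#' @slot nb_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2; 0 degenerates to Poisson).
#' @slot seed Integer seed driving all randomness.
#' @export
setClass("SimConfig", representation(
  n_chromosomes = "integer",
  chrom_length = "integer",
  n_genes = "integer",
  snp_rate = "numeric",
  small_indel_rate = "numeric",
  sv_counts = "integer",
  sv_size_range = "numeric",
  allele_class_mix = "numeric",
  repeat_fraction = "numeric",
  tissues = "character",
  expr_mean_log = "numeric",
  tissue_effect_sd = "numeric",
  allele_effect_sd = "numeric",
  nb_dispersion = "numeric",
  seed = "integer"
))

SV_CATEGORIES <- c("insertion", "deletion", "tandem_expansion",
                   "tandem_contraction", "repeat_expansion",
                   "repeat_contraction")
ALLELE_CLASSES <- c("two_allele", "multi_allele", "unpaired", "identical")

setValidity("SimConfig", function(object) {
  msg <- character(0)
  rates <- c(snp_rate = object@snp_rate,
             small_indel_rate = object@small_indel_rate,
             repeat_fraction = object@repeat_fraction)
  bad <- rates < 0 | rates > 1
  if (any(bad))
    msg <- c(msg, paste0("rates must lie in [0,1]: ",
                         paste(names(rates)[bad], collapse = ", ")))
  if (!setequal(names(object@sv_counts), SV_CATEGORIES))
    msg <- c(msg, "sv_counts must be named by the six SV categories")
  if (any(object@sv_counts < 0)) msg <- c(msg, "sv_counts must be >= 0")
  if (length(object@sv_size_range) != 2 ||
      object@sv_size_range[1] < 50 || object@sv_size_range[2] > 100000 ||
      object@sv_size_range[1] > object@sv_size_range[2])
    msg <- c(msg, "sv_size_range must be an interval within [50, 100000]")
  if (!setequal(names(object@allele_class_mix), ALLELE_CLASSES))
    msg <- c(msg, "allele_class_mix must be named by the four allele classes")
  if (abs(sum(object@allele_class_mix) - 1) > 1e-9)
    msg <- c(msg, "allele_class_mix must sum to 1")
  if (any(object@allele_class_mix < 0))
    msg <- c(msg, "allele_class_mix proportions must be >= 0")
  if (object@n_chromosomes < 1) msg <- c(msg, "need >= 1 chromosome")
  if (object@chrom_length < 1000) msg <- c(msg, "chrom_length too small")
  if (object@n_genes < 0) msg <- c(msg, "n_genes must be >= 0")
  if (object@tissue_effect_sd < 0 || object@allele_effect_sd < 0 ||
      object@nb_dispersion < 0)
    msg <- c(msg, "effect SDs and dispersion must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-diploid configuration
#'
#' Defaults emulate a desk-scale version of a highly heterozygous diploid
#' genome: SNP rate 0.008/bp (the genome-wide SNP density implied by tens of
#' millions of SNPs over a ~3 Gb genome), small indels at about a tenth of
#' that, sixty structural variants drawn from the six-category taxonomy, and
#' five-tissue allele-level expression.
#'
#' @param n_chromosomes,chrom_length,n_genes Genome layout.
#' @param snp_rate,small_indel_rate Per-bp divergence rates between the
#'   two haplotypes.
#' @param sv_counts Named counts of planted SVs per category.
#' @param sv_size_range SV size interval (bp), within [50, 100000].
#' @param allele_class_mix Proportions of gene loci per allele class.
#' @param repeat_fraction Fraction of the background built from repeat motifs.
#' @param tissues Tissue labels for the expression design.
#' @param expr_mean_log,tissue_effect_sd,allele_effect_sd,nb_dispersion
#'   Expression-model parameters (natural-log scale).
#' @param seed Integer seed.
#' @return A validated \linkS4class{SimConfig} object.
#' @examples
#' cfg <- simConfig(n_chromosomes = 1, chrom_length = 50000L, n_genes = 10)
#' @export
simConfig <- function(n_chromosomes = 5L,
                      chrom_length = 1200000L,
                      n_genes = 1000L,
                      snp_rate = 0.008,
                      small_indel_rate = 0.00077,
                      sv_counts = c(insertion = 10L, deletion = 10L,
                                    tandem_expansion = 10L,
                                    tandem_contraction = 10L,
                                    repeat_expansion = 10L,
                                    repeat_contraction = 10L),
                      sv_size_range = c(50, 10000),
                      allele_class_mix = c(two_allele = 0.70,
                                           multi_allele = 0.10,
                                           unpaired = 0.05,
                                           identical = 0.15),
                      repeat_fraction = 0.10,
                      tissues = c("R", "S", "B", "YL", "ML"),
                      expr_mean_log = log(100),
                      tissue_effect_sd = 1.0,
                      allele_effect_sd = 0.25,
                      nb_dispersion = 0.05,
                      seed = 1L) {
  sv <- as.integer(sv_counts)
  names(sv) <- names(sv_counts)
  new("SimConfig",
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.integer(chrom_length),
      n_genes = as.integer(n_genes),
      snp_rate = snp_rate,
      small_indel_rate = small_indel_rate,
      sv_counts = sv,
      sv_size_range = as.numeric(sv_size_range),
      allele_class_mix = allele_class_mix,
      repeat_fraction = repeat_fraction,
      tissues = tissues,
      expr_mean_log = expr_mean_log,
      tissue_effect_sd = tissue_effect_sd,
      allele_effect_sd = allele_effect_sd,
      nb_dispersion = nb_dispersion,
      seed = as.integer(seed))
}

#' Synthetic diploid bundle with ground truth
#'
#' Container for a generated diploid: the monoploid reference, the two
#' haplotype sequence sets, per-haplotype gene models and coding sequences,
#' the truth set of every planted event, and the simulated allele-level
#' count table.
#'
#' @slot monoploid,hapA,hapB \link[Biostrings]{DNAStringSet} genomes.
#' @slot genesA,genesB Gene tables (gene_id, chrom, strand, start, end;
#'   0-based half-open).
#' @slot exonsA,exonsB Exon tables (gene_id, start, end, exon_rank).
#' @slot cdsA,cdsB Coding sequences in coding orientation.
#' @slot truth List of truth records (planted_snps, planted_indels,
#'   planted_svs, allele_truth, ase_truth, expr_truth, ...).
#' @slot counts Gene-by-tissue count matrix (both haplotypes' genes as rows).
#' @slot eff_length Named effective lengths (bp) for expression.
#' @slot config The generating \linkS4class{SimConfig}.
#' @export
setClass("SimBundle", representation(
  monoploid = "ANY", hapA = "ANY", hapB = "ANY",
  genesA = "data.frame", genesB = "data.frame",
  exonsA = "data.frame", exonsB = "data.frame",
  cdsA = "ANY", cdsB = "ANY",
  truth = "list", counts = "matrix", eff_length = "numeric",
  config = "SimConfig"))

#' Allele table relating genes across two haplotypes
#'
#' @slot pairs Accepted and audited candidate pairs with similarity, source,
#'   status, and (when computed) Ka/Ks columns.
#' @slot loci Locus table: locus_id, genesA, genesB (comma-collapsed),
#'   class, primary pair and similarity.
#' @slot audit All candidate pairs including rejected ones.
#' @slot summary List of locus-level and gene-level class counts.
#' @export
setClass("AlleleTable", representation(
  pairs = "data.frame", loci = "data.frame", audit = "data.frame",
  summary = "list"))

#' Whole-haplotype comparison result
#'
#' @slot blocks Chained unique-anchor alignment blocks.
#' @slot variants SNP and small-indel calls.
#' @slot svs Classified structural-variant calls with size bins.
#' @slot summary SV summary (per category, per size bin, totals).
#' @export
setClass("HaplotypeComparison", representation(
  blocks = "data.frame", variants = "data.frame", svs = "data.frame",
  summary = "list"))

#' @describeIn SimBundle-class Compact description of the bundle.
#' @param object A \code{SimBundle}.
#' @export
setMethod("show", "SimBundle", function(object) {
  cat("SimBundle:", length(object@monoploid), "chromosome(s),",
      nrow(object@genesA), "HA /", nrow(object@genesB), "HB genes\n")
  cat("  planted: ", nrow(object@truth$planted_snps), " SNPs, ",
      nrow(object@truth$planted_indels), " small indels, ",
      nrow(object@truth$planted_svs), " SVs\n", sep = "")
  cat("  counts:", nrow(object@counts), "genes x", ncol(object@counts),
      "tissues\n")
})

#' @describeIn AlleleTable-class Locus-class summary.
#' @param object An \code{AlleleTable}.
#' @export
setMethod("show", "AlleleTable", function(object) {
  s <- object@summary
  cat("AlleleTable:", nrow(object@loci), "loci,", nrow(object@pairs),
      "accepted pairs\n")
  cat("  loci by class:",
      paste(names(s$locus_counts), s$locus_counts, collapse = ", "), "\n")
})

#' @describeIn HaplotypeComparison-class Variant and SV tallies.
#' @param object A \code{HaplotypeComparison}.
#' @export
setMethod("show", "HaplotypeComparison", function(object) {
  v <- object@variants
  cat("HaplotypeComparison:", nrow(object@blocks), "alignment blocks\n")
  cat("  ", sum(v$kind == "snp"), " SNPs, ",
      sum(v$kind != "snp"), " small indels, ",
      nrow(object@svs), " SVs\n", sep = "")
})

#' Accessors for haplotab result objects
#'
#' @param x A \linkS4class{SimBundle}, \linkS4class{AlleleTable} or
#'   \linkS4class{HaplotypeComparison}.
#' @param haplotype \code{"A"} or \code{"B"}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("haplotypeSeq", function(x, haplotype = "A")
  standardGeneric("haplotypeSeq"))
#' @rdname accessors
#' @export
setMethod("haplotypeSeq", "SimBundle", function(x, haplotype = "A")
  if (identical(haplotype, "A")) x@hapA else x@hapB)

#' @rdname accessors
#' @export
setGeneric("monoploidSeq", function(x) standardGeneric("monoploidSeq"))
#' @rdname accessors
#' @export
setMethod("monoploidSeq", "SimBundle", function(x) x@monoploid)

#' @rdname accessors
#' @export
setGeneric("geneModels", function(x, haplotype = "A")
  standardGeneric("geneModels"))
#' @rdname accessors
#' @export
setMethod("geneModels", "SimBundle", function(x, haplotype = "A")
  if (identical(haplotype, "A")) x@genesA else x@genesB)

#' @rdname accessors
#' @export
setGeneric("cdsSeqs", function(x, haplotype = "A") standardGeneric("cdsSeqs"))
#' @rdname accessors
#' @export
setMethod("cdsSeqs", "SimBundle", function(x, haplotype = "A")
  if (identical(haplotype, "A")) x@cdsA else x@cdsB)

#' @rdname accessors
#' @export
setGeneric("truthSet", function(x) standardGeneric("truthSet"))
#' @rdname accessors
#' @export
setMethod("truthSet", "SimBundle", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("exprCounts", function(x) standardGeneric("exprCounts"))
#' @rdname accessors
#' @export
setMethod("exprCounts", "SimBundle", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("allelePairs", function(x) standardGeneric("allelePairs"))
#' @rdname accessors
#' @export
setMethod("allelePairs", "AlleleTable", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("alleleLoci", function(x) standardGeneric("alleleLoci"))
#' @rdname accessors
#' @export
setMethod("alleleLoci", "AlleleTable", function(x) x@loci)

#' @rdname accessors
#' @export
setGeneric("alleleSummary", function(x) standardGeneric("alleleSummary"))
#' @rdname accessors
#' @export
setMethod("alleleSummary", "AlleleTable", function(x) x@summary)

#' @rdname accessors
#' @export
setGeneric("alignmentBlocks", function(x) standardGeneric("alignmentBlocks"))
#' @rdname accessors
#' @export
setMethod("alignmentBlocks", "HaplotypeComparison", function(x) x@blocks)

#' @rdname accessors
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))
#' @rdname accessors
#' @export
setMethod("variantCalls", "HaplotypeComparison", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("svCalls", function(x) standardGeneric("svCalls"))
#' @rdname accessors
#' @export
setMethod("svCalls", "HaplotypeComparison", function(x) x@svs)

#' @rdname accessors
#' @export
setGeneric("svSummary", function(x) standardGeneric("svSummary"))
#' @rdname accessors
#' @export
setMethod("svSummary", "HaplotypeComparison", function(x) x@summary)
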