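# Allele-level expression: TPM normalisation, highly-expressed filtering,
# exact binomial allelic-imbalance tests and sample correlation clustering.

#' Transcripts-per-million normalisation
#'
#' Per sample, counts are divided by effective length and rescaled so each
#' column sums to one million.
#'
#' @param counts Non-negative integer matrix (genes x samples).
#' @param eff_length Effective lengths (bp), named by gene or in row order.
#' @return TPM matrix of the same shape.
#' @examples
#' tpm(matrix(c(10, 20), 2, 1, dimnames = list(c("g1", "g2"), "s")),
#'     c(g1 = 1000, g2 = 2000))
#' @export
tpm <- function(counts, eff_length) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(eff_length)) && !is.null(rownames(counts)))
    eff_length <- eff_length[rownames(counts)]
  if (any(is.na(eff_length)) || any(eff_length <= 0))
    stop("eff_length must be positive for every gene")
  rate <- counts / eff_length
  csum <- colSums(rate)
  zero <- csum == 0
  if (any(zero))
    stop("TPM undefined for all-zero sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(rate, 2, csum, "/") * 1e6
}

#' Genes highly expressed in at least one sample
#'
#' @param tpm_mat TPM matrix.
#' @param threshold Strict TPM cutoff (default 10).
#' @return Character vector of gene ids with TPM > threshold somewhere.
#' @export
highlyExpressed <- function(tpm_mat, threshold = 10) {
  if (nrow(tpm_mat) == 0) return(character(0))
  rownames(tpm_mat)[apply(tpm_mat > threshold, 1, any)]
}

#' Exact binomial allelic-imbalance test
#'
#' Tests each pair's A-side count against the length-corrected null
#' p0 = len_a / (len_a + len_b) with an exact two-sided binomial test
#' (outcome probabilities at most that of the observation are summed).
#' P-values are Benjamini-Hochberg adjusted within each tissue; pairs with
#' both counts zero are NA and excluded from the adjustment.
#'
#' @param pairs Data frame with columns \code{pair_id}, \code{tissue},
#'   \code{count_a}, \code{count_b}, \code{len_a}, \code{len_b}.
#' @param alpha FDR threshold for calling a direction (default 0.05).
#' @return \code{pairs} with \code{p_value}, \code{fdr} and
#'   \code{direction} (\code{A}, \code{B} or \code{balanced}) columns.
#' @export
aseTest <- function(pairs, alpha = 0.05) {
  n <- nrow(pairs)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ca <- pairs$count_a[i]; cb <- pairs$count_b[i]
    if (ca + cb == 0) next
    p0 <- pairs$len_a[i] / (pairs$len_a[i] + pairs$len_b[i])
    p[i] <- stats::binom.test(ca, ca + cb, p = p0)$p.value
  }
  pairs$p_value <- p
  pairs$fdr <- NA_real_
  for (tt in unique(pairs$tissue)) {
    sel <- pairs$tissue == tt & !is.na(p)
    pairs$fdr[sel] <- stats::p.adjust(p[sel], method = "BH")
  }
  dir <- rep(NA_character_, n)
  callable <- !is.na(pairs$fdr)
  sig <- callable & pairs$fdr < alpha
  dir[callable] <- "balanced"
  aa <- pairs$count_a / pairs$len_a > pairs$count_b / pairs$len_b
  dir[sig & aa] <- "A"
  dir[sig & !aa] <- "B"
  pairs$direction <- dir
  pairs
}

#' Sample correlation matrix and clustering of allele expression
#'
#' Pearson correlation of log2(TPM + 1) across allele-pair rows, treating
#' the A-side and B-side expression in each tissue as separate samples;
#' agglomerative clustering with average linkage on distance
#' 1 - correlation.
#'
#' @param tpm_mat TPM matrix, rows = allele pairs, columns = samples
#'   (haplotype x tissue).
#' @return List with \code{correlation} (matrix) and \code{dendrogram}
#'   (an \code{hclust} object).
#' @export
sampleCorrelationCluster <- function(tpm_mat) {
  if (ncol(tpm_mat) < 2) stop("need at least two samples")
  lt <- log2(tpm_mat + 1)
  sds <- apply(lt, 2, stats::sd)
  if (any(sds == 0))
    stop("constant sample vector(s): correlation undefined for ",
         paste(colnames(tpm_mat)[sds == 0], collapse = ", "))
  cc <- stats::cor(lt)
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  list(correlation = cc, dendrogram = hc)
}

#' Assemble per-pair per-tissue ASE input from a count table
#'
#' @param counts Gene-by-tissue count matrix.
#' @param pairs Data frame with \code{geneA}, \code{geneB} (one row per
#'   allele pair) and optionally \code{locus_id}.
#' @param eff_length Named effective lengths.
#' @return Long-format data frame ready for \code{\link{aseTest}}.
#' @export
asePairCounts <- function(counts, pairs, eff_length) {
  tissues <- colnames(counts)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$geneA[i]; gb <- pairs$geneB[i]
    if (!(ga %in% rownames(counts)) || !(gb %in% rownames(counts)))
      return(NULL)
    data.frame(
      pair_id = if ("locus_id" %in% names(pairs)) pairs$locus_id[i]
                else paste(ga, gb, sep = "|"),
      tissue = tissues,
      count_a = counts[ga, ], count_b = counts[gb, ],
      len_a = unname(eff_length[ga]), len_b = unname(eff_length[gb]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
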