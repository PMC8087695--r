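# Allele-table assembly: placement rescue on the monoploid reference,
# similarity filtering, paralog resolution, locus classification and
# selection screening.

#' Place coding sequences on the monoploid reference
#'
#' Exact k-mer seeds of each CDS (both orientations) that are unique in the
#' reference are chained collinearly per chromosome; the placement is the
#' hull of the best chain and identity is the fraction of CDS bases covered
#' by chained seeds. Genes with no seed chain get no placement.
#'
#' @param cds Named CDS set (character vector or DNAStringSet).
#' @param monoploid Monoploid reference sequences.
#' @param k Seed length (default 21).
#' @return Data frame: \code{gene_id}, \code{ref_chrom}, \code{ref_start},
#'   \code{ref_end} (0-based half-open), \code{identity}, \code{n_seeds};
#'   unplaceable genes are omitted (count reported via message).
#' @export
placeOnReference <- function(cds, monoploid, k = 21L) {
  cds <- .as_seq_vector(cds); ref <- .as_seq_vector(monoploid)
  if (!length(cds))
    return(data.frame(gene_id = character(0), ref_chrom = character(0),
                      ref_start = integer(0), ref_end = integer(0),
                      identity = numeric(0), n_seeds = integer(0)))
  pl <- .place_cds(unname(ref), unname(cds), as.integer(k))
  out <- data.frame(gene_id = names(cds),
                    ref_chrom = names(ref)[pl$chrom_idx],
                    ref_start = pl$ref_start, ref_end = pl$ref_end,
                    identity = pl$identity, n_seeds = pl$n_seeds,
                    strand = pl$strand)
  lost <- sum(is.na(out$ref_chrom))
  if (lost > 0) message(lost, " gene(s) had no placement on the reference")
  out <- out[!is.na(out$ref_chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair genes by shared reference coordinates
#'
#' A pair is emitted when two placements sit on the same reference
#' chromosome and their overlap exceeds \code{min_frac} of the shorter
#' placement (strict inequality). Mirrors the rescue rule that gene pairs
#' sharing more than half their reference coordinates can exist as alleles.
#'
#' @param placementsA,placementsB Placement tables from
#'   \code{\link{placeOnReference}}.
#' @param min_frac Required overlap fraction of the shorter placement,
#'   in (0, 1] (default 0.5).
#' @return Data frame of candidate pairs: \code{geneA}, \code{geneB},
#'   \code{source = "placement"}, \code{overlap}.
#' @export
coordinateOverlapPairs <- function(placementsA, placementsB, min_frac = 0.5) {
  if (!is.numeric(min_frac) || length(min_frac) != 1 ||
      min_frac <= 0 || min_frac > 1)
    stop("config error: min_frac must lie in (0, 1]")
  empty <- data.frame(geneA = character(0), geneB = character(0),
                      source = character(0), overlap = integer(0))
  if (nrow(placementsA) == 0 || nrow(placementsB) == 0) return(empty)
  lv <- union(placementsA$ref_chrom, placementsB$ref_chrom)
  grA <- GenomicRanges::GRanges(factor(placementsA$ref_chrom, levels = lv),
          IRanges::IRanges(placementsA$ref_start + 1L, placementsA$ref_end))
  grB <- GenomicRanges::GRanges(factor(placementsB$ref_chrom, levels = lv),
          IRanges::IRanges(placementsB$ref_start + 1L, placementsB$ref_end))
  ov <- GenomicRanges::findOverlaps(grA, grB)
  if (!length(ov)) return(empty)
  qa <- S4Vectors::queryHits(ov); qb <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(grA)[qa],
                                          IRanges::ranges(grB)[qb]))
  minlen <- pmin(IRanges::width(IRanges::ranges(grA))[qa],
                 IRanges::width(IRanges::ranges(grB))[qb])
  keep <- w > min_frac * minlen
  if (!any(keep)) return(empty)
  data.frame(geneA = placementsA$gene_id[qa[keep]],
             geneB = placementsB$gene_id[qb[keep]],
             source = "placement", overlap = w[keep])
}

#' Compute CDS similarities for candidate pairs
#'
#' Global affine-gap alignment of the two coding sequences; similarity is
#' identical columns over columns after trimming terminal gaps.
#'
#' @param pairs Candidate pair table with \code{geneA}, \code{geneB}.
#' @param cdsA,cdsB Named CDS sets.
#' @return \code{pairs} with a \code{similarity} column.
#' @export
pairSimilarities <- function(pairs, cdsA, cdsB) {
  cdsA <- .as_seq_vector(cdsA); cdsB <- .as_seq_vector(cdsB)
  pairs$similarity <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- cdsA[[pairs$geneA[i]]]; b <- cdsB[[pairs$geneB[i]]]
    alignSimilarity(.gotoh_align(a, b, 1, -1, -2, -0.5))
  }, 0)
  pairs
}

#' Apply the similarity rule to candidate pairs
#'
#' Pairs with similarity exactly 1 are the same allele; pairs above the
#' threshold (strict) are alleles; the rest are rejected but kept for audit.
#'
#' @param pairs Pair table with a \code{similarity} column.
#' @param threshold Similarity cutoff, strict (default 0.7).
#' @return \code{pairs} with a \code{status} column
#'   (\code{same_allele} / \code{allele} / \code{rejected}).
#' @export
filterBySimilarity <- function(pairs, threshold = 0.7) {
  st <- rep("rejected", nrow(pairs))
  st[pairs$similarity > threshold] <- "allele"
  st[pairs$similarity == 1] <- "same_allele"
  pairs$status <- st
  pairs
}

#' Resolve multiple genes sharing one reference locus
#'
#' Pairs are sorted by similarity (descending; ties by lexicographic gene
#' ids); the best accepted cross-haplotype pair becomes the primary allele
#' pair and remaining genes passing the similarity threshold are attached as
#' paralogs.
#'
#' @param pairs Candidate pairs of one locus, with \code{similarity} and
#'   \code{status} columns.
#' @return List with \code{primary} (one-row data frame or NULL),
#'   \code{paralog} (pairs attached as paralogs) and \code{rejected}.
#' @export
resolveMultiHits <- function(pairs) {
  acc <- pairs[pairs$status %in% c("allele", "same_allele"), , drop = FALSE]
  rej <- pairs[pairs$status == "rejected", , drop = FALSE]
  if (nrow(acc) == 0)
    return(list(primary = NULL, paralog = acc, rejected = rej))
  o <- order(-acc$similarity, acc$geneB, acc$geneA)
  acc <- acc[o, , drop = FALSE]
  primary <- acc[1, , drop = FALSE]
  rest <- acc[-1, , drop = FALSE]
  # pairs introducing a new gene relative to the primary pair are paralog
  # attachments; duplicate links between already-claimed genes are dropped
  claimed <- c(primary$geneA, primary$geneB)
  keep <- logical(nrow(rest))
  for (i in seq_len(nrow(rest))) {
    new_genes <- setdiff(c(rest$geneA[i], rest$geneB[i]), claimed)
    if (length(new_genes)) {
      keep[i] <- TRUE
      claimed <- c(claimed, new_genes)
    }
  }
  list(primary = primary, paralog = rest[keep, , drop = FALSE],
       rejected = rej)
}

#' Assemble the allele table
#'
#' Loci are built by union-find over genes linked by accepted pairs
#' (synteny and placement candidates together). Within each locus the best
#' accepted pair is primary and extra genes become paralogs
#' (\code{\link{resolveMultiHits}}). Loci with more than two genes are
#' \code{multi_allele}, exactly one gene per haplotype is
#' \code{two_allele}, and genes with no accepted partner but a reference
#' placement are \code{one_allele}.
#'
#' @param candidates All candidate pairs with \code{similarity},
#'   \code{status} and \code{source} columns.
#' @param placements Combined placement table (for one_allele evidence).
#' @param genesA,genesB Gene tables (to partition gene ids by haplotype).
#' @return An \linkS4class{AlleleTable}.
#' @export
buildAlleleTable <- function(candidates, placements = NULL,
                             genesA = NULL, genesB = NULL) {
  acc <- candidates[candidates$status %in% c("allele", "same_allele"), ,
                    drop = FALSE]
  # union-find over genes
  genes <- unique(c(acc$geneA, acc$geneB))
  parent <- stats::setNames(seq_along(genes), genes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(acc))) {
    ra <- find(match(acc$geneA[i], genes))
    rb <- find(match(acc$geneB[i], genes))
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  comp <- vapply(seq_along(genes), function(i) find(i), 1L)
  comp_of <- stats::setNames(comp, genes)

  loci <- list(); pair_rows <- list()
  lid <- 0L
  for (cid in sort(unique(comp))) {
    members <- genes[comp == cid]
    sub <- acc[acc$geneA %in% members | acc$geneB %in% members, ,
               drop = FALSE]
    res <- resolveMultiHits(sub)
    if (is.null(res$primary)) next
    lid <- lid + 1L
    locus_id <- sprintf("AT%05d", lid)
    gA <- sort(unique(c(res$primary$geneA, res$paralog$geneA)))
    gB <- sort(unique(c(res$primary$geneB, res$paralog$geneB)))
    n_genes <- length(gA) + length(gB)
    cls <- if (n_genes > 2) "multi_allele" else "two_allele"
    loci[[lid]] <- data.frame(
      locus_id = locus_id, genesA = paste(gA, collapse = ","),
      genesB = paste(gB, collapse = ","), class = cls,
      n_genes = n_genes,
      primary_geneA = res$primary$geneA, primary_geneB = res$primary$geneB,
      similarity = res$primary$similarity,
      primary_status = res$primary$status)
    pr <- res$primary; pr$role <- "primary"; pr$locus_id <- locus_id
    pair_rows[[length(pair_rows) + 1L]] <- pr
    if (nrow(res$paralog)) {
      pl <- res$paralog; pl$role <- "paralog"; pl$locus_id <- locus_id
      pair_rows[[length(pair_rows) + 1L]] <- pl
    }
  }
  loci_df <- if (length(loci)) do.call(rbind, loci) else
    data.frame(locus_id = character(0), genesA = character(0),
               genesB = character(0), class = character(0),
               n_genes = integer(0), primary_geneA = character(0),
               primary_geneB = character(0), similarity = numeric(0),
               primary_status = character(0))
  pairs_df <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    cbind(candidates[0, , drop = FALSE],
          data.frame(role = character(0), locus_id = character(0)))

  # sanity: no gene in two loci
  all_locus_genes <- c(unlist(strsplit(loci_df$genesA, ",")),
                       unlist(strsplit(loci_df$genesB, ",")))
  all_locus_genes <- all_locus_genes[nzchar(all_locus_genes)]
  if (anyDuplicated(all_locus_genes))
    stop("internal consistency error: a gene was linked into two loci")

  # one_allele loci: unpaired genes with placement evidence
  paired <- all_locus_genes
  one_rows <- list()
  if (!is.null(placements)) {
    placed <- setdiff(placements$gene_id, paired)
    ids_a <- if (!is.null(genesA)) intersect(placed, genesA$gene_id) else
      grep("^HA\\.", placed, value = TRUE)
    ids_b <- if (!is.null(genesB)) intersect(placed, genesB$gene_id) else
      grep("^HB\\.", placed, value = TRUE)
    for (g in sort(c(ids_a, ids_b))) {
      lid <- lid + 1L
      side_a <- g %in% ids_a
      one_rows[[length(one_rows) + 1L]] <- data.frame(
        locus_id = sprintf("AT%05d", lid),
        genesA = if (side_a) g else "", genesB = if (side_a) "" else g,
        class = "one_allele", n_genes = 1L,
        primary_geneA = NA_character_, primary_geneB = NA_character_,
        similarity = NA_real_, primary_status = NA_character_)
    }
  }
  if (length(one_rows)) loci_df <- rbind(loci_df, do.call(rbind, one_rows))
  rownames(loci_df) <- NULL; rownames(pairs_df) <- NULL

  summary <- .allele_summary(loci_df)
  methods::new("AlleleTable", pairs = pairs_df, loci = loci_df,
               audit = candidates, summary = summary)
}

.allele_summary <- function(loci) {
  cls <- factor(loci$class,
                levels = c("multi_allele", "two_allele", "one_allele"))
  locus_counts <- table(cls)
  genes_per <- function(sel) {
    g <- c(unlist(strsplit(loci$genesA[sel], ",")),
           unlist(strsplit(loci$genesB[sel], ",")))
    sum(nzchar(g))
  }
  gene_counts <- c(
    multi_allele = genes_per(loci$class == "multi_allele"),
    two_allele = genes_per(loci$class == "two_allele"),
    one_allele = genes_per(loci$class == "one_allele"))
  sub_bearing <- genes_per(loci$class %in% c("multi_allele", "two_allele") &
                           !is.na(loci$similarity) & loci$similarity < 1)
  list(locus_counts = as.list(locus_counts),
       gene_counts = as.list(gene_counts),
       genes_with_alleles = sum(gene_counts),
       genes_with_substitution = sub_bearing,
       mean_similarity = if (any(!is.na(loci$similarity)))
         mean(loci$similarity, na.rm = TRUE) else NA_real_)
}

#' Compute Ka/Ks for allele pairs
#'
#' Codon-aligns the two coding sequences of each pair and applies
#' Nei-Gojobori counting with Jukes-Cantor correction. Pairs whose CDS fail
#' the preconditions (length not a multiple of 3, internal stop) are flagged
#' \code{excluded} and get NA rates.
#'
#' @param pairs Pair table with \code{geneA}, \code{geneB}.
#' @param cdsA,cdsB Named CDS sets.
#' @return \code{pairs} with columns \code{ka}, \code{ks}, \code{kaks},
#'   \code{kaks_flag}.
#' @export
pairKaks <- function(pairs, cdsA, cdsB) {
  cdsA <- .as_seq_vector(cdsA); cdsB <- .as_seq_vector(cdsB)
  n <- nrow(pairs)
  ka <- ks <- ratio <- rep(NA_real_, n)
  flag <- rep("excluded", n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      kaksNG86(codonAlign(cdsA[[pairs$geneA[i]]], cdsB[[pairs$geneB[i]]])),
      error = function(e) NULL)
    if (is.null(res)) next
    ka[i] <- res$ka; ks[i] <- res$ks; ratio[i] <- res$ratio
    flag[i] <- res$flag
  }
  pairs$ka <- ka; pairs$ks <- ks; pairs$kaks <- ratio
  pairs$kaks_flag <- flag
  pairs
}

#' Flag allele pairs under positive selection
#'
#' Pairs with Ka/Ks > 1 are flagged \code{positive_selection}; pairs with
#' Ks = 0 are \code{ratio_undefined} and never positive.
#'
#' @param pairs Pair table with \code{ka}, \code{ks}, \code{kaks} columns.
#' @return \code{pairs} with a \code{selection} column.
#' @export
classifySelection <- function(pairs) {
  sel <- rep("none", nrow(pairs))
  undef <- !is.na(pairs$ks) & pairs$ks == 0 |
    (!is.na(pairs$kaks_flag) & pairs$kaks_flag %in%
       c("ratio_undefined", "identical"))
  ok <- !is.na(pairs$kaks) & pairs$kaks > 1
  sel[ok] <- "positive_selection"
  sel[undef] <- "ratio_undefined"
  pairs$selection <- sel
  pairs
}
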