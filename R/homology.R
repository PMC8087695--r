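# Gene homology scoring, cscore filtering and collinearity chaining: the
# synteny arm of allele identification between two haplotype gene sets.

#' Score candidate homologous gene pairs across haplotypes
#'
#' Candidate partners are pre-filtered by shared k-mer count between coding
#' sequences (genes sharing fewer than \code{min_shared} k-mers are never
#' compared), then scored by affine-gap global alignment. At most
#' \code{top_n} hits are kept per gene on either side.
#'
#' @param cdsA,cdsB Named CDS sets (character vector or
#'   \link[Biostrings]{DNAStringSet}) for haplotypes A and B.
#' @param k K-mer size for the pre-filter (default 12).
#' @param top_n Maximum retained hits per gene (default 5).
#' @param min_shared Minimum shared k-mer count to align a pair (default 10).
#' @return Data frame of hits: \code{geneA}, \code{geneB}, \code{score},
#'   \code{identity}, \code{shared_kmers}.
#' @export
scoreGenePairs <- function(cdsA, cdsB, k = 12L, top_n = 5L, min_shared = 10L) {
  cdsA <- .as_seq_vector(cdsA); cdsB <- .as_seq_vector(cdsB)
  empty <- data.frame(geneA = character(0), geneB = character(0),
                      score = numeric(0), identity = numeric(0),
                      shared_kmers = integer(0))
  if (length(cdsA) == 0 || length(cdsB) == 0) return(empty)

  kmerTab <- function(seqs) {
    rows <- lapply(seq_along(seqs), function(i) {
      s <- seqs[[i]]
      n <- nchar(s) - k + 1L
      if (n < 1) return(NULL)
      data.frame(kmer = unique(substring(s, 1:n, k:(n + k - 1L))), gene = i)
    })
    do.call(rbind, rows)
  }
  ta <- kmerTab(cdsA); tb <- kmerTab(cdsB)
  if (is.null(ta) || is.null(tb)) return(empty)
  common <- intersect(ta$kmer, tb$kmer)
  if (!length(common)) return(empty)
  ta <- ta[ta$kmer %in% common, ]; tb <- tb[tb$kmer %in% common, ]
  joined <- merge(ta, tb, by = "kmer", suffixes = c("A", "B"))
  key <- (joined$geneA - 1) * (length(cdsB) + 1) + joined$geneB
  r <- rle(sort(key))
  shared <- r$lengths
  gA <- (r$values - 1) %/% (length(cdsB) + 1) + 1
  gB <- r$values - (gA - 1) * (length(cdsB) + 1)
  sel <- shared >= min_shared
  if (!any(sel)) return(empty)
  gA <- gA[sel]; gB <- gB[sel]; shared <- shared[sel]

  score <- vapply(seq_along(gA), function(i)
    .gotoh_score(cdsA[[gA[i]]], cdsB[[gB[i]]], 1, -1, -2, -0.5), 0)
  hits <- data.frame(geneA = names(cdsA)[gA], geneB = names(cdsB)[gB],
                     score = score, shared_kmers = shared)
  # top_n per gene on both sides
  rankWithin <- function(keys, sc) {
    o <- order(keys, -sc)
    r <- stats::ave(sc[o], keys[o], FUN = seq_along)
    out <- integer(length(sc)); out[o] <- r; out
  }
  keep <- rankWithin(hits$geneA, hits$score) <= top_n &
          rankWithin(hits$geneB, hits$score) <= top_n
  hits <- hits[keep, , drop = FALSE]
  hits$identity <- vapply(seq_len(nrow(hits)), function(i)
    alignSimilarity(.gotoh_align(cdsA[[hits$geneA[i]]],
                                 cdsB[[hits$geneB[i]]], 1, -1, -2, -0.5)), 0)
  rownames(hits) <- NULL
  hits[, c("geneA", "geneB", "score", "identity", "shared_kmers")]
}

.as_seq_vector <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    out
  } else {
    out <- as.character(x)
    names(out) <- names(x)
    out
  }
}

#' Filter homology hits by cscore
#'
#' The cscore of a hit is its alignment score divided by the best score
#' involving either of its genes; reciprocal best hits score exactly 1. At
#' the conventional cutoff 0.99 the surviving hits are near-1:1.
#'
#' @param hits Hit table from \code{\link{scoreGenePairs}}.
#' @param c Cscore cutoff in (0, 1]; hits with cscore < c are removed.
#' @return The filtered hit table with a \code{cscore} column.
#' @export
cscoreFilter <- function(hits, c = 0.99) {
  if (!is.numeric(c) || length(c) != 1 || c <= 0 || c > 1)
    stop("config error: cscore cutoff must lie in (0, 1]")
  if (nrow(hits) == 0) { hits$cscore <- numeric(0); return(hits) }
  bestA <- tapply(hits$score, hits$geneA, max)
  bestB <- tapply(hits$score, hits$geneB, max)
  hits$cscore <- hits$score /
    pmax(bestA[hits$geneA], bestB[hits$geneB])
  out <- hits[hits$cscore >= c, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# gene rank (ordinal position) along each chromosome
.gene_ranks <- function(genes) {
  o <- order(genes$chrom, genes$start)
  r <- stats::ave(genes$start[o], genes$chrom[o], FUN = seq_along)
  data.frame(gene_id = genes$gene_id[o], chrom = genes$chrom[o], rank = r)
}

#' Chain homology hits into collinear synteny blocks
#'
#' Per chromosome pair and orientation, finds maximal chains of anchors by a
#' longest-increasing-subsequence dynamic programme over gene ranks, with a
#' rank-gap limit between consecutive anchors. Chains shorter than
#' \code{min_anchors} are discarded; each anchor belongs to at most one
#' block (longer chains win; ties resolved leftmost on haplotype A).
#'
#' @param hits Filtered hit table (e.g. from \code{\link{cscoreFilter}}).
#' @param genesA,genesB Gene tables with \code{gene_id}, \code{chrom},
#'   \code{start}.
#' @param min_anchors Minimum anchors per block (default 4).
#' @param max_rank_gap Maximum rank gap between consecutive anchors
#'   (default 25).
#' @return List with \code{blocks} (block_id, chromA, chromB, orientation,
#'   n_anchors) and \code{anchors} (block_id, geneA, geneB, rankA, rankB).
#' @export
chainBlocks <- function(hits, genesA, genesB, min_anchors = 4L,
                        max_rank_gap = 25L) {
  emptyb <- data.frame(block_id = integer(0), chromA = character(0),
                       chromB = character(0), orientation = character(0),
                       n_anchors = integer(0))
  emptya <- data.frame(block_id = integer(0), geneA = character(0),
                       geneB = character(0), rankA = numeric(0),
                       rankB = numeric(0))
  if (nrow(hits) == 0) return(list(blocks = emptyb, anchors = emptya))
  rA <- .gene_ranks(genesA); rB <- .gene_ranks(genesB)
  ia <- match(hits$geneA, rA$gene_id); ib <- match(hits$geneB, rB$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("hits reference genes absent from the gene tables")
  anc <- data.frame(geneA = hits$geneA, geneB = hits$geneB,
                    chromA = rA$chrom[ia], chromB = rB$chrom[ib],
                    rankA = rA$rank[ia], rankB = rB$rank[ib])
  blocks <- list(); anchors <- list(); bid <- 0L
  for (grp in split(anc, paste(anc$chromA, anc$chromB))) {
    active <- grp
    repeat {
      if (nrow(active) == 0) break
      best <- NULL
      for (orient in c("same", "inverted")) {
        ch <- .best_chain(active, orient, max_rank_gap)
        if (!length(ch)) next
        better <- is.null(best) || length(ch) > length(best$idx) ||
          (length(ch) == length(best$idx) &&
           active$rankA[ch[1]] < best$firstA)
        if (better)
          best <- list(idx = ch, orientation = orient,
                       firstA = active$rankA[ch[1]])
      }
      if (is.null(best) || length(best$idx) < min_anchors) break
      bid <- bid + 1L
      sel <- active[best$idx, , drop = FALSE]
      blocks[[bid]] <- data.frame(
        block_id = bid, chromA = sel$chromA[1], chromB = sel$chromB[1],
        orientation = best$orientation, n_anchors = nrow(sel))
      anchors[[bid]] <- data.frame(
        block_id = bid, geneA = sel$geneA, geneB = sel$geneB,
        rankA = sel$rankA, rankB = sel$rankB)
      active <- active[-best$idx, , drop = FALSE]
    }
  }
  if (!length(blocks)) return(list(blocks = emptyb, anchors = emptya))
  list(blocks = do.call(rbind, blocks), anchors = do.call(rbind, anchors))
}

# best chain (indices into df) for one orientation; LIS with rank-gap limit;
# deterministic: ties resolved by leftmost rankA
.best_chain <- function(df, orientation, max_rank_gap) {
  n <- nrow(df)
  if (n == 0) return(integer(0))
  rb <- if (orientation == "same") df$rankB else -df$rankB
  o <- order(df$rankA, rb)
  ra <- df$rankA[o]; rbo <- rb[o]
  dp <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[j] < ra[i] && rbo[j] < rbo[i] &&
          ra[i] - ra[j] <= max_rank_gap &&
          abs(rbo[i] - rbo[j]) <= max_rank_gap &&
          dp[j] + 1L > dp[i]) {
        dp[i] <- dp[j] + 1L; prev[i] <- j
      }
    }
  }
  terms <- which(dp == max(dp))
  ti <- terms[which.min(ra[terms])]
  chain <- integer(0); i <- ti
  while (i > 0) { chain <- c(i, chain); i <- prev[i] }
  o[chain]
}

#' Extract allele candidates from synteny blocks
#'
#' Each block's anchor pairs become allele candidates tagged
#' \code{source = "synteny"}; genes in no block are returned as leftovers
#' for placement rescue.
#'
#' @param chains Result of \code{\link{chainBlocks}}.
#' @param genesA,genesB Gene tables.
#' @return List with \code{pairs} (geneA, geneB, source, block_id) and
#'   \code{leftover} (list of A and B gene ids in no block).
#' @export
syntenyAlleleCandidates <- function(chains, genesA, genesB) {
  anc <- chains$anchors
  pairs <- data.frame(geneA = anc$geneA, geneB = anc$geneB,
                      source = rep("synteny", nrow(anc)),
                      block_id = anc$block_id)
  list(pairs = pairs,
       leftover = list(A = setdiff(genesA$gene_id, anc$geneA),
                       B = setdiff(genesB$gene_id, anc$geneB)))
}
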