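# Whole-haplotype comparison: unique-anchor alignment, SNP and small-indel
# calling from aligned inter-anchor gaps, and six-category SV classification
# from the junction gap-sign table, with reconstruction-based verification.

#' Unique-anchor alignment of two sequences
#'
#' Anchors are exact matches seeded at k-mers (k = \code{min_anchor}) unique
#' in both sequences, extended maximally and chained by a weighted
#' longest-increasing-subsequence over both coordinates. Consecutive blocks
#' may overlap on either sequence; those overlaps carry the tandem/repeat
#' signal used by \code{\link{classifySvs}}.
#'
#' @param seq_ref,seq_qry Sequences (character scalars).
#' @param min_anchor Minimum anchor length (default 20).
#' @param max_len Desk-scale guard on sequence length (default 10 Mb); longer
#'   input must arrive pre-aligned (PAF).
#' @return Data frame of blocks: \code{ref_start}, \code{ref_end},
#'   \code{qry_start}, \code{qry_end} (0-based half-open), sorted by
#'   \code{ref_start}.
#' @export
anchorAlign <- function(seq_ref, seq_qry, min_anchor = 20L,
                        max_len = 10e6) {
  if (nchar(seq_ref) > max_len || nchar(seq_qry) > max_len)
    stop("sequence exceeds the desk-scale guard (", max_len,
         " bp); supply precomputed alignments via PAF instead")
  bl <- .find_anchors(seq_ref, seq_qry, as.integer(min_anchor))
  if (nrow(bl) == 0)
    warning("no unique anchors found; sequences may be degenerate repeats")
  bl[order(bl$ref_start), , drop = FALSE]
}

# per-junction geometry between consecutive blocks
.junctions <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2)
    return(data.frame(r1 = integer(0), r2 = integer(0), q1 = integer(0),
                      q2 = integer(0), g_ref = integer(0),
                      g_qry = integer(0), trim = integer(0)))
  i <- seq_len(n - 1L)
  g_ref <- blocks$ref_start[i + 1L] - blocks$ref_end[i]
  g_qry <- blocks$qry_start[i + 1L] - blocks$qry_end[i]
  trim <- pmax(0L, -g_ref, -g_qry)
  data.frame(r1 = blocks$ref_end[i], r2 = blocks$ref_start[i + 1L] + trim,
             q1 = blocks$qry_end[i], q2 = blocks$qry_start[i + 1L] + trim,
             g_ref = g_ref, g_qry = g_qry, trim = trim)
}

#' Call SNPs and small indels between anchored blocks
#'
#' Inter-block regions where both gaps are non-negative and at most
#' \code{max_gap_align} are globally aligned; mismatch columns become SNPs,
#' gap runs of 1-49 bp become small insertions/deletions (insertion = extra
#' query bases), and gap runs of 50+ bp are deferred to SV classification.
#'
#' @param blocks Block table from \code{\link{anchorAlign}}.
#' @param seq_ref,seq_qry The two sequences.
#' @param max_gap_align Largest gap pair that is alignment-resolved
#'   (default 10000).
#' @param min_sv Size at which an event stops being a small indel and is
#'   deferred to SV classification (default 50).
#' @return List with \code{variants} (kind, ref_pos, ref_base, alt_base,
#'   size, plus ref_start/ref_end/alt edit fields), \code{deferred}
#'   (insertion/deletion events of 50+ bp found inside aligned gaps) and
#'   \code{aligned_junctions} (ref intervals that were alignment-resolved).
#' @export
callPointVariants <- function(blocks, seq_ref, seq_qry,
                              max_gap_align = 10000L, min_sv = 50L) {
  jn <- .junctions(blocks)
  vars <- list(); defer <- list(); aligned <- list()
  for (i in seq_len(nrow(jn))) {
    j <- jn[i, ]
    rl <- j$r2 - j$r1; ql <- j$q2 - j$q1
    size <- abs(j$g_qry - j$g_ref)
    if (rl > max_gap_align || ql > max_gap_align) next
    # SV-size junctions with an overlap signature belong to classifySvs;
    # sub-SV junctions are alignment-resolved on the trimmed (non-negative)
    # gap pair so anchor-extension jitter cannot open call holes
    if (size >= min_sv && (j$g_ref < 0 || j$g_qry < 0)) next
    if (rl == 0 && ql == 0) next
    if (rl == 0 || ql == 0) {
      # pure gap: single insertion or deletion event
      size <- abs(ql - rl)
      kind <- if (ql > rl) "insertion" else "deletion"
      alt <- if (ql > rl) substr(seq_qry, j$q1 + 1L, j$q2) else ""
      ev <- data.frame(kind = kind, ref_pos = j$r1, size = size,
                       ref_start = j$r1, ref_end = j$r2, alt = alt,
                       ref_base = NA_character_, alt_base = NA_character_)
      if (size >= min_sv) defer[[length(defer) + 1L]] <- ev
      else {
        ev$kind <- if (kind == "insertion") "small_insertion"
                   else "small_deletion"
        vars[[length(vars) + 1L]] <- ev
      }
      aligned[[length(aligned) + 1L]] <-
        data.frame(r1 = j$r1, r2 = j$r2)
      next
    }
    a <- substr(seq_ref, j$r1 + 1L, j$r2)
    b <- substr(seq_qry, j$q1 + 1L, j$q2)
    aln <- .gotoh_align(a, b, 1, -1, -2, -0.5)
    ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    rpos <- j$r1
    k <- 1L; L <- length(ca)
    while (k <= L) {
      if (ca[k] != "-" && cb[k] != "-") {
        if (ca[k] != cb[k])
          vars[[length(vars) + 1L]] <- data.frame(
            kind = "snp", ref_pos = rpos, size = 1L,
            ref_start = rpos, ref_end = rpos + 1L, alt = cb[k],
            ref_base = ca[k], alt_base = cb[k])
        rpos <- rpos + 1L; k <- k + 1L
      } else if (ca[k] == "-") {       # insertion (extra qry bases)
        e <- k
        while (e <= L && ca[e] == "-") e <- e + 1L
        ins <- paste(cb[k:(e - 1L)], collapse = "")
        size <- e - k
        ev <- data.frame(kind = "insertion", ref_pos = rpos, size = size,
                         ref_start = rpos, ref_end = rpos, alt = ins,
                         ref_base = NA_character_, alt_base = NA_character_)
        if (size >= min_sv) defer[[length(defer) + 1L]] <- ev
        else { ev$kind <- "small_insertion"
               vars[[length(vars) + 1L]] <- ev }
        k <- e
      } else {                          # deletion (extra ref bases)
        e <- k
        while (e <= L && cb[e] == "-") e <- e + 1L
        size <- e - k
        ev <- data.frame(kind = "deletion", ref_pos = rpos, size = size,
                         ref_start = rpos, ref_end = rpos + size, alt = "",
                         ref_base = NA_character_, alt_base = NA_character_)
        if (size >= min_sv) defer[[length(defer) + 1L]] <- ev
        else { ev$kind <- "small_deletion"
               vars[[length(vars) + 1L]] <- ev }
        rpos <- rpos + size; k <- e
      }
    }
    aligned[[length(aligned) + 1L]] <- data.frame(r1 = j$r1, r2 = j$r2)
  }
  bindOr <- function(lst, proto) if (length(lst)) do.call(rbind, lst)
                                 else proto
  proto <- data.frame(kind = character(0), ref_pos = integer(0),
                      size = integer(0), ref_start = integer(0),
                      ref_end = integer(0), alt = character(0),
                      ref_base = character(0), alt_base = character(0))
  list(variants = bindOr(vars, proto), deferred = bindOr(defer, proto),
       aligned_junctions = bindOr(aligned,
         data.frame(r1 = integer(0), r2 = integer(0))))
}

#' Classify structural variants from block junctions
#'
#' Junction events are typed by the signs of the reference and query gaps
#' between consecutive blocks: both non-negative gives insertion/deletion
#' (by sign of the net length change), a reference-side overlap marks a
#' tandem expansion (the reference segment aligns twice against an extra
#' query copy), a query-side overlap marks a tandem contraction, and
#' overlaps on both sides mark repeat expansion/contraction by the sign of
#' the net change. Deferred long gaps from
#' \code{\link{callPointVariants}} become insertions/deletions directly.
#' Sizes outside \code{[min_size, max_size]} are excluded.
#'
#' @param blocks Block table.
#' @param deferred Deferred events from \code{\link{callPointVariants}}.
#' @param seq_ref,seq_qry The two sequences.
#' @param max_gap_align Junctions this size or smaller on both sides were
#'   alignment-resolved and are skipped here (default 10000).
#' @param min_size,max_size SV size window (defaults 50 and 100000).
#' @param overlap_slop Block overlaps of at most this many bp are treated
#'   as sign-zero when categorising (anchor-extension jitter guard;
#'   default 20).
#' @return SV table: \code{ref_pos}, \code{size}, \code{category},
#'   \code{size_bin}, plus \code{ref_start}/\code{ref_end}/\code{alt} edit
#'   fields for reconstruction.
#' @export
classifySvs <- function(blocks, deferred, seq_ref, seq_qry,
                        max_gap_align = 10000L,
                        min_size = 50L, max_size = 100000L,
                        overlap_slop = 20L) {
  jn <- .junctions(blocks)
  svs <- list()
  for (i in seq_len(nrow(jn))) {
    j <- jn[i, ]
    rl <- j$r2 - j$r1; ql <- j$q2 - j$q1
    size <- abs(j$g_qry - j$g_ref)
    # junctions already alignment-resolved by callPointVariants are skipped:
    # those are the sub-SV junctions, plus clean-gap junctions whose long
    # gap runs arrive here through `deferred`
    small_junction <- size < min_size &&
      rl <= max_gap_align && ql <= max_gap_align
    clean_aligned <- j$g_ref >= 0 && j$g_qry >= 0 &&
      rl <= max_gap_align && ql <= max_gap_align
    if (small_junction || clean_aligned) next
    if (size < min_size) next
    if (size > max_size) {
      message("SV of size ", size, " exceeds max_size; excluded")
      next
    }
    # anchor extension can overshoot a few bases into an event and produce
    # spurious 1-20 bp overlaps; such jitter must not flip the category
    ref_ov <- j$g_ref < -overlap_slop
    qry_ov <- j$g_qry < -overlap_slop
    category <- if (!ref_ov && !qry_ov) {
      if (j$g_qry > j$g_ref) "insertion" else "deletion"
    } else if (ref_ov && !qry_ov) {
      "tandem_expansion"
    } else if (qry_ov && !ref_ov) {
      "tandem_contraction"
    } else {
      if (j$g_qry - j$g_ref > 0) "repeat_expansion" else "repeat_contraction"
    }
    alt <- if (j$q2 > j$q1) substr(seq_qry, j$q1 + 1L, j$q2) else ""
    svs[[length(svs) + 1L]] <- data.frame(
      ref_pos = j$r1, size = size, category = category,
      ref_start = j$r1, ref_end = j$r2, alt = alt)
  }
  if (nrow(deferred)) {
    d <- deferred[deferred$size >= min_size & deferred$size <= max_size, ,
                  drop = FALSE]
    if (nrow(d) < nrow(deferred))
      message(nrow(deferred) - nrow(d), " deferred event(s) outside the SV ",
              "size window; excluded")
    for (i in seq_len(nrow(d)))
      svs[[length(svs) + 1L]] <- data.frame(
        ref_pos = d$ref_pos[i], size = d$size[i], category = d$kind[i],
        ref_start = d$ref_start[i], ref_end = d$ref_end[i], alt = d$alt[i])
  }
  out <- if (length(svs)) do.call(rbind, svs) else
    data.frame(ref_pos = integer(0), size = integer(0),
               category = character(0), ref_start = integer(0),
               ref_end = integer(0), alt = character(0))
  out$size_bin <- svSizeBin(out$size)
  out[order(out$ref_start), , drop = FALSE]
}

#' Annotate SVs with overlapping genes
#'
#' A gene is listed when its interval overlaps the SV reference interval by
#' at least one bp.
#'
#' @param svs SV table with \code{chrom} (or single-chromosome),
#'   \code{ref_start}, \code{ref_end}.
#' @param genes Gene table with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}.
#' @return \code{svs} with a \code{genes_hit} column (comma-collapsed) and
#'   \code{n_genes_hit}.
#' @export
annotateSvGenes <- function(svs, genes) {
  if (nrow(svs) == 0) {
    svs$genes_hit <- character(0); svs$n_genes_hit <- integer(0)
    return(svs)
  }
  svchrom <- if ("chrom" %in% names(svs)) svs$chrom else
    rep(genes$chrom[1], nrow(svs))
  # zero-width insertions still occupy a junction point
  gr_sv <- GenomicRanges::GRanges(svchrom,
    IRanges::IRanges(svs$ref_start + 1L, pmax(svs$ref_end, svs$ref_start + 1L)))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_sv, gr_g)
  hit <- split(genes$gene_id[S4Vectors::subjectHits(ov)],
               S4Vectors::queryHits(ov))
  svs$genes_hit <- ""
  svs$genes_hit[as.integer(names(hit))] <-
    vapply(hit, function(g) paste(sort(g), collapse = ","), "")
  svs$n_genes_hit <- ifelse(nzchar(svs$genes_hit),
    lengths(strsplit(svs$genes_hit, ",")), 0L)
  svs
}

#' Apply variant calls to a reference sequence
#'
#' Splices every call's replacement (\code{ref_start}, \code{ref_end},
#' \code{alt}) into the reference; calls must be sorted-compatible and
#' non-overlapping.
#'
#' @param seq_ref Reference chromosome sequence.
#' @param calls Data frame of calls with edit fields (point variants and
#'   SVs can be row-bound).
#' @return The reconstructed query-side sequence.
#' @export
applyVariants <- function(seq_ref, calls) {
  if (nrow(calls) == 0) return(seq_ref)
  .apply_edits(seq_ref, calls[, c("ref_start", "ref_end", "alt")])
}

#' Verify call completeness by reconstruction
#'
#' Applies all calls to the reference and compares the result with the
#' query over the anchored-plus-aligned territory (first to last block).
#'
#' @param seq_ref,seq_qry The two sequences.
#' @param blocks Block table.
#' @param calls Combined call table (variants and SVs).
#' @return List with \code{match} (logical) and \code{first_mismatch}
#'   (0-based offset into the compared region, or NA).
#' @export
verifyReconstruction <- function(seq_ref, seq_qry, blocks, calls) {
  if (nrow(blocks) == 0) return(list(match = NA, first_mismatch = NA))
  recon <- applyVariants(seq_ref, calls)
  shift <- if (nrow(calls)) sum(nchar(calls$alt) -
                                (calls$ref_end - calls$ref_start)) else 0L
  r1 <- blocks$ref_start[1]; rN <- blocks$ref_end[nrow(blocks)]
  q1 <- blocks$qry_start[1]; qN <- blocks$qry_end[nrow(blocks)]
  a <- substr(recon, r1 + 1L, rN + shift)
  b <- substr(seq_qry, q1 + 1L, qN)
  if (identical(a, b)) return(list(match = TRUE, first_mismatch = NA))
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(ca), length(cb))
  fm <- which(ca[seq_len(n)] != cb[seq_len(n)])[1]
  if (is.na(fm)) fm <- n + 1L
  list(match = FALSE, first_mismatch = fm - 1L)
}

#' Summarize structural variants in a per-category, per-bin table
#'
#' @param svs SV table with \code{category}, \code{size}, \code{size_bin}
#'   and optionally \code{chrom}.
#' @return List: counts per category, counts per size bin, total count,
#'   total size in Mb, per-chromosome counts.
#' @export
summarizeSvs <- function(svs) {
  cat_counts <- table(factor(svs$category, levels = SV_CATEGORIES))
  bin_counts <- table(factor(svs$size_bin, levels = SV_SIZE_BINS))
  by_chrom <- if ("chrom" %in% names(svs) && nrow(svs))
    as.list(table(svs$chrom)) else list()
  list(per_category = as.list(cat_counts),
       per_size_bin = as.list(bin_counts),
       total_count = nrow(svs),
       total_size_mb = sum(svs$size) / 1e6,
       per_chromosome = by_chrom)
}

#' Compare two haplotype genomes end to end
#'
#' Runs unique-anchor alignment, point-variant calling and SV
#' classification for every shared chromosome and assembles a
#' \linkS4class{HaplotypeComparison}.
#'
#' @param hapA,hapB Genome sequence sets (named; A is the reference side).
#' @param genesA Optional reference-side gene table for SV gene annotation.
#' @param min_anchor,max_gap_align,min_size,max_size Stage parameters.
#' @return A \linkS4class{HaplotypeComparison}.
#' @export
compareHaplotypes <- function(hapA, hapB, genesA = NULL, min_anchor = 20L,
                              max_gap_align = 10000L, min_size = 50L,
                              max_size = 100000L) {
  a <- .as_seq_vector(hapA); b <- .as_seq_vector(hapB)
  chroms <- intersect(names(a), names(b))
  blocks <- list(); vars <- list(); svs <- list(); aligned <- list()
  for (ch in chroms) {
    bl <- anchorAlign(a[[ch]], b[[ch]], min_anchor = min_anchor)
    cp <- callPointVariants(bl, a[[ch]], b[[ch]],
                            max_gap_align = max_gap_align,
                            min_sv = min_size)
    sv <- classifySvs(bl, cp$deferred, a[[ch]], b[[ch]],
                      max_gap_align = max_gap_align,
                      min_size = min_size, max_size = max_size)
    if (nrow(bl)) bl$chrom <- ch
    if (nrow(cp$variants)) cp$variants$chrom <- ch
    if (nrow(sv)) sv$chrom <- ch
    aj <- cp$aligned_junctions
    if (nrow(aj)) aj$chrom <- ch
    blocks[[ch]] <- bl; vars[[ch]] <- cp$variants; svs[[ch]] <- sv
    aligned[[ch]] <- aj
  }
  bindNamed <- function(lst, proto = data.frame()) {
    lst <- lst[vapply(lst, nrow, 1L) > 0]
    if (!length(lst)) return(proto)
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  }
  sv_proto <- data.frame(ref_pos = integer(0), size = integer(0),
                         category = character(0), ref_start = integer(0),
                         ref_end = integer(0), alt = character(0),
                         size_bin = character(0), chrom = character(0))
  svdf <- bindNamed(svs, sv_proto)
  if (!is.null(genesA) && nrow(svdf)) svdf <- annotateSvGenes(svdf, genesA)
  summary <- if (nrow(svdf)) summarizeSvs(svdf) else
    summarizeSvs(data.frame(category = character(0), size = integer(0),
                            size_bin = character(0)))
  summary$aligned_junctions <- bindNamed(aligned,
    data.frame(r1 = integer(0), r2 = integer(0), chrom = character(0)))
  var_proto <- data.frame(kind = character(0), ref_pos = integer(0),
                          size = integer(0), ref_start = integer(0),
                          ref_end = integer(0), alt = character(0),
                          ref_base = character(0), alt_base = character(0),
                          chrom = character(0))
  blk_proto <- data.frame(ref_start = integer(0), ref_end = integer(0),
                          qry_start = integer(0), qry_end = integer(0),
                          chrom = character(0))
  methods::new("HaplotypeComparison", blocks = bindNamed(blocks, blk_proto),
               variants = bindNamed(vars, var_proto), svs = svdf,
               summary = summary)
}
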