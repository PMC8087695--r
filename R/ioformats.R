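# Readers and writers for the external formats the pipeline touches.
# External coordinates follow each format's convention (GFF3 and VCF
# 1-based, PAF 0-based half-open); all internal coordinates are 0-based
# half-open.

#' Read a FASTA file
#'
#' Accepts arbitrary line wrapping; sequences are normalised to upper case;
#' record ids are the first whitespace-delimited token.
#'
#' @param path FASTA file.
#' @return A \link[Biostrings]{DNAStringSet}.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA record id(s): ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(Biostrings::width(x) == 0))
    stop("empty sequence in FASTA: ",
         paste(names(x)[Biostrings::width(x) == 0], collapse = ", "))
  x
}

#' Write sequences as FASTA (60-column wrap)
#'
#' @param seqs Named character vector or DNAStringSet.
#' @param path Output path.
#' @export
writeFasta <- function(seqs, path) {
  if (length(seqs) == 0) stop("no sequences to write")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id(s)")
  x <- if (methods::is(seqs, "XStringSet")) seqs
       else Biostrings::DNAStringSet(seqs)
  if (any(Biostrings::width(x) == 0)) stop("refusing to write empty sequence")
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS rows (one mRNA per gene; CDS mirrors the
#' exons) with 1-based closed coordinates and CDS phases.
#'
#' @param genes Gene table (\code{gene_id}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end}; 0-based half-open).
#' @param exons Exon table (\code{gene_id}, \code{start}, \code{end},
#'   \code{exon_rank}).
#' @param path Output path.
#' @export
writeGff3 <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$exon_rank), , drop = FALSE]
    rows <- c(
      sprintf("%s\thaplotab\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
      sprintf("%s\thaplotab\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$gene_id))
    phase <- 0L
    for (j in seq_len(nrow(ex))) {
      e <- ex[j, ]
      rows <- c(rows,
        sprintf("%s\thaplotab\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                g$chrom, e$start + 1L, e$end, g$strand, g$gene_id,
                e$exon_rank, g$gene_id),
        sprintf("%s\thaplotab\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.c%d;Parent=%s.t1",
                g$chrom, e$start + 1L, e$end, g$strand, phase, g$gene_id,
                e$exon_rank, g$gene_id))
      phase <- (3L - ((e$end - e$start) - phase) %% 3L) %% 3L
    }
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS rows into the internal 0-based half-open
#' representation. Multi-isoform genes raise an error: select one isoform
#' per gene upstream.
#'
#' @param path GFF3 file.
#' @return List with \code{genes} and \code{exons} tables.
#' @export
readGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  mr <- which(typ == "mRNA")
  mparent <- parents[mr]
  if (anyDuplicated(mparent))
    stop("multi-isoform gene(s) found: ",
         paste(unique(mparent[duplicated(mparent)]), collapse = ", "),
         "; select a single isoform per gene before import")
  gsel <- which(typ == "gene")
  genes <- data.frame(
    gene_id = ids[gsel],
    chrom = as.character(GenomicRanges::seqnames(gr))[gsel],
    strand = as.character(BiocGenerics::strand(gr))[gsel],
    start = GenomicRanges::start(gr)[gsel] - 1L,
    end = GenomicRanges::end(gr)[gsel])
  mrna_gene <- stats::setNames(mparent, ids[mr])
  esel <- which(typ == "exon")
  exons <- data.frame(
    gene_id = unname(mrna_gene[parents[esel]]),
    chrom = as.character(GenomicRanges::seqnames(gr))[esel],
    start = GenomicRanges::start(gr)[esel] - 1L,
    end = GenomicRanges::end(gr)[esel])
  # exon rank: transcription order (coordinate order, reversed on -)
  strand_of <- stats::setNames(genes$strand, genes$gene_id)
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rk <- unlist(lapply(split(seq_len(nrow(exons)), exons$gene_id),
    function(ix) {
      n <- length(ix)
      if (identical(strand_of[[exons$gene_id[ix[1]]]], "-")) rev(seq_len(n))
      else seq_len(n)
    }), use.names = FALSE)
  exons$exon_rank <- rk
  exons <- exons[order(exons$gene_id, exons$exon_rank), , drop = FALSE]
  rownames(genes) <- NULL; rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Read a PAF alignment file
#'
#' @param path PAF file (12+ tab-separated columns).
#' @param min_len Minimum block length; shorter records are dropped with a
#'   message.
#' @return Data frame with the 12 standard PAF columns (residue coordinates
#'   0-based half-open; \code{strand} in \{+,-\}).
#' @export
readPaf <- function(path, min_len = 0L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 12))
    stop("malformed PAF: line ", which(nc < 12)[1], " has ",
         nc[which(nc < 12)[1]], " columns (12+ required)")
  get <- function(i) vapply(parts, `[[`, "", i)
  df <- data.frame(
    qname = get(1), qlen = as.integer(get(2)),
    qstart = as.integer(get(3)), qend = as.integer(get(4)),
    strand = get(5),
    tname = get(6), tlen = as.integer(get(7)),
    tstart = as.integer(get(8)), tend = as.integer(get(9)),
    nmatch = as.integer(get(10)), alen = as.integer(get(11)),
    mapq = as.integer(get(12)))
  if (!all(df$strand %in% c("+", "-")))
    stop("malformed PAF: strand column must be + or -")
  keep <- df$alen >= min_len
  if (any(!keep))
    message(sum(!keep), " PAF record(s) below min_len dropped")
  df[keep, , drop = FALSE]
}

#' Write alignments as PAF
#'
#' @param df Data frame in the layout returned by \code{\link{readPaf}}.
#' @param path Output path.
#' @export
writePaf <- function(df, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   df$qname, df$qlen, df$qstart, df$qend, df$strand,
                   df$tname, df$tlen, df$tstart, df$tend, df$nmatch,
                   df$alen, df$mapq)
  writeLines(lines, path)
  invisible(path)
}

#' Write SNPs and small indels as minimal VCF 4.2
#'
#' Emits CHROM/POS/REF/ALT records (no genotype columns) sorted by
#' position; indels are left-anchored on the preceding reference base,
#' which requires the reference sequences.
#'
#' @param path Output path.
#' @param snps Data frame with \code{chrom}, \code{pos} (0-based),
#'   \code{ref}/\code{ref_base}, \code{alt}/\code{alt_base}.
#' @param indels Optional indel table (\code{chrom}, \code{pos},
#'   \code{size}, \code{kind}, \code{seq}).
#' @param ref_seqs Reference sequences (required when indels are written).
#' @export
writeVariantsVcf <- function(path, snps, indels = NULL, ref_seqs = NULL) {
  refcol <- if ("ref_base" %in% names(snps)) "ref_base" else "ref"
  altcol <- if ("alt_base" %in% names(snps)) "alt_base" else "alt"
  rows <- data.frame(chrom = snps$chrom, pos = snps$pos + 1L,
                     ref = snps[[refcol]], alt = snps[[altcol]])
  if (!is.null(indels) && nrow(indels)) {
    if (is.null(ref_seqs))
      stop("ref_seqs required to left-anchor indel records")
    ref_seqs <- .as_seq_vector(ref_seqs)
    anchor <- substring(ref_seqs[indels$chrom], indels$pos, indels$pos)
    ins <- indels$kind %in% c("small_insertion", "insertion")
    refv <- ifelse(ins, anchor,
      paste0(anchor, indels$seq))
    altv <- ifelse(ins, paste0(anchor, indels$seq), anchor)
    rows <- rbind(rows, data.frame(chrom = indels$chrom, pos = indels$pos,
                                   ref = refv, alt = altv))
  }
  o <- order(rows$chrom, rows$pos)
  if (!identical(o, seq_len(nrow(rows))))
    message("variant records sorted by position on write")
  rows <- rows[o, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(rows))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", rows$chrom, rows$pos,
                       rows$ref, rows$alt), con)
  invisible(path)
}

#' Write classified SVs as TSV
#'
#' Columns: chrom, start (1-based), end, size, category, size_bin.
#'
#' @param path Output path.
#' @param svs SV table.
#' @export
writeSvTable <- function(path, svs) {
  out <- data.frame(chrom = svs$chrom, start = svs$ref_start + 1L,
                    end = pmax(svs$ref_end, svs$ref_start + 1L),
                    size = svs$size, category = svs$category,
                    size_bin = svs$size_bin)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an allele table as TSV
#'
#' Columns: locus_id, genesA, genesB, class, similarity, ka, ks, kaks,
#' source, status.
#'
#' @param path Output path.
#' @param atab An \linkS4class{AlleleTable} (with Ka/Ks columns merged on
#'   its pairs when available).
#' @export
writeAlleleTable <- function(path, atab) {
  loci <- alleleLoci(atab)
  pairs <- allelePairs(atab)
  prim <- pairs[pairs$role == "primary", , drop = FALSE]
  m <- match(loci$locus_id, prim$locus_id)
  getc <- function(col, default = NA)
    if (col %in% names(prim)) prim[[col]][m] else rep(default, nrow(loci))
  out <- data.frame(
    locus_id = loci$locus_id, genesA = loci$genesA, genesB = loci$genesB,
    class = loci$class, similarity = loci$similarity,
    ka = getc("ka"), ks = getc("ks"), kaks = getc("kaks"),
    source = getc("source", NA_character_),
    status = loci$primary_status)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a gene-by-tissue count table
#'
#' @param counts Count matrix.
#' @param path TSV path.
#' @export
writeCountsTsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
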