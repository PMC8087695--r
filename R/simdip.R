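# Synthetic diploid generator: a monoploid reference with gene models and
# reserved structural-variant sites, a haplotype pair derived from it by
# planting SNPs, small indels and six-category SVs, and a negative-binomial
# five-tissue allele-level count table. Every planted event is recorded in a
# truth set so downstream recovery can be measured exactly.

#' Generate a monoploid reference genome with gene models
#'
#' Builds per-chromosome sequences from random background interleaved with
#' gene footprints, repeat-motif blocks (to \code{repeat_fraction}) and
#' reserved structural-variant sites whose layout matches
#' \code{sv_counts}/\code{sv_size_range}. Gene models have an exon-intron-exon
#' structure; coding sequences are concatenations of sense codons (length
#' divisible by 3, no internal stops). Deterministic under the config seed.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return A list with \code{seqs} (named character vector of chromosome
#'   sequences), \code{genes}, \code{exons}, \code{cds} (named character
#'   vector, coding orientation) and \code{sv_sites}.
#' @examples
#' mono <- generateMonoploid(simConfig(n_chromosomes = 1,
#'   chrom_length = 60000L, n_genes = 5, sv_counts = c(insertion = 0L,
#'   deletion = 0L, tandem_expansion = 0L, tandem_contraction = 0L,
#'   repeat_expansion = 0L, repeat_contraction = 0L)))
#' @export
generateMonoploid <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  nch <- config@n_chromosomes
  L <- config@chrom_length

  # ---- plan features -------------------------------------------------------
  genes_per_chrom <- tabulate(.chunk_evenly(config@n_genes, nch), nbins = nch)
  sv_list <- rep(names(config@sv_counts), times = config@sv_counts)
  sv_chrom <- if (length(sv_list)) ((seq_along(sv_list) - 1L) %% nch) + 1L
              else integer(0)

  motifs <- vapply(1:4, function(i) .rand_dna(sample(200:800, 1)), "")

  gid <- 0L
  all_genes <- list(); all_exons <- list(); all_cds <- list()
  all_sites <- list(); seqs <- character(nch)

  for (ch in seq_len(nch)) {
    feats <- list()
    # gene features
    for (g in seq_len(genes_per_chrom[ch])) {
      n_cod <- sample(100:400, 1)
      cds <- paste(sample(SENSE_CODONS, n_cod, replace = TRUE), collapse = "")
      len <- 3L * n_cod
      s <- sample(seq(50L, len - 50L), 1)
      li <- sample(100:400, 1)
      strand <- sample(c("+", "-"), 1)
      feats[[length(feats) + 1L]] <- list(
        kind = "gene", cds = cds, split = s, intron = .rand_dna(li),
        strand = strand, width = len + li)
    }
    # sv site features
    for (i in which(sv_chrom == ch)) {
      cat_i <- sv_list[i]
      smin <- config@sv_size_range[1]; smax <- config@sv_size_range[2]
      S <- round(exp(stats::runif(1, log(smin), log(smax))))
      S <- max(smin, min(smax, S))
      site <- switch(cat_i,
        insertion = list(width = 0L, content = "", size = S),
        deletion = {
          seg <- .rand_dna(S); list(width = S, content = seg, size = S)
        },
        tandem_expansion = {
          seg <- .rand_dna(S); list(width = S, content = seg, size = S)
        },
        tandem_contraction = {
          seg <- .rand_dna(S)
          list(width = 2L * S, content = paste0(seg, seg), size = S)
        },
        repeat_expansion = {
          ml <- max(25L, round(S / 2)); sz <- 2L * ml
          m <- .rand_dna(ml)
          list(width = 4L * ml, content = strrep(m, 4L), size = sz,
               motif_len = ml)
        },
        repeat_contraction = {
          ml <- max(50L, S)
          m <- .rand_dna(ml)
          list(width = 4L * ml, content = strrep(m, 4L), size = ml,
               motif_len = ml)
        })
      site$kind <- "sv_site"; site$category <- cat_i
      feats[[length(feats) + 1L]] <- site
    }
    # repeat blocks
    rep_target <- round(config@repeat_fraction * L)
    placed <- 0L
    while (placed < rep_target) {
      m <- motifs[sample(length(motifs), 1)]
      block <- strrep(m, sample(1:4, 1))
      if (placed + nchar(block) > rep_target)
        block <- substr(block, 1, rep_target - placed)
      if (nchar(block) < 30) break
      feats[[length(feats) + 1L]] <- list(kind = "repeat",
                                          content = block,
                                          width = nchar(block))
      placed <- placed + nchar(block)
    }

    feats <- feats[sample(length(feats))]
    widths <- vapply(feats, function(f) as.integer(f$width), 1L)
    nfeat <- length(feats)
    min_gap <- 150L
    background <- L - sum(widths) - min_gap * (nfeat + 1L)
    if (background < 0)
      stop("sizing error: features (genes, SV sites, repeats) do not fit in ",
           "chromosome of length ", L)
    cuts <- sort(sample.int(background + 1L, nfeat, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts, background)) + min_gap

    # ---- assemble ----------------------------------------------------------
    pieces <- character(2L * nfeat + 1L)
    cursor <- 0L
    chrom_name <- paste0("chr", ch)
    for (i in seq_len(nfeat + 1L)) {
      pieces[2L * i - 1L] <- .rand_dna(gaps[i])
      cursor <- cursor + gaps[i]
      if (i > nfeat) break
      f <- feats[[i]]
      if (f$kind == "gene") {
        gid <- gid + 1L
        id <- sprintf("G%05d", gid)
        cds <- f$cds; s <- f$split
        len <- nchar(cds); li <- nchar(f$intron)
        body_plus <- paste0(substr(cds, 1, s), f$intron,
                            substr(cds, s + 1, len))
        Fw <- len + li
        if (f$strand == "+") {
          body <- body_plus
          ex <- data.frame(gene_id = id, chrom = chrom_name,
                           start = cursor + c(0L, s + li),
                           end = cursor + c(s, Fw),
                           exon_rank = 1:2)
        } else {
          body <- .revcomp(body_plus)
          ex <- data.frame(gene_id = id, chrom = chrom_name,
                           start = cursor + c(Fw - s, 0L),
                           end = cursor + c(Fw, Fw - s - li),
                           exon_rank = 1:2)
        }
        all_genes[[length(all_genes) + 1L]] <- data.frame(
          gene_id = id, chrom = chrom_name, strand = f$strand,
          start = cursor, end = cursor + Fw)
        all_exons[[length(all_exons) + 1L]] <- ex
        all_cds[[id]] <- cds
        pieces[2L * i] <- body
        cursor <- cursor + Fw
      } else if (f$kind == "sv_site") {
        all_sites[[length(all_sites) + 1L]] <- data.frame(
          chrom = chrom_name, start = cursor, width = as.integer(f$width),
          category = f$category, size = as.integer(f$size),
          motif_len = if (is.null(f$motif_len)) NA_integer_
                      else as.integer(f$motif_len))
        pieces[2L * i] <- f$content
        cursor <- cursor + as.integer(f$width)
      } else {
        pieces[2L * i] <- f$content
        cursor <- cursor + as.integer(f$width)
      }
    }
    seqs[ch] <- paste(pieces, collapse = "")
    names(seqs)[ch] <- chrom_name
  }

  genes <- if (length(all_genes)) do.call(rbind, all_genes) else
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), start = integer(0), end = integer(0))
  exons <- if (length(all_exons)) do.call(rbind, all_exons) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), exon_rank = integer(0))
  exons <- exons[order(exons$gene_id, exons$exon_rank), , drop = FALSE]
  rownames(genes) <- NULL; rownames(exons) <- NULL
  sites <- if (length(all_sites)) do.call(rbind, all_sites) else
    data.frame(chrom = character(0), start = integer(0), width = integer(0),
               category = character(0), size = integer(0),
               motif_len = integer(0))
  list(seqs = seqs, genes = genes, exons = exons,
       cds = unlist(all_cds), sv_sites = sites)
}

SENSE_CODONS <- {
  all3 <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                paste0), c("A","C","G","T"), paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Partition gene loci into allele classes
#'
#' Loci are apportioned to the four classes (\code{two_allele},
#' \code{multi_allele}, \code{unpaired}, \code{identical}) by
#' largest-remainder rounding of \code{allele_class_mix}, then assigned to a
#' random permutation of the loci. For \code{unpaired} loci the missing side
#' alternates between haplotypes.
#'
#' @param genes Monoploid gene table (one row per locus).
#' @param config A \linkS4class{SimConfig}.
#' @return Data frame with \code{locus_id}, \code{gene_id}, \code{class},
#'   \code{missing_side} (NA except for unpaired loci).
#' @export
assignAlleleClasses <- function(genes, config) {
  stopifnot(is(config, "SimConfig"))
  n <- nrow(genes)
  counts <- .largest_remainder(config@allele_class_mix[ALLELE_CLASSES], n)
  if (sum(counts) != n) stop("sizing error: class mixture does not apportion")
  set.seed(config@seed + 3L)
  cls <- rep(names(counts), times = counts)
  cls <- cls[sample(n)]
  miss <- rep(NA_character_, n)
  up <- which(cls == "unpaired")
  if (length(up)) miss[up] <- rep(c("B", "A"), length.out = length(up))
  data.frame(locus_id = sprintf("L%05d", seq_len(n)),
             gene_id = genes$gene_id, class = cls, missing_side = miss)
}

# ---- haplotype derivation --------------------------------------------------

# pick a stop-safe substitution inside a CDS; returns list(pos0, ref, alt) in
# coding orientation or NULL
.safe_cds_sub <- function(cds, pos0) {
  ci <- pos0 %/% 3L
  codon <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
  p <- pos0 %% 3L + 1L
  ref <- substr(codon, p, p)
  alts <- setdiff(BASES, ref)
  alts <- alts[sample(length(alts))]
  for (a in alts) {
    mut <- codon
    substr(mut, p, p) <- a
    if (!(mut %in% .stop_codons)) return(list(pos0 = pos0, ref = ref, alt = a))
  }
  NULL
}

# map a 0-based CDS position to genomic coordinates for a 2-exon gene
.cds_to_genomic <- function(pos0, exons, strand) {
  l1 <- exons$end[1] - exons$start[1]
  if (strand == "+") {
    if (pos0 < l1) exons$start[1] + pos0
    else exons$start[2] + (pos0 - l1)
  } else {
    if (pos0 < l1) exons$end[1] - 1L - pos0
    else exons$end[2] - 1L - (pos0 - l1)
  }
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Derive two haplotypes from a monoploid reference
#'
#' Haplotype A is the monoploid unchanged; haplotype B carries planted SNPs,
#' small indels (1-49 bp), the configured six-category structural variants at
#' the reserved sites, at least one coding substitution per
#' two-allele/multi-allele locus, tandem gene duplications for multi-allele
#' loci, and annotation loss on one side for unpaired loci. Loci assigned to
#' the \code{identical} class are kept free of any planted event. Every event
#' is recorded with A-side and B-side coordinates.
#'
#' @param mono Output of \code{\link{generateMonoploid}}.
#' @param config The same \linkS4class{SimConfig}.
#' @return List with \code{hapA}, \code{hapB} (named character vectors),
#'   per-haplotype \code{genesA}/\code{genesB}/\code{exonsA}/\code{exonsB},
#'   \code{cdsA}/\code{cdsB}, and \code{truth}.
#' @export
deriveHaplotypes <- function(mono, config) {
  stopifnot(is(config, "SimConfig"))
  classes <- assignAlleleClasses(mono$genes, config)
  set.seed(config@seed + 1L)
  chroms <- names(mono$seqs)
  genes <- mono$genes
  exons <- mono$exons
  edits <- list()          # chrom, ref_start, ref_end, alt, kind, id
  snp_truth <- list(); indel_truth <- list(); sv_truth <- list()
  paralog_truth <- list()

  cls_of <- stats::setNames(classes$class, classes$gene_id)
  locus_of <- stats::setNames(classes$locus_id, classes$gene_id)

  # --- SV edits at reserved sites ---
  sites <- mono$sv_sites
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    p <- st$start; S <- st$size
    chrseq <- mono$seqs[[st$chrom]]
    ed <- switch(st$category,
      insertion = data.frame(ref_start = p, ref_end = p,
                             alt = .rand_dna(S)),
      deletion = data.frame(ref_start = p, ref_end = p + S, alt = ""),
      tandem_expansion = data.frame(ref_start = p + S, ref_end = p + S,
        alt = substr(chrseq, p + 1L, p + S)),
      tandem_contraction = data.frame(ref_start = p + S, ref_end = p + 2L * S,
        alt = ""),
      repeat_expansion = {
        ml <- st$motif_len
        m <- substr(chrseq, p + 1L, p + ml)
        data.frame(ref_start = p + 4L * ml, ref_end = p + 4L * ml,
                   alt = strrep(m, 2L))
      },
      repeat_contraction = {
        ml <- st$motif_len
        data.frame(ref_start = p + 3L * ml, ref_end = p + 4L * ml, alt = "")
      })
    ed$chrom <- st$chrom; ed$kind <- paste0("sv:", st$category)
    edits[[length(edits) + 1L]] <- ed
    sv_truth[[length(sv_truth) + 1L]] <- data.frame(
      chrom = st$chrom, pos = p, size = S, category = st$category,
      span = st$width)
  }

  # --- forced CDS substitutions (two_allele and multi_allele loci) ---
  cds_sub_of <- list()  # per gene: data.frame(pos0, ref, alt) coding orient
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    cl <- cls_of[[g$gene_id]]
    if (!cl %in% c("two_allele", "multi_allele")) next
    cds <- mono$cds[[g$gene_id]]
    len <- nchar(cds)
    k <- max(1L, stats::rbinom(1, len, config@snp_rate))
    pos <- sort(sample.int(len, min(k, len)) - 1L)
    subs <- list()
    for (p0 in pos) {
      s <- .safe_cds_sub(cds, p0)
      if (!is.null(s)) subs[[length(subs) + 1L]] <- as.data.frame(s)
    }
    if (!length(subs)) {  # retry anywhere until one safe sub found
      for (p0 in sample.int(len) - 1L) {
        s <- .safe_cds_sub(cds, p0)
        if (!is.null(s)) { subs[[1L]] <- as.data.frame(s); break }
      }
    }
    subs <- do.call(rbind, subs)
    cds_sub_of[[g$gene_id]] <- subs
    ex <- exons[exons$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(subs))) {
      gp <- .cds_to_genomic(subs$pos0[j], ex, g$strand)
      galt <- if (g$strand == "+") subs$alt[j] else .complement[[subs$alt[j]]]
      gref <- if (g$strand == "+") subs$ref[j] else .complement[[subs$ref[j]]]
      edits[[length(edits) + 1L]] <- data.frame(
        chrom = g$chrom, ref_start = gp, ref_end = gp + 1L, alt = galt,
        kind = "snp")
      snp_truth[[length(snp_truth) + 1L]] <- data.frame(
        chrom = g$chrom, pos = gp, ref = gref, alt = galt, in_cds = TRUE)
    }
  }

  # --- paralog insertions for multi_allele loci ---
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (!identical(cls_of[[g$gene_id]], "multi_allele")) next
    body <- substr(mono$seqs[[g$chrom]], g$start + 1L, g$end)
    # extra substitutions on the copy (~2% of CDS, stop-safe)
    cds <- mono$cds[[g$gene_id]]
    len <- nchar(cds)
    ex <- exons[exons$gene_id == g$gene_id, ]
    k <- max(3L, stats::rbinom(1, len, 0.02))
    psubs <- sort(sample.int(len, min(k, len)) - 1L)
    for (p0 in psubs) {
      s <- .safe_cds_sub(cds, p0)
      if (is.null(s)) next
      gp <- .cds_to_genomic(s$pos0, ex, g$strand) - g$start  # within body
      galt <- if (g$strand == "+") s$alt else .complement[[s$alt]]
      substr(body, gp + 1L, gp + 1L) <- galt
    }
    ins_at <- g$end + 20L
    edits[[length(edits) + 1L]] <- data.frame(
      chrom = g$chrom, ref_start = ins_at, ref_end = ins_at, alt = body,
      kind = paste0("paralog:", g$gene_id))
    paralog_truth[[length(paralog_truth) + 1L]] <- data.frame(
      chrom = g$chrom, pos = ins_at, size = nchar(body),
      locus_id = locus_of[[g$gene_id]], gene_id = g$gene_id)
  }

  # --- eligibility masks for background SNPs and indels ---
  guard <- 60L
  snp_elig <- list(); indel_elig <- list()
  for (ch in chroms) {
    L <- nchar(mono$seqs[[ch]])
    sm <- rep(TRUE, L); im <- rep(TRUE, L)
    exch <- exons[exons$chrom == ch, ]
    for (j in seq_len(nrow(exch))) {
      a <- max(1L, exch$start[j] - 1L); b <- min(L, exch$end[j] + 2L)
      sm[a:b] <- FALSE
      a2 <- max(1L, exch$start[j] - guard); b2 <- min(L, exch$end[j] + guard)
      im[a2:b2] <- FALSE
    }
    gch <- genes[genes$chrom == ch, ]
    for (j in seq_len(nrow(gch))) {
      cl <- cls_of[[gch$gene_id[j]]]
      a <- max(1L, gch$start[j] - guard)
      b <- min(L, gch$end[j] + guard + 40L)
      if (identical(cl, "identical")) { sm[a:b] <- FALSE; im[a:b] <- FALSE }
      if (identical(cl, "multi_allele")) {  # keep paralog junction clean
        a3 <- max(1L, gch$end[j] - 5L); b3 <- min(L, gch$end[j] + guard + 40L)
        sm[a3:b3] <- FALSE; im[a3:b3] <- FALSE
      }
    }
    sch <- sites[sites$chrom == ch, ]
    for (j in seq_len(nrow(sch))) {
      a <- max(1L, sch$start[j] - guard + 1L)
      b <- min(L, sch$start[j] + sch$width[j] + guard)
      sm[a:b] <- FALSE; im[a:b] <- FALSE
    }
    snp_elig[[ch]] <- sm; indel_elig[[ch]] <- im
  }

  # --- background SNPs ---
  for (ch in chroms) {
    elig <- which(snp_elig[[ch]])  # 1-based positions
    if (!length(elig)) next
    n <- stats::rbinom(1, length(elig), config@snp_rate)
    if (n == 0) next
    pos <- sort(sample(elig, n))
    refb <- substring(mono$seqs[[ch]], pos, pos)
    altb <- vapply(refb, function(r) sample(setdiff(BASES, r), 1), "")
    edits[[length(edits) + 1L]] <- data.frame(
      chrom = ch, ref_start = pos - 1L, ref_end = pos, alt = altb,
      kind = "snp")
    snp_truth[[length(snp_truth) + 1L]] <- data.frame(
      chrom = ch, pos = pos - 1L, ref = refb, alt = altb, in_cds = FALSE)
  }

  # --- background small indels ---
  for (ch in chroms) {
    eligv <- indel_elig[[ch]]
    elig <- which(eligv)
    if (!length(elig)) next
    n <- stats::rbinom(1, length(elig), config@small_indel_rate)
    if (n == 0) next
    pos <- sort(sample(elig, n))
    sizes <- pmin(1L + stats::rgeom(n, 0.18), 49L)
    kinds <- sample(c("small_insertion", "small_deletion"), n, replace = TRUE)
    for (j in seq_len(n)) {
      p <- pos[j]; S <- sizes[j]
      if (kinds[j] == "small_deletion") {
        if (p + S - 1L > length(eligv) || !all(eligv[p:(p + S - 1L)])) next
        edits[[length(edits) + 1L]] <- data.frame(
          chrom = ch, ref_start = p - 1L, ref_end = p - 1L + S, alt = "",
          kind = "small_deletion")
        indel_truth[[length(indel_truth) + 1L]] <- data.frame(
          chrom = ch, pos = p - 1L, size = S, kind = "small_deletion",
          seq = substr(mono$seqs[[ch]], p, p + S - 1L))
      } else {
        ins <- .rand_dna(S)
        edits[[length(edits) + 1L]] <- data.frame(
          chrom = ch, ref_start = p - 1L, ref_end = p - 1L, alt = ins,
          kind = "small_insertion")
        indel_truth[[length(indel_truth) + 1L]] <- data.frame(
          chrom = ch, pos = p - 1L, size = S, kind = "small_insertion",
          seq = ins)
      }
    }
  }

  edits <- if (length(edits)) do.call(rbind, edits) else
    data.frame(chrom = character(0), ref_start = integer(0),
               ref_end = integer(0), alt = character(0), kind = character(0))

  # --- resolve residual collisions (background vs background), keep first ---
  edits <- edits[order(edits$chrom, edits$ref_start, edits$ref_end), ,
                 drop = FALSE]
  keep <- rep(TRUE, nrow(edits))
  last_end <- -1L; last_ch <- ""
  for (i in seq_len(nrow(edits))) {
    if (edits$chrom[i] != last_ch) { last_ch <- edits$chrom[i]; last_end <- -1L }
    if (edits$ref_start[i] < last_end) { keep[i] <- FALSE; next }
    last_end <- max(last_end, edits$ref_end[i])
  }
  dropped <- edits[!keep, , drop = FALSE]
  edits <- edits[keep, , drop = FALSE]
  # prune truth records of dropped background edits
  if (nrow(dropped)) {
    dk <- paste(dropped$chrom, dropped$ref_start, dropped$kind)
    prune <- function(df, kind) {
      if (!nrow(df)) return(df)
      df[!(paste(df$chrom, df$pos, kind) %in% dk), , drop = FALSE]
    }
    if (length(snp_truth)) {
      st <- do.call(rbind, snp_truth)
      st <- st[!(paste(st$chrom, st$pos, "snp") %in% dk), , drop = FALSE]
      snp_truth <- list(st)
    }
    if (length(indel_truth)) {
      it <- do.call(rbind, indel_truth)
      it <- it[!(paste(it$chrom, it$pos, it$kind) %in% dk), , drop = FALSE]
      indel_truth <- list(it)
    }
  }

  # --- build haplotype B and lift coordinates ---
  hapB <- mono$seqs
  genesB <- genes; exonsB <- exons
  genesB$gene_id <- .prefix_ids("HB.", genesB$gene_id)
  exonsB$gene_id <- .prefix_ids("HB.", exonsB$gene_id)
  pos_b_map <- list()
  for (ch in chroms) {
    ech <- edits[edits$chrom == ch, , drop = FALSE]
    hapB[[ch]] <- .apply_edits(mono$seqs[[ch]], ech)
    gsel <- genesB$chrom == ch
    genesB$start[gsel] <- .lift_positions(genesB$start[gsel], ech)
    genesB$end[gsel] <- .lift_positions(genesB$end[gsel], ech)
    esel <- exonsB$chrom == ch
    exonsB$start[esel] <- .lift_positions(exonsB$start[esel], ech)
    exonsB$end[esel] <- .lift_positions(exonsB$end[esel], ech)
    pos_b_map[[ch]] <- ech
  }

  # paralog gene models on B
  para_df <- if (length(paralog_truth)) do.call(rbind, paralog_truth) else
    data.frame(chrom = character(0), pos = integer(0), size = integer(0),
               locus_id = character(0), gene_id = character(0))
  paraB_genes <- list(); paraB_exons <- list()
  for (j in seq_len(nrow(para_df))) {
    pd <- para_df[j, ]
    ech <- pos_b_map[[pd$chrom]]
    # shift accumulated strictly before this insertion edit
    idx <- which(ech$ref_start == pd$pos & ech$ref_end == pd$pos &
                 startsWith(ech$kind, "paralog:"))
    shifts <- nchar(ech$alt) - (ech$ref_end - ech$ref_start)
    before <- if (idx > 1) sum(shifts[seq_len(idx - 1L)]) else 0L
    b_start <- pd$pos + before
    g <- genes[genes$gene_id == pd$gene_id, ]
    ex <- exons[exons$gene_id == pd$gene_id, ]
    pid <- paste0("HB.", pd$gene_id, "P1")
    paraB_genes[[j]] <- data.frame(
      gene_id = pid, chrom = pd$chrom, strand = g$strand,
      start = b_start, end = b_start + pd$size)
    paraB_exons[[j]] <- data.frame(
      gene_id = pid, chrom = pd$chrom,
      start = b_start + (ex$start - g$start),
      end = b_start + (ex$end - g$start), exon_rank = ex$exon_rank)
  }
  if (length(paraB_genes)) {
    genesB <- rbind(genesB, do.call(rbind, paraB_genes))
    exonsB <- rbind(exonsB, do.call(rbind, paraB_exons))
  }

  # unpaired loci: drop the missing side's annotation
  genesA <- genes
  genesA$gene_id <- .prefix_ids("HA.", genesA$gene_id)
  exonsA <- exons
  exonsA$gene_id <- .prefix_ids("HA.", exonsA$gene_id)
  missA <- classes$gene_id[!is.na(classes$missing_side) &
                           classes$missing_side == "A"]
  missB <- classes$gene_id[!is.na(classes$missing_side) &
                           classes$missing_side == "B"]
  genesA <- genesA[!genesA$gene_id %in% paste0("HA.", missA), , drop = FALSE]
  exonsA <- exonsA[!exonsA$gene_id %in% paste0("HA.", missA), , drop = FALSE]
  genesB <- genesB[!genesB$gene_id %in% paste0("HB.", missB), , drop = FALSE]
  exonsB <- exonsB[!exonsB$gene_id %in% paste0("HB.", missB), , drop = FALSE]
  genesA <- genesA[order(genesA$chrom, genesA$start), , drop = FALSE]
  genesB <- genesB[order(genesB$chrom, genesB$start), , drop = FALSE]
  rownames(genesA) <- NULL; rownames(genesB) <- NULL

  cdsA <- .extract_cds(mono$seqs, genesA, exonsA)
  cdsB <- .extract_cds(hapB, genesB, exonsB)

  # truth assembly with B-side coordinates
  st <- if (length(snp_truth)) do.call(rbind, snp_truth) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), in_cds = logical(0))
  it <- if (length(indel_truth)) do.call(rbind, indel_truth) else
    data.frame(chrom = character(0), pos = integer(0), size = integer(0),
               kind = character(0), seq = character(0))
  svt <- if (length(sv_truth)) do.call(rbind, sv_truth) else
    data.frame(chrom = character(0), pos = integer(0), size = integer(0),
               category = character(0), span = integer(0))
  liftb <- function(df) {
    if (!nrow(df)) { df$pos_b <- integer(0); return(df) }
    df$pos_b <- NA_integer_
    for (ch in unique(df$chrom)) {
      sel <- df$chrom == ch
      df$pos_b[sel] <- .lift_positions(df$pos[sel], pos_b_map[[ch]])
    }
    df
  }
  st <- liftb(st); it <- liftb(it); svt <- liftb(svt)
  rownames(st) <- NULL; rownames(it) <- NULL; rownames(svt) <- NULL

  allele_truth <- if (nrow(classes)) data.frame(
    locus_id = classes$locus_id, class = classes$class,
    geneA = ifelse(classes$gene_id %in% missA, NA_character_,
                   paste0("HA.", classes$gene_id)),
    geneB = ifelse(classes$gene_id %in% missB, NA_character_,
                   paste0("HB.", classes$gene_id)),
    paralogB = rep(NA_character_, nrow(classes)))
  else data.frame(locus_id = character(0), class = character(0),
                  geneA = character(0), geneB = character(0),
                  paralogB = character(0))
  if (nrow(para_df)) {
    m <- match(para_df$locus_id, allele_truth$locus_id)
    allele_truth$paralogB[m] <- paste0("HB.", para_df$gene_id, "P1")
  }

  truth <- list(planted_snps = st, planted_indels = it, planted_svs = svt,
                allele_truth = allele_truth,
                paralog_insertions = para_df,
                edits = edits)
  list(hapA = mono$seqs, hapB = hapB,
       genesA = genesA, genesB = genesB, exonsA = exonsA, exonsB = exonsB,
       cdsA = cdsA, cdsB = cdsB, truth = truth)
}

# extract coding sequences (coding orientation) from chromosome strings
.extract_cds <- function(seqs, genes, exons) {
  out <- character(nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, ]
    ex <- ex[order(ex$exon_rank), , drop = FALSE]
    parts <- substring(seqs[[g$chrom]], ex$start + 1L, ex$end)
    if (g$strand == "+") out[i] <- paste(parts, collapse = "")
    else out[i] <- paste(vapply(parts, .revcomp, ""), collapse = "")
  }
  out
}

#' Simulate allele-level expression counts across tissues
#'
#' Counts follow a negative-binomial model: the log mean is
#' \code{expr_mean_log} plus a per-locus per-tissue effect (shared by the two
#' alleles of a pair, SD \code{tissue_effect_sd}) plus half the allelic
#' log-ratio (SD \code{allele_effect_sd}) with opposite signs on the two
#' alleles. Dispersion is introduced as a Gamma(1/phi, phi) multiplier shared
#' by the two alleles of a pair within a tissue, so marginal counts are
#' NB(mu, mu + phi mu^2) while the allelic ratio conditional on the pair
#' total stays exactly binomial.
#'
#' @param allele_truth Locus table from \code{\link{deriveHaplotypes}}.
#' @param eff_length Named CDS lengths for all genes.
#' @param config A \linkS4class{SimConfig}.
#' @return List with \code{counts} (gene x tissue matrix), \code{ase_truth}
#'   (locus, tissue, log_ratio) and \code{expr_truth} (gene, tissue, mean).
#' @export
simulateExpression <- function(allele_truth, eff_length, config) {
  stopifnot(is(config, "SimConfig"))
  if (config@tissue_effect_sd < 0 || config@allele_effect_sd < 0)
    stop("config error: effect SDs must be non-negative")
  set.seed(config@seed + 2L)
  tissues <- config@tissues
  nt <- length(tissues)
  gene_ids <- names(eff_length)
  counts <- matrix(0L, nrow = length(gene_ids), ncol = nt,
                   dimnames = list(gene_ids, tissues))
  expr_truth <- list(); ase_rows <- list()
  phi <- config@nb_dispersion
  for (i in seq_len(nrow(allele_truth))) {
    lt <- allele_truth[i, ]
    teff <- stats::rnorm(nt, 0, config@tissue_effect_sd)
    aeff <- stats::rnorm(1, 0, config@allele_effect_sd)
    G <- if (phi > 0) stats::rgamma(nt, shape = 1 / phi, scale = phi)
         else rep(1, nt)
    members <- c(A = lt$geneA, B = lt$geneB)
    members <- members[!is.na(members)]
    for (side in names(members)) {
      gid <- members[[side]]
      if (!gid %in% gene_ids) next
      off <- if (length(members) == 2)
        (if (side == "A") aeff / 2 else -aeff / 2) else 0
      mu <- exp(config@expr_mean_log + teff + off)
      counts[gid, ] <- stats::rpois(nt, mu * G)
      expr_truth[[length(expr_truth) + 1L]] <- data.frame(
        gene_id = gid, tissue = tissues, mean = mu)
    }
    if (length(members) == 2)
      ase_rows[[length(ase_rows) + 1L]] <- data.frame(
        locus_id = lt$locus_id, tissue = tissues, log_ratio = aeff)
    if (!is.na(lt$paralogB) && lt$paralogB %in% gene_ids) {
      Gp <- if (phi > 0) stats::rgamma(nt, shape = 1 / phi, scale = phi)
            else rep(1, nt)
      mu <- exp(config@expr_mean_log + teff)
      counts[lt$paralogB, ] <- stats::rpois(nt, mu * Gp)
      expr_truth[[length(expr_truth) + 1L]] <- data.frame(
        gene_id = lt$paralogB, tissue = tissues, mean = mu)
    }
  }
  list(counts = counts,
       ase_truth = if (length(ase_rows)) do.call(rbind, ase_rows) else
         data.frame(locus_id = character(0), tissue = character(0),
                    log_ratio = numeric(0)),
       expr_truth = if (length(expr_truth)) do.call(rbind, expr_truth) else
         data.frame(gene_id = character(0), tissue = character(0),
                    mean = numeric(0)))
}

#' Generate a complete synthetic diploid bundle
#'
#' Runs \code{\link{generateMonoploid}}, \code{\link{deriveHaplotypes}} and
#' \code{\link{simulateExpression}} and wraps the result in a
#' \linkS4class{SimBundle}. Byte-identical output for identical
#' configurations.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return A \linkS4class{SimBundle}.
#' @examples
#' \donttest{
#' b <- simulateDiploid(simConfig(n_chromosomes = 1, chrom_length = 100000L,
#'   n_genes = 20, seed = 7L))
#' }
#' @export
simulateDiploid <- function(config = simConfig()) {
  mono <- generateMonoploid(config)
  hap <- deriveHaplotypes(mono, config)
  eff <- vapply(hap$cdsB, nchar, 1L)
  effA <- vapply(hap$cdsA, nchar, 1L)
  eff_length <- c(effA, eff)
  expr <- simulateExpression(hap$truth$allele_truth, eff_length, config)
  truth <- hap$truth
  truth$ase_truth <- expr$ase_truth
  truth$expr_truth <- expr$expr_truth
  new("SimBundle",
      monoploid = Biostrings::DNAStringSet(mono$seqs),
      hapA = Biostrings::DNAStringSet(hap$hapA),
      hapB = Biostrings::DNAStringSet(hap$hapB),
      genesA = hap$genesA, genesB = hap$genesB,
      exonsA = hap$exonsA, exonsB = hap$exonsB,
      cdsA = Biostrings::DNAStringSet(hap$cdsA),
      cdsB = Biostrings::DNAStringSet(hap$cdsB),
      truth = truth, counts = expr$counts, eff_length = eff_length,
      config = config)
}
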