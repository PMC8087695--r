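#' Affine-gap global alignment (Gotoh)
#'
#' Optimal global alignment under an affine gap model: a gap of length L
#' costs \code{gap_open + (L-1) * gap_extend}. Ties are broken
#' deterministically: match/mismatch is preferred over a gap in \code{b},
#' which is preferred over a gap in \code{a}.
#'
#' @param a,b Non-empty sequences (character scalars).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters. Defaults
#'   +1 / -1 / -2 / -0.5.
#' @return A list with \code{aligned_a}, \code{aligned_b} (equal-length
#'   gapped strings) and \code{score}.
#' @examples
#' globalAlign("ACGTACGT", "ACGAACGT")$score
#' @export
globalAlign <- function(a, b, match = 1, mismatch = -1,
                        gap_open = -2, gap_extend = -0.5) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  if (mismatch >= match) stop("mismatch score must be below match score")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  .gotoh_align(a, b, match, mismatch, gap_open, gap_extend)
}

#' Pairwise similarity of an alignment
#'
#' Identical columns divided by the number of columns remaining after
#' trimming terminal gap runs at both ends. Symmetric in the two rows.
#'
#' @param aln A list with \code{aligned_a} and \code{aligned_b} as returned
#'   by \code{\link{globalAlign}}.
#' @return Similarity in [0, 1].
#' @examples
#' alignSimilarity(globalAlign("ACGTACGT", "ACGAACGT"))
#' @export
alignSimilarity <- function(aln) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("aligned rows differ in length")
  gap <- ca == "-" | cb == "-"
  n <- length(ca)
  lead <- 0L
  while (lead < n && gap[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && gap[n - trail]) trail <- trail + 1L
  keep <- if (lead + trail >= n) integer(0) else (lead + 1L):(n - trail)
  if (length(keep) == 0) stop("no columns remain after trimming terminal gaps")
  sum(ca[keep] == cb[keep]) / length(keep)
}

#' Codon-aware alignment of two coding sequences
#'
#' Translates both CDS, globally aligns the proteins with unit scores
#' (match +1, mismatch 0, gap open -2, gap extend -0.5) and threads the
#' protein alignment back onto codons, so gaps occur only in multiples of
#' three nucleotides.
#'
#' @param cds_a,cds_b Coding sequences; lengths divisible by 3, no internal
#'   stop codons.
#' @return List with codon-level \code{aligned_a}, \code{aligned_b} and the
#'   protein alignment \code{score}.
#' @examples
#' codonAlign("ATGAAAGGG", "ATGAAAGGG")
#' @export
codonAlign <- function(cds_a, cds_b) {
  for (s in list(cds_a, cds_b)) {
    if (nchar(s) %% 3 != 0) stop("CDS length must be divisible by 3")
    if (nchar(s) < 3) stop("CDS too short")
  }
  codons_a <- .split_codons(cds_a)
  codons_b <- .split_codons(cds_b)
  aa_a <- .codon_aa(codons_a)
  aa_b <- .codon_aa(codons_b)
  if (any(is.na(aa_a)) || any(is.na(aa_b))) stop("invalid codon in CDS")
  if (any(aa_a[-length(aa_a)] == "*") || any(aa_b[-length(aa_b)] == "*") ||
      aa_a[length(aa_a)] == "*" || aa_b[length(aa_b)] == "*")
    stop("internal stop codon in CDS; pair excluded from rate estimation")
  paln <- .gotoh_align(paste(aa_a, collapse = ""), paste(aa_b, collapse = ""),
                       1, 0, -2, -0.5)
  pa <- strsplit(paln$aligned_a, "", fixed = TRUE)[[1]]
  pb <- strsplit(paln$aligned_b, "", fixed = TRUE)[[1]]
  ia <- 0L; ib <- 0L
  outa <- character(length(pa)); outb <- character(length(pb))
  for (i in seq_along(pa)) {
    if (pa[i] == "-") outa[i] <- "---" else {
      ia <- ia + 1L; outa[i] <- codons_a[ia]
    }
    if (pb[i] == "-") outb[i] <- "---" else {
      ib <- ib + 1L; outb[i] <- codons_b[ib]
    }
  }
  list(aligned_a = paste(outa, collapse = ""),
       aligned_b = paste(outb, collapse = ""),
       score = paln$score)
}

.split_codons <- function(s) {
  n <- nchar(s) %/% 3
  substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# ---- Nei-Gojobori (1986) machinery ----------------------------------------

# synonymous site fraction per codon: for each of the 3 positions, the
# fraction of the 3 alternative bases that preserve the amino acid.
# Changes to stop codons count as nonsynonymous, so fractions sum to 3.
.ng86_sites_one <- function(codon) {
  aa <- .codon_aa(codon)
  s <- 0
  for (p in 1:3) {
    ref <- substr(codon, p, p)
    for (b in BASES) {
      if (b == ref) next
      mut <- codon
      substr(mut, p, p) <- b
      if (identical(unname(.codon_aa(mut)), unname(aa))) s <- s + 1 / 3
    }
  }
  s
}

# average syn/nonsyn differences between two codons over all minimal
# mutational pathways; pathways through stop codons are excluded (falling
# back to all pathways if every one is blocked)
.ng86_diffs_one <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(nd = 0, sd = 0))
  perms <- .permutations(pos)
  tot_nd <- 0; tot_sd <- 0; nvalid <- 0
  all_nd <- 0; all_sd <- 0
  for (k in seq_len(nrow(perms))) {
    cur <- c1
    nd <- 0; sd <- 0; ok <- TRUE
    for (p in perms[k, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (.codon_aa(nxt) == "*") ok <- FALSE
      if (identical(.codon_aa(nxt), .codon_aa(cur))) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    all_nd <- all_nd + nd; all_sd <- all_sd + sd
    if (ok) { tot_nd <- tot_nd + nd; tot_sd <- tot_sd + sd; nvalid <- nvalid + 1 }
  }
  if (nvalid > 0) c(nd = tot_nd / nvalid, sd = tot_sd / nvalid)
  else c(nd = all_nd / nrow(perms), sd = all_sd / nrow(perms))
}

.permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

# cache of per-codon sites and per-pair differences, filled lazily
.ng86_cache <- new.env(parent = emptyenv())

.ng86_sites <- function(codon) {
  key <- paste0("S", codon)
  v <- .ng86_cache[[key]]
  if (is.null(v)) {
    v <- .ng86_sites_one(codon)
    assign(key, v, envir = .ng86_cache)
  }
  v
}

.ng86_diffs <- function(c1, c2) {
  key <- paste0("D", c1, c2)
  v <- .ng86_cache[[key]]
  if (is.null(v)) {
    v <- .ng86_diffs_one(c1, c2)
    assign(key, v, envir = .ng86_cache)
  }
  v
}

#' Nei-Gojobori (1986) Ka/Ks from a codon alignment
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the
#' two sequences), averages syn/nonsyn differences over all minimal
#' mutational pathways between differing codons (pathways through stop
#' codons excluded), and applies the Jukes-Cantor correction
#' d = -(3/4) log(1 - (4/3) p). Codon columns containing any gap are dropped.
#'
#' @param codon_aln Codon alignment from \code{\link{codonAlign}}.
#' @return List with \code{ka}, \code{ks}, \code{ratio} (NA when \code{ks}
#'   is 0), site counts \code{n_sites}, \code{s_sites}, difference counts
#'   \code{nd}, \code{sd}, and a \code{flag} (\code{"ok"},
#'   \code{"ratio_undefined"}, \code{"identical"} or \code{"saturated"}).
#' @examples
#' kaksNG86(codonAlign("ATGAAA", "ATGAGA"))
#' @export
kaksNG86 <- function(codon_aln) {
  ca <- .split_codons(codon_aln$aligned_a)
  cb <- .split_codons(codon_aln$aligned_b)
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0) stop("no ungapped codon columns")
  Ssum <- 0; ndsum <- 0; sdsum <- 0
  for (i in seq_along(ca)) {
    Ssum <- Ssum + (.ng86_sites(ca[i]) + .ng86_sites(cb[i])) / 2
    if (ca[i] != cb[i]) {
      d <- .ng86_diffs(ca[i], cb[i])
      ndsum <- ndsum + d[["nd"]]
      sdsum <- sdsum + d[["sd"]]
    }
  }
  total <- 3 * length(ca)
  Nsum <- total - Ssum
  pN <- if (Nsum > 0) ndsum / Nsum else 0
  pS <- if (Ssum > 0) sdsum / Ssum else 0
  flag <- "ok"
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ka <- jc(pN); ks <- jc(pS)
  if (is.na(ka) || is.na(ks)) flag <- "saturated"
  ratio <- NA_real_
  if (!is.na(ka) && !is.na(ks)) {
    if (ks > 0) ratio <- ka / ks
    else if (ka > 0) flag <- "ratio_undefined"
    else flag <- "identical"
  } else if (!is.na(ka) && ka == 0 && sdsum > 0) {
    # no nonsynonymous change at all: the ratio is 0 even when the
    # synonymous proportion saturates the correction
    ratio <- 0
    flag <- "ok"
  }
  list(ka = ka, ks = ks, ratio = ratio,
       n_sites = Nsum, s_sites = Ssum, nd = ndsum, sd = sdsum, flag = flag)
}
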