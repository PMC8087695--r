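# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
.BASE_CODES <- c(A = 65L, C = 67L, G = 71L, T = 84L)

# fast random DNA string
.rand_dna <- function(n) {
  if (n <= 0) return("")
  intToUtf8(sample(.BASE_CODES, n, replace = TRUE))
}

.revcomp <- function(s) {
  if (nchar(s) == 0) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# signed size bin labels for structural variants
#' Assign Table-style size bins to SV sizes
#'
#' Bins are 50-500, 500-10000, 10000-50000 and 50000-100000 bp; lower bound
#' inclusive, upper exclusive, final bin closed at 100000.
#'
#' @param size Integer vector of SV sizes in bp.
#' @return Character vector of bin labels (NA outside [50, 100000]).
#' @examples svSizeBin(c(300, 600, 20000))
#' @export
svSizeBin <- function(size) {
  out <- rep(NA_character_, length(size))
  out[size >= 50 & size < 500] <- "50-500"
  out[size >= 500 & size < 10000] <- "500-10000"
  out[size >= 10000 & size < 50000] <- "10000-50000"
  out[size >= 50000 & size <= 100000] <- "50000-100000"
  out
}

SV_SIZE_BINS <- c("50-500", "500-10000", "10000-50000", "50000-100000")

# largest-remainder apportionment of proportions into integer counts
.largest_remainder <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ord <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE),
                 method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

# apply a sorted non-overlapping edit table (ref_start, ref_end, alt) to a
# sequence string; returns the edited string
.apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0) return(seq)
  edits <- edits[order(edits$ref_start, edits$ref_end), , drop = FALSE]
  if (any(edits$ref_start[-1] < edits$ref_end[-nrow(edits)]))
    stop("overlapping edits")
  n <- nchar(seq)
  pieces <- character(2 * nrow(edits) + 1)
  prev <- 0L
  for (i in seq_len(nrow(edits))) {
    pieces[2 * i - 1] <- substr(seq, prev + 1L, edits$ref_start[i])
    pieces[2 * i] <- edits$alt[i]
    prev <- edits$ref_end[i]
  }
  pieces[2 * nrow(edits) + 1] <- substr(seq, prev + 1L, n)
  paste(pieces, collapse = "")
}

# map 0-based positions on the reference through an edit table to the edited
# sequence's coordinates (positions inside replaced spans map to span start)
.lift_positions <- function(pos, edits) {
  if (nrow(edits) == 0) return(pos)
  edits <- edits[order(edits$ref_start), , drop = FALSE]
  shift <- nchar(edits$alt) - (edits$ref_end - edits$ref_start)
  cum <- cumsum(shift)
  idx <- findInterval(pos, edits$ref_end)  # edits fully before pos
  out <- pos + ifelse(idx > 0, cum[idx], 0L)
  as.integer(out)
}

.stop_codons <- c("TAA", "TAG", "TGA")

# genetic code lookup (universal code)
.codon_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

# paste0 recycles zero-length vectors against a scalar prefix; this does not
.prefix_ids <- function(prefix, x) {
  if (length(x) == 0) return(character(0))
  paste0(prefix, x)
}

.chunk_evenly <- function(n, k) {
  # split n items into k chunks as evenly as possible
  base <- n %/% k
  extra <- n %% k
  rep(seq_len(k), times = base + (seq_len(k) <= extra))[seq_len(n)]
}
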