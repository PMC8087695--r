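# Independent oracles used across the test suite. These deliberately use
# different algorithms from the package implementation: exhaustive recursion
# instead of dynamic programming, direct permutation walks instead of cached
# tables.

# exhaustive affine-gap global alignment score: plain recursion over every
# alignment path (feasible for sequences up to ~8 bp)
oracleAlignScore <- function(a, b, match = 1, mismatch = -1,
                             gap_open = -2, gap_extend = -0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, prev) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      s <- if (av[i + 1] == bv[j + 1]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i < n) {
      cost <- if (identical(prev, "X")) gap_extend else gap_open
      best <- max(best, cost + rec(i + 1, j, "X"))
    }
    if (j < m) {
      cost <- if (identical(prev, "Y")) gap_extend else gap_open
      best <- max(best, cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(0, 0, "none")
}

# brute-force Nei-Gojobori counts for one codon pair: site fractions read
# straight off the genetic code, differences averaged over explicit
# permutation walks with stop-codon pathways excluded
oracleNG86 <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(codon) {
    total <- 0
    for (p in 1:3) for (b in bases) {
      if (b == substr(codon, p, p)) next
      mut <- codon; substr(mut, p, p) <- b
      if (gc[[mut]] == gc[[codon]]) total <- total + 1 / 3
    }
    total
  }
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- sd <- 0
  if (length(pos)) {
    perms <- .oracle_perms(pos)
    accum <- matrix(0, 0, 2)
    for (k in seq_len(nrow(perms))) {
      cur <- c1; nd_k <- 0; sd_k <- 0; blocked <- FALSE
      for (p in perms[k, ]) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == "*") blocked <- TRUE
        if (gc[[nxt]] == gc[[cur]]) sd_k <- sd_k + 1 else nd_k <- nd_k + 1
        cur <- nxt
      }
      if (!blocked) accum <- rbind(accum, c(nd_k, sd_k))
    }
    if (nrow(accum) == 0) {  # all pathways blocked: average over all
      for (k in seq_len(nrow(perms))) {
        cur <- c1; nd_k <- 0; sd_k <- 0
        for (p in perms[k, ]) {
          nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
          if (gc[[nxt]] == gc[[cur]]) sd_k <- sd_k + 1 else nd_k <- nd_k + 1
          cur <- nxt
        }
        accum <- rbind(accum, c(nd_k, sd_k))
      }
    }
    nd <- mean(accum[, 1]); sd <- mean(accum[, 2])
  }
  S <- (syn_sites(c1) + syn_sites(c2)) / 2
  list(nd = nd, sd = sd, s_sites = S, n_sites = 3 - S)
}

.oracle_perms <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  do.call(rbind, lapply(seq_along(x), function(i)
    cbind(x[i], .oracle_perms(x[-i]))))
}

SENSE_CODONS_TEST <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  all3[!all3 %in% c("TAA", "TAG", "TGA")]
}

randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# a small simulated bundle shared by several test files
smallBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simConfig(n_chromosomes = 1L, chrom_length = 150000L,
        n_genes = 20L, seed = 5L,
        sv_counts = c(insertion = 1L, deletion = 1L,
          tandem_expansion = 1L, tandem_contraction = 1L,
          repeat_expansion = 1L, repeat_contraction = 1L),
        sv_size_range = c(50, 500))
      cache <<- simulateDiploid(cfg)
    }
    cache
  }
})

noSv <- c(insertion = 0L, deletion = 0L, tandem_expansion = 0L,
          tandem_contraction = 0L, repeat_expansion = 0L,
          repeat_contraction = 0L)
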