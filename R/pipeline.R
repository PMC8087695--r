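# Pipeline orchestration: simulate -> synteny -> alleles (+Ka/Ks) ->
# variants -> ASE, with a report bundle on disk, plus truth-set comparison.

#' Pipeline configuration
#'
#' Collects every stage threshold with its conventional default: cscore
#' 0.99, similarity 0.7 (strict), SV window 50-100000 bp, TPM 10 (strict),
#' ASE alpha 0.05.
#'
#' @param sim A \linkS4class{SimConfig} for the simulate stage.
#' @param cscore,similarity_threshold,min_anchors,max_rank_gap,
#'   placement_k,min_overlap_frac,min_anchor,max_gap_align,sv_min_size,
#'   sv_max_size,tpm_threshold,alpha Stage parameters.
#' @param run_ase Run the expression stage.
#' @return A named list of class \code{haplotab_config}.
#' @export
pipelineConfig <- function(sim = simConfig(),
                           cscore = 0.99, similarity_threshold = 0.7,
                           min_anchors = 4L, max_rank_gap = 25L,
                           placement_k = 21L, min_overlap_frac = 0.5,
                           min_anchor = 20L, max_gap_align = 10000L,
                           sv_min_size = 50L, sv_max_size = 100000L,
                           tpm_threshold = 10, alpha = 0.05,
                           run_ase = TRUE) {
  stopifnot(cscore > 0, cscore <= 1, similarity_threshold > 0,
            similarity_threshold < 1, sv_min_size >= 1,
            sv_max_size >= sv_min_size, alpha > 0, alpha < 1)
  structure(list(sim = sim, cscore = cscore,
                 similarity_threshold = similarity_threshold,
                 min_anchors = as.integer(min_anchors),
                 max_rank_gap = as.integer(max_rank_gap),
                 placement_k = as.integer(placement_k),
                 min_overlap_frac = min_overlap_frac,
                 min_anchor = as.integer(min_anchor),
                 max_gap_align = as.integer(max_gap_align),
                 sv_min_size = as.integer(sv_min_size),
                 sv_max_size = as.integer(sv_max_size),
                 tpm_threshold = tpm_threshold, alpha = alpha,
                 run_ase = isTRUE(run_ase)),
            class = "haplotab_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A \code{haplotab_config}.
#' @param path YAML path.
#' @export
writePipelineConfig <- function(config, path) {
  lst <- unclass(config)
  sim <- lst$sim
  lst$sim <- list(
    n_chromosomes = sim@n_chromosomes, chrom_length = sim@chrom_length,
    n_genes = sim@n_genes, snp_rate = sim@snp_rate,
    small_indel_rate = sim@small_indel_rate,
    sv_counts = as.list(sim@sv_counts),
    sv_size_range = sim@sv_size_range,
    allele_class_mix = as.list(sim@allele_class_mix),
    repeat_fraction = sim@repeat_fraction, tissues = sim@tissues,
    expr_mean_log = sim@expr_mean_log,
    tissue_effect_sd = sim@tissue_effect_sd,
    allele_effect_sd = sim@allele_effect_sd,
    nb_dispersion = sim@nb_dispersion, seed = sim@seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- lst$sim
  lst$sim <- simConfig(
    n_chromosomes = sim$n_chromosomes, chrom_length = sim$chrom_length,
    n_genes = sim$n_genes, snp_rate = sim$snp_rate,
    small_indel_rate = sim$small_indel_rate,
    sv_counts = unlist(sim$sv_counts),
    sv_size_range = unlist(sim$sv_size_range),
    allele_class_mix = unlist(sim$allele_class_mix),
    repeat_fraction = sim$repeat_fraction, tissues = sim$tissues,
    expr_mean_log = sim$expr_mean_log,
    tissue_effect_sd = sim$tissue_effect_sd,
    allele_effect_sd = sim$allele_effect_sd,
    nb_dispersion = sim$nb_dispersion, seed = sim$seed)
  do.call(pipelineConfig, lst)
}

#' Build the allele table from a simulated (or supplied) diploid
#'
#' Runs the synteny arm (k-mer-prefiltered scoring, cscore filter,
#' collinearity chaining), rescues leftover genes by monoploid placement
#' overlap, applies the similarity rule, assembles loci and computes Ka/Ks
#' with selection flags on primary pairs.
#'
#' @param bundle A \linkS4class{SimBundle} (or compatible list).
#' @param config A \code{haplotab_config}.
#' @return List with the \linkS4class{AlleleTable} (\code{table}), the
#'   pair table with rates (\code{pairs}), synteny \code{chains} and
#'   \code{placements}.
#' @export
buildAlleleTableFromBundle <- function(bundle, config = pipelineConfig()) {
  cdsA <- cdsSeqs(bundle, "A"); cdsB <- cdsSeqs(bundle, "B")
  genesA <- geneModels(bundle, "A"); genesB <- geneModels(bundle, "B")
  hits <- scoreGenePairs(cdsA, cdsB)
  filt <- cscoreFilter(hits, c = config$cscore)
  chains <- chainBlocks(filt, genesA, genesB,
                        min_anchors = config$min_anchors,
                        max_rank_gap = config$max_rank_gap)
  syn <- syntenyAlleleCandidates(chains, genesA, genesB)
  placements <- placeOnReference(c(.as_seq_vector(cdsA),
                                   .as_seq_vector(cdsB)),
                                 monoploidSeq(bundle),
                                 k = config$placement_k)
  # placement rescue: a pair participates when at least one side was left
  # out of the synteny blocks (this is what attaches paralogs to loci whose
  # primary pair came from synteny)
  plA_all <- placements[placements$gene_id %in% genesA$gene_id, ,
                        drop = FALSE]
  plB_all <- placements[placements$gene_id %in% genesB$gene_id, ,
                        drop = FALSE]
  plA <- plA_all[plA_all$gene_id %in% syn$leftover$A, , drop = FALSE]
  plB <- plB_all[plB_all$gene_id %in% syn$leftover$B, , drop = FALSE]
  resc <- rbind(
    coordinateOverlapPairs(plA, plB_all,
                           min_frac = config$min_overlap_frac),
    coordinateOverlapPairs(plA_all, plB,
                           min_frac = config$min_overlap_frac))
  resc <- resc[!duplicated(resc[, c("geneA", "geneB")]), , drop = FALSE]
  cand <- rbind(syn$pairs[, c("geneA", "geneB", "source")],
                resc[, c("geneA", "geneB", "source")])
  cand <- cand[!duplicated(cand[, c("geneA", "geneB")]), , drop = FALSE]
  cand <- pairSimilarities(cand, cdsA, cdsB)
  cand <- filterBySimilarity(cand, threshold = config$similarity_threshold)
  atab <- buildAlleleTable(cand, placements, genesA, genesB)
  pairs <- allelePairs(atab)
  if (nrow(pairs)) {
    pairs <- pairKaks(pairs, cdsA, cdsB)
    pairs <- classifySelection(pairs)
  }
  atab@pairs <- pairs
  s <- atab@summary
  prim <- pairs[pairs$role == "primary", , drop = FALSE]
  s$mean_kaks <- if (nrow(prim)) mean(prim$kaks, na.rm = TRUE) else NA_real_
  s$positive_selection <- sum(prim$selection == "positive_selection",
                              na.rm = TRUE)
  atab@summary <- s
  list(table = atab, pairs = pairs, chains = chains,
       placements = placements)
}

#' Run the full pipeline and write a report bundle
#'
#' Simulates a diploid under \code{config$sim}, builds the allele table,
#' calls variants and SVs between the haplotypes, and (optionally) runs the
#' allele-specific expression stage, writing every artifact into
#' \code{out_dir}. Two runs with the same configuration produce
#' byte-identical bundles.
#'
#' @param config A \code{haplotab_config}.
#' @param out_dir Output directory (created if needed).
#' @param bundle Optional pre-built \linkS4class{SimBundle}; when NULL one
#'   is simulated from \code{config$sim}.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir,
                        bundle = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  logln <- function(...) log <<- c(log, paste0(...))
  logln("haplotab run, package version ",
        as.character(utils::packageVersion("haplotab")))
  logln("seed: ", config$sim@seed)
  logln("thresholds: cscore=", config$cscore,
        " similarity>", config$similarity_threshold,
        " sv=[", config$sv_min_size, ",", config$sv_max_size, "]",
        " tpm>", config$tpm_threshold, " alpha=", config$alpha)

  if (is.null(bundle)) bundle <- simulateDiploid(config$sim)
  writeFasta(monoploidSeq(bundle), file.path(out_dir, "monoploid.fa"))
  writeFasta(haplotypeSeq(bundle, "A"), file.path(out_dir, "haplotypeA.fa"))
  writeFasta(haplotypeSeq(bundle, "B"), file.path(out_dir, "haplotypeB.fa"))
  writeGff3(bundle@genesA, bundle@exonsA, file.path(out_dir, "genesA.gff3"))
  writeGff3(bundle@genesB, bundle@exonsB, file.path(out_dir, "genesB.gff3"))
  writeCountsTsv(exprCounts(bundle), file.path(out_dir, "counts.tsv"))
  jsonlite::write_json(truthSet(bundle)[c("planted_snps", "planted_indels",
                                          "planted_svs", "allele_truth")],
                       file.path(out_dir, "truth.json"), dataframe = "rows",
                       na = "null")

  al <- buildAlleleTableFromBundle(bundle, config)
  writeAlleleTable(file.path(out_dir, "allele_table.tsv"), al$table)
  jsonlite::write_json(alleleSummary(al$table),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, na = "null", digits = 8)
  logln("allele table: ", nrow(alleleLoci(al$table)), " loci")

  hv <- compareHaplotypes(haplotypeSeq(bundle, "A"),
                          haplotypeSeq(bundle, "B"),
                          genesA = geneModels(bundle, "A"),
                          min_anchor = config$min_anchor,
                          max_gap_align = config$max_gap_align,
                          min_size = config$sv_min_size,
                          max_size = config$sv_max_size)
  v <- variantCalls(hv)
  snps <- v[v$kind == "snp", , drop = FALSE]
  indels <- v[v$kind != "snp", , drop = FALSE]
  indels <- data.frame(chrom = indels$chrom, pos = indels$ref_pos,
                       size = indels$size, kind = indels$kind,
                       seq = ifelse(indels$kind == "small_insertion",
                                    indels$alt, NA))
  if (nrow(indels))
    indels$seq[indels$kind == "small_deletion"] <- NA
  # deletion seq from the reference
  refs <- .as_seq_vector(haplotypeSeq(bundle, "A"))
  del <- which(indels$kind == "small_deletion")
  if (length(del))
    indels$seq[del] <- substring(refs[indels$chrom[del]],
                                 indels$pos[del] + 1L,
                                 indels$pos[del] + indels$size[del])
  writeVariantsVcf(file.path(out_dir, "variants.vcf"),
                   data.frame(chrom = snps$chrom, pos = snps$ref_pos,
                              ref = snps$ref_base, alt = snps$alt_base),
                   indels, refs)
  writeSvTable(file.path(out_dir, "svs.tsv"), svCalls(hv))
  sv_sum <- svSummary(hv)
  sv_sum$aligned_junctions <- NULL
  jsonlite::write_json(sv_sum, file.path(out_dir, "sv_summary.json"),
                       auto_unbox = TRUE, digits = 8)
  logln("variants: ", nrow(snps), " SNPs, ", nrow(indels),
        " small indels, ", nrow(svCalls(hv)), " SVs")

  ase <- NULL
  if (config$run_ase) {
    counts <- exprCounts(bundle)
    if (is.null(counts) || nrow(counts) == 0)
      stop("missing input: counts are required for the ASE stage")
    prim <- al$pairs[al$pairs$role == "primary", , drop = FALSE]
    pc <- asePairCounts(counts, prim, bundle@eff_length)
    pc <- aseTest(pc, alpha = config$alpha)
    utils::write.table(pc, file.path(out_dir, "ase.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tpm_ab <- .pair_tpm_matrix(counts, prim, bundle@eff_length,
                               bundle@config@tissues)
    cl <- sampleCorrelationCluster(tpm_ab)
    utils::write.table(
      data.frame(sample = rownames(cl$correlation), cl$correlation,
                 check.names = FALSE),
      file.path(out_dir, "corr.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    ase <- list(tests = pc, cluster = cl, tpm = tpm_ab)
    logln("ase: ", nrow(pc), " pair-tissue tests")
  }
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(list(bundle = bundle, alleles = al, variants = hv, ase = ase,
                 config = config, out_dir = out_dir))
}

# pairs x (haplotype x tissue) TPM matrix for correlation clustering
.pair_tpm_matrix <- function(counts, prim, eff_length, tissues) {
  keep <- prim$geneA %in% rownames(counts) & prim$geneB %in% rownames(counts)
  prim <- prim[keep, , drop = FALSE]
  tp <- tpm(counts[unique(c(prim$geneA, prim$geneB)), , drop = FALSE],
            eff_length)
  m <- cbind(tp[prim$geneA, tissues, drop = FALSE],
             tp[prim$geneB, tissues, drop = FALSE])
  colnames(m) <- c(paste0("A.", tissues), paste0("B.", tissues))
  rownames(m) <- prim$locus_id
  m
}

#' Compare pipeline output with the generator truth set
#'
#' Computes allele-pair recall and precision, multi-allele paralog
#' attachment, identical-pair labelling, SNP recall/precision within the
#' anchored-plus-aligned territory, and the planted-SV recovery table
#' (category match, size within a tolerance).
#'
#' @param result The list returned by \code{\link{runPipeline}} (or a list
#'   with \code{alleles} and \code{variants}).
#' @param truth A truth set from \code{\link{truthSet}}.
#' @param sv_size_tol Allowed absolute size error for SV recovery
#'   (default 5 bp).
#' @return List of recovery metrics (machine-readable).
#' @export
truthCompare <- function(result, truth, sv_size_tol = 5L) {
  if (nrow(truth$allele_truth) == 0 && nrow(truth$planted_snps) == 0)
    return(list(note = "empty truth set: no metrics computable"))
  at <- truth$allele_truth
  pair_recall <- pair_precision <- multi_attach <- ident_ok <- NA
  if (!is.null(result$alleles)) {
  pairs <- result$alleles$pairs
  prim <- pairs[pairs$role == "primary", , drop = FALSE]
  truth_pairs <- at[!is.na(at$geneA) & !is.na(at$geneB), , drop = FALSE]
  tp_keys <- paste(truth_pairs$geneA, truth_pairs$geneB)
  pred_keys <- paste(prim$geneA, prim$geneB)
  pair_recall <- if (length(tp_keys)) mean(tp_keys %in% pred_keys) else NA
  pair_precision <- if (length(pred_keys)) mean(pred_keys %in% tp_keys)
                    else NA

  # multi-allele paralog attachment
  loci <- alleleLoci(result$alleles$table)
  multi_truth <- at[at$class == "multi_allele" & !is.na(at$paralogB), ,
                    drop = FALSE]
  attach_ok <- vapply(seq_len(nrow(multi_truth)), function(i) {
    mt <- multi_truth[i, ]
    row <- loci[grepl(mt$geneA, loci$genesA, fixed = TRUE), , drop = FALSE]
    if (nrow(row) != 1) return(FALSE)
    grepl(mt$paralogB, row$genesB, fixed = TRUE) &&
      grepl(mt$geneB, row$genesB, fixed = TRUE)
  }, TRUE)
  multi_attach <- if (nrow(multi_truth)) mean(attach_ok) else NA

  ident_truth <- at[at$class == "identical" & !is.na(at$geneA) &
                    !is.na(at$geneB), , drop = FALSE]
  ident_keys <- paste(ident_truth$geneA, ident_truth$geneB)
  ident_pred <- prim[prim$status == "same_allele", , drop = FALSE]
  ident_ok <- if (nrow(ident_truth))
    mean(ident_keys %in% paste(ident_pred$geneA, ident_pred$geneB)) else NA
  }

  # SNP recovery within anchored + aligned territory
  snp_recall <- snp_precision <- sv_recovery <- NA
  in_territory <- logical(0)
  sv_ok <- logical(0)
  tsv <- truth$planted_svs
  conf <- matrix(0L, length(SV_CATEGORIES), length(SV_CATEGORIES),
                 dimnames = list(truth = SV_CATEGORIES,
                                 called = SV_CATEGORIES))
  if (!is.null(result$variants)) {
  hv <- result$variants
  blocks <- alignmentBlocks(hv)
  aj <- svSummary(hv)$aligned_junctions
  snp_calls <- variantCalls(hv)
  snp_calls <- snp_calls[snp_calls$kind == "snp", , drop = FALSE]
  ts <- truth$planted_snps
  territory <- function(ch) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    r <- IRanges::IRanges(b$ref_start + 1L, b$ref_end)
    if (!is.null(aj) && nrow(aj)) {
      a <- aj[aj$chrom == ch, , drop = FALSE]
      if (nrow(a)) r <- c(r, IRanges::IRanges(a$r1 + 1L, pmax(a$r2, a$r1)))
    }
    IRanges::reduce(r)
  }
  in_territory <- rep(FALSE, nrow(ts))
  for (ch in unique(ts$chrom)) {
    terr <- territory(ch)
    sel <- which(ts$chrom == ch)
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(ts$pos[sel] + 1L, ts$pos[sel] + 1L), terr)
    in_territory[sel] <- ov
  }
  truth_keys <- paste(ts$chrom, ts$pos, ts$alt)
  call_keys <- paste(snp_calls$chrom, snp_calls$ref_pos, snp_calls$alt_base)
  snp_recall <- if (any(in_territory))
    mean(truth_keys[in_territory] %in% call_keys) else NA
  snp_precision <- if (length(call_keys))
    mean(call_keys %in% truth_keys) else NA

  # planted SV recovery
  svs <- svCalls(hv)
  sv_ok <- logical(nrow(tsv))
  for (i in seq_len(nrow(tsv))) {
    tv <- tsv[i, ]
    win <- tv$span + 500L
    cand <- svs[svs$chrom == tv$chrom &
                svs$ref_pos >= tv$pos - win &
                svs$ref_pos <= tv$pos + tv$span + win, , drop = FALSE]
    if (!nrow(cand)) next
    j <- which.min(abs(cand$size - tv$size))
    conf[tv$category, cand$category[j]] <-
      conf[tv$category, cand$category[j]] + 1L
    sv_ok[i] <- cand$category[j] == tv$category &&
      abs(cand$size[j] - tv$size) <= sv_size_tol
  }
  sv_recovery <- if (nrow(tsv)) mean(sv_ok) else NA
  }

  list(pair_recall = pair_recall, pair_precision = pair_precision,
       multi_attach = multi_attach, identical_same_allele = ident_ok,
       snp_recall = snp_recall, snp_precision = snp_precision,
       n_truth_snps_in_territory = sum(in_territory),
       sv_recovery = sv_recovery, sv_recovered = sum(sv_ok),
       sv_planted = nrow(tsv), sv_confusion = conf)
}
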