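# haplotab

Haplotype-resolved diploid genome assemblies resolve the two chromosome
sets (haplotypes A and B) of a heterozygous individual separately. For
highly heterozygous organisms — self-incompatible crops with ~3 %
heterozygosity are the motivating case — the two haplotypes differ by
millions of SNPs, small indels and tens of thousands of structural
variants, and most protein-coding genes exist as a diverged allele pair.
`haplotab` turns such an assembly pair into:

* an **allele table** pairing each gene on A with its counterpart(s) on B,
  built from synteny blocks (cscore-filtered homology anchors chained by a
  longest-increasing-subsequence over gene ranks) plus a placement-rescue
  arm on the monoploid reference (pairs sharing more than half their
  reference coordinates), with a strict similarity rule: similarity 1 ⇒
  *same allele*, similarity > 0.7 ⇒ *allele*, otherwise rejected; extra
  genes at a locus are sorted by similarity and attached as paralogs, and
  loci are classed as multi-allele (> 2 genes), two-allele, or one-allele
  (placement evidence but no partner);
* **haplotype variation calls**: unique-anchor alignment (exact matches
  seeded at k-mers unique in both sequences, maximally extended, chained),
  SNPs and 1–49 bp indels from aligned inter-anchor gaps, and six-category
  structural variants — insertion, deletion, tandem expansion/contraction,
  repeat expansion/contraction — classified from the signs of the
  reference/query gaps at block junctions, binned 50–500 / 500–10,000 /
  10,000–50,000 / 50,000–100,000 bp, verified by splicing every call back
  into A and requiring exact reconstruction of B;
* **evolutionary rates** per allele pair: CDS similarity and Nei–Gojobori
  (1986) Ka/Ks with Jukes–Cantor correction (sites counted per codon,
  differences averaged over minimal mutational pathways excluding stops),
  with a positive-selection flag at Ka/Ks > 1;
* **allele-specific expression**: TPM normalisation, a strict TPM > 10
  highly-expressed filter, exact two-sided binomial imbalance tests
  against a length-corrected null with BH adjustment per tissue, and
  average-linkage clustering of sample correlations on log₂(TPM+1).

A synthetic diploid generator (`simConfig()`/`simulateDiploid()`) plants
all of these events with a full ground-truth record, so the entire
pipeline is testable and benchmarkable offline; `truthCompare()` measures
recovery against the truth.

## Worked example

Simulate a small diploid (1 × 300 kb, 60 gene loci, 12 planted SVs), build
the allele table, call variants, and compare to the truth:

```r
library(haplotab)
cfg <- simConfig(n_chromosomes = 1L, chrom_length = 300000L, n_genes = 60L,
  sv_counts = c(insertion = 2L, deletion = 2L, tandem_expansion = 2L,
                tandem_contraction = 2L, repeat_expansion = 2L,
                repeat_contraction = 2L),
  sv_size_range = c(50, 2000), seed = 42L)
bundle <- simulateDiploid(cfg)
bundle
#> SimBundle: 1 chromosome(s), 59 HA / 64 HB genes
#>   planted: 2279 SNPs, 191 small indels, 12 SVs
#>   counts: 123 genes x 5 tissues

al <- buildAlleleTableFromBundle(bundle, pipelineConfig(sim = cfg))
al$table
#> AlleleTable: 60 loci, 63 accepted pairs
#>   loci by class: multi_allele 6, two_allele 51, one_allele 3

hv <- compareHaplotypes(haplotypeSeq(bundle, "A"), haplotypeSeq(bundle, "B"),
                        geneModels(bundle, "A"))
hv
#> HaplotypeComparison: 1851 alignment blocks
#>   2285 SNPs, 197 small indels, 18 SVs

m <- truthCompare(list(alleles = al, variants = hv), truthSet(bundle))
unlist(m[c("pair_recall", "pair_precision", "snp_recall", "snp_precision",
           "sv_recovered", "sv_planted")])
#>    pair_recall pair_precision     snp_recall  snp_precision   sv_recovered
#>      1.0000000      1.0000000      0.9929794      0.9903720     12.0000000
#>     sv_planted
#>     12.0000000
```

The bundle's 59/64 gene split reflects the planted allele classes: 3 loci
are hemizygous on each side (one-allele), and 6 multi-allele loci carry a
tandem paralog copy on B. Every planted pair was recovered; SNP recall and
precision are measured within anchored territory; all 12 planted SVs came
back with the right category (the 18 calls include the 6 paralog gene
duplications, which genuinely are tandem expansions of B). Per-pair rates
live on the pair table:

```r
head(allelePairs(al$table)[, c("geneA", "geneB", "similarity", "status",
                               "ka", "ks", "kaks")], 4)
#>       geneA       geneB similarity status          ka          ks      kaks
#> 1 HA.G00001   HB.G00001  0.9924242 allele 0.009078984 0.003324105 2.7312564
#> 2 HA.G00002   HB.G00002  0.9955257 allele 0.006024129 0.000000000        NA
#> 3 HA.G00003   HB.G00003  0.9951691 allele 0.004243293 0.006772055 0.6265886
#> 4 HA.G00003 HB.G00003P1  0.9838969 allele 0.019335120 0.006718970 2.8776911
```

`runPipeline(pipelineConfig(sim = cfg), out_dir)` runs all stages and
writes the full report bundle (FASTA/GFF3/VCF/TSV/JSON plus a run log);
two runs with the same configuration are byte-identical.

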