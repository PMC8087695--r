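Package: haplotab
Title: Allele Tables, Haplotype Variation and Allele-Specific Expression for
    Phased Diploid Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the two phased haplotypes of a diploid
    genome assembly. Builds an allele table from synteny blocks (cscore
    filtering and collinearity chaining) plus coordinate-overlap placement
    rescue on a monoploid reference, computes pairwise similarity and
    Nei-Gojobori Ka/Ks for allele pairs, calls SNPs, small indels and
    six-category structural variants between haplotypes from unique-anchor
    alignments, and tests allele-specific expression from per-allele tissue
    counts (TPM normalisation, exact binomial imbalance tests, sample
    correlation clustering). Ships a synthetic diploid genome generator with
    a full ground-truth set so the whole pipeline can be exercised and
    benchmarked without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
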