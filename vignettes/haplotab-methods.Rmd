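---
title: "Allele tables, haplotype variation and allele-specific expression:
  models and methods"
author: "haplotab package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haplotab methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(haplotab)
```

# Scope

`haplotab` analyses a haplotype-resolved diploid genome assembly: two phased
chromosome sets (A and B) plus a collapsed monoploid reference that serves as
a common coordinate frame. It answers four questions that arise as soon as
such an assembly exists for a highly heterozygous organism (the motivating
case is a self-incompatible woody crop with heterozygosity in the
2.8--3.4 % range):

1. **Which gene on B is the allele of which gene on A?** (the *allele
   table*, with paralogs and allele-class accounting)
2. **How do the haplotypes differ at the sequence level?** (SNPs, small
   indels, and six categories of structural variant)
3. **How fast are allele pairs diverging, and is any pair under positive
   selection?** (similarity, Nei--Gojobori Ka/Ks)
4. **Are the two alleles of a pair expressed unequally?** (TPM, exact
   binomial imbalance tests, tissue correlation structure)

Because real assemblies of this kind are multi-gigabase downloads, the
package ships a synthetic diploid generator with a complete ground-truth
record of every planted event. All recovery claims made by the test suite
and `scripts/acceptance.R` are claims about this generator's output, at
stated sizes — not about any particular real genome.

# The synthetic diploid generator

`simConfig()` + `simulateDiploid()` build a bundle deterministically from a
seed: byte-identical sequences, annotations, truth records and count tables
on every run.

**Monoploid layout.** Each chromosome is assembled left to right from
random background interleaved with three feature types, each separated by at
least 150 bp of background: gene footprints (exon--intron--exon; the CDS is
a string of 100--400 sense codons, so it is divisible by 3 and has no
internal stop by construction; strands are random and minus-strand bodies
are reverse-complemented into the genome), repeat blocks (tandem arrays of
a small motif library filling `repeat_fraction` of the chromosome), and
reserved structural-variant sites.

**Haplotype derivation.** Haplotype A *is* the monoploid; every planted
event is expressed in B with both A-side and B-side coordinates recorded.
This single-coordinate-anchor convention makes truth bookkeeping exact: the
length difference between B and A equals the signed sum of planted event
sizes, a property the test suite asserts to the base pair.

**Allele classes.** Loci are apportioned into `two_allele`,
`multi_allele`, `unpaired` and `identical` classes by largest-remainder
rounding of `allele_class_mix`. Two-allele and multi-allele loci are forced
to carry at least one stop-safe coding substitution (so that "alleles with
at least one base substitution" is a meaningful planted category);
identical loci are fenced off from every event type; unpaired loci keep
their sequence but lose their annotation on one (alternating) haplotype,
which models hemizygous annotation rather than sequence loss. Multi-allele
loci are realised as *tandem gene duplications*: the gene body is copied
20 bp downstream on B with ~2 % extra stop-safe coding divergence. The
copy is recorded in the allele truth (with its size, so length bookkeeping
stays exact) but deliberately **not** in `planted_svs`: it is a genuine
tandem expansion of B, and keeping it out of the SV truth keeps the
planted-SV recovery metric a clean 1:1 match against `sv_counts`.

**Structural variants.** The six categories are planted with the junction
signature that an Assemblytics-style classifier detects:

| category | monoploid site | edit in B | caller signature |
|---|---|---|---|
| insertion | (none) | novel random sequence | clean gap, query longer |
| deletion | unique segment | segment removed | clean gap, reference longer |
| tandem_expansion | unique segment `s` | second copy of `s` appended | blocks overlap on reference |
| tandem_contraction | `s s` | one copy removed | blocks overlap on query |
| repeat_expansion | motif array `m⁴` | two copies appended (`m⁶`) | blocks overlap on both |
| repeat_contraction | motif array `m⁴` | one copy removed (`m³`) | blocks overlap on both |

Sizes are drawn log-uniformly from `sv_size_range`. The default range is
[50, 10000] bp rather than the full [50, 100000] supported by the caller:
at the default desk scale (5 × 1.2 Mb) the larger cap would force total
divergence far beyond the heterozygosity band the generator is meant to
emulate; with the default range, SNPs (0.008/bp), small indels
(0.00077/bp, sizes 1 + geometric capped at 49) and ~60 SVs together land
near 2.8 % divergence. A note on "repeat expansion": a novel motif copy
placed at a *distant* locus looks like a plain insertion to any
junction-signature classifier; copy-number change inside an array is the
event that actually carries the repeat signature, so that is what the
generator plants.

**Expression.** Counts follow a negative-binomial model:
`log mean = expr_mean_log + t(locus, tissue) + a(locus)/2·(±1)`, with the
tissue effect `t ~ N(0, tissue_effect_sd)` *shared* by the two alleles of
a pair (this shared component is what makes same-tissue A/B samples
cluster together) and the allelic log-ratio `a ~ N(0, allele_effect_sd)`
split with opposite signs. Dispersion φ (`nb_dispersion`) enters as a
Gamma(1/φ, φ) multiplier on the Poisson rate that is *shared by the two
alleles of a pair within a tissue*: marginally each count is
NB(μ, μ + φμ²) as required, while conditional on the pair total the
A-count remains exactly binomial. This choice is deliberate: it models
locus-level noise (library, mappability) that affects both alleles alike,
and it is the regime in which an exact binomial imbalance test is
correctly calibrated. With independent NB draws per allele the binomial
null would be overdispersed and no exact test could hold its size. φ = 0
degenerates to Poisson.

# Allele identification

**Synteny arm.** All-versus-all CDS homology scoring is k-mer-prefiltered
(k = 12; pairs sharing fewer than `min_shared = 10` 12-mers are never
aligned — two unrelated random 300 bp CDS share none) and scored by
affine-gap global alignment (match +1, mismatch −1, gap open −2, extend
−0.5, Gotoh three-state DP in C++). The *cscore* of a hit is its score
divided by the best score involving either gene — exactly 1 for reciprocal
best hits — and the conventional 0.99 cutoff reduces the hit set to
near-1:1 pairs. Surviving anchors are chained per chromosome pair and
orientation by a longest-increasing-subsequence DP over gene ranks
(ordinal positions), with a rank-gap limit of 25 between consecutive
anchors and a minimum of 4 anchors per block; these two values are not
stated by any source and follow common collinearity-tool practice, exposed
as parameters. Equal-length chains are resolved leftmost on haplotype A
for determinism.

**Placement rescue.** Genes left out of every synteny block are placed on
the monoploid by exact 21-mer seeds (unique in the reference, both
orientations, chained by an LIS on reference position; identity = fraction
of the CDS covered by chained seeds). Two placements on the same reference
chromosome pair up when their overlap *exceeds* half the shorter placement
(strict). One detail matters: rescue pairs are formed whenever *at least
one* side was leftover, not only between two leftovers — otherwise a
tandem paralog (leftover, because the cscore filter kept only the best
partner) could never be attached to a locus whose primary pair came from
synteny, and the paralog-sorting step would be dead code.

**Similarity rule and classes.** Candidate pairs are aligned at the CDS
nucleotide level; similarity is identical columns over columns after
trimming terminal gap runs. Similarity exactly 1 ⇒ `same_allele`; strictly
above 0.7 ⇒ `allele`; at or below 0.7 ⇒ rejected (kept in the audit
table). Whether the original analysis measured similarity on nucleotides
or proteins is not stated anywhere; CDS nucleotide identity is the
simplest definition consistent with the rest of the pipeline and is used
throughout. Loci are assembled by union-find over accepted pairs; within a
locus the best accepted pair (ties: lexicographically smaller gene ids) is
primary and additional genes passing the threshold attach as paralogs.
Loci with >2 genes are `multi_allele`, exactly one gene per side
`two_allele`; a gene with no accepted partner but a reference placement
becomes a `one_allele` locus — the placement requirement distinguishes
hemizygosity from annotation absence. The summary reports both locus-level
and gene-level counts, plus the "genes with at least one base
substitution" total that excludes `same_allele` loci, because published
allele accounts of this kind mix gene- and locus-level numbers in ways
that cannot be reconciled from totals alone.

# Evolutionary rates

Ka/Ks uses Nei--Gojobori (1986) counting on a codon alignment obtained by
aligning the two protein sequences (unit scores: match +1, mismatch 0,
gaps −2/−0.5) and threading gaps back onto codons, so gaps come only in
multiples of 3; codon columns containing any gap are dropped (pairwise
deletion). Site fractions per codon count a mutation to a stop codon as
nonsynonymous, which keeps N + S = 3 × codon columns exactly; differences
are averaged over all minimal mutational pathways between differing
codons, excluding pathways through stops (with a fallback to all pathways
in the degenerate case where every ordering is blocked). Proportions are
Jukes--Cantor corrected, d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 flags the pair
saturated. One boundary case is resolved in favour of interpretability: a
pair with *no* nonsynonymous difference at all has ratio 0 even when its
synonymous proportion saturates the correction (at single-codon scale one
synonymous difference over a third of a site always saturates). Pairs with
Ka/Ks > 1 are flagged under positive selection; Ks = 0 yields
`ratio_undefined`, never a positive call. The method was chosen for exact
re-implementability — every count is checkable against a brute-force
pathway oracle over all 61 × 61 sense-codon pairs, which the test suite
does — not for comparability with any particular likelihood estimator, so
no claim is made that mean ratios are absolutely comparable across
estimators.

# Haplotype variation

**Anchors.** Exact matches seeded at k-mers (k = `min_anchor` = 20) that
occur exactly once in *both* sequences, merged along diagonals, extended
maximally, then chained by a weighted LIS (weight = anchor length) that
requires both start coordinates to increase but deliberately allows
consecutive blocks to overlap — the overlap *is* the tandem/repeat
signal. A guard refuses chromosomes above 10 Mb; larger inputs should
arrive as PAF from an external aligner.

**Junction routing.** For consecutive blocks, let g_ref and g_qry be the
signed gaps and size = |g_qry − g_ref|. Junctions with size < 50 bp are
alignment-resolved on their *trimmed* (non-negative) gap pair: mismatch
columns become SNPs, gap runs of 1--49 bp small indels. Junctions with
size ≥ 50 and clean non-negative gaps (each ≤ `max_gap_align` = 10 kb) are
also alignment-resolved, with long gap runs deferred as insertion/deletion
SVs; junctions with an overlap signature or gaps above the limit go to the
sign table: both gaps clean ⇒ insertion/deletion by sign of net change;
reference-side overlap ⇒ tandem expansion (an extra query copy makes the
reference segment align twice); query-side overlap ⇒ tandem contraction;
overlap on both sides ⇒ repeat expansion/contraction by sign. Maximal
extension overshoots into an event by a few bases with probability 4^−k
per base, so overlaps of at most `overlap_slop` = 20 bp are treated as
sign-zero — without this clamp, 1--3 bp jitter overlaps flip clean
insertions into "tandem" calls; event sizes are unaffected because the
jitter cancels in g_qry − g_ref. Size bins follow the conventional
50--500 / 500--10,000 / 10,000--50,000 / 50,000--100,000 layout,
lower-inclusive; the 50 bp floor is inclusive (49 bp is a small indel,
50 bp an SV).

**Verification by reconstruction.** Every call (point or SV) carries its
replacement interval, so `applyVariants()` can splice all calls into A and
the result is compared with B over the anchored-plus-aligned territory.
The test suite requires this round trip to be *exact* across a 5-seed
panel — a much stronger statement than per-event recovery, since any
missed, duplicated or mis-coordinated call breaks it.

**What recovery numbers mean.** SNP recall/precision are measured within
anchored+aligned territory; SNPs inside repeat arrays or near large events
are not anchored and are out of scope by construction, as they would be
for any unique-anchor aligner. The 1 Mb variant-recovery experiment runs
with `multi_allele = 0` in the class mix: a multi-allele locus is itself a
tandem duplication of B (an SV not in `planted_svs`) and locally destroys
anchor uniqueness; pair-level multi-allele recovery is measured by the
allele-table experiment instead.

# Allele-specific expression

TPM divides each count by its effective length (CDS length in the
simulated bundles) and rescales each sample to one million; column sums
are exact to floating-point and the transform is invariant to count
scaling. The "highly expressed" rule is strict: TPM > 10 in at least one
tissue.

The imbalance test is an exact two-sided binomial test of the A-count out
of the pair total against the length-corrected null
p₀ = len_A/(len_A + len_B), with outcome probabilities at most that of the
observation summed (the classical two-sided construction). This replaces a
replicate-based differential-expression test on purpose: with a single
library per tissue no dispersion can be estimated, whereas the exact
binomial test is correctly calibrated under the shared-noise count model
above — the test suite checks a rejection rate within [0.03, 0.07] at
α = 0.05 over 2000 null pairs, and non-decreasing power over planted
log-ratios {0, 0.5, 1, 2}. P-values are Benjamini--Hochberg adjusted
within tissue (pairs with zero total are excluded from the adjustment);
direction is called at FDR < α.

Sample structure is summarised by Pearson correlation of log₂(TPM+1)
across allele pairs, treating A-side and B-side expression per tissue as
separate samples, clustered by average linkage on 1 − r. Under the default
effect regime (tissue SD 1.0 ≫ allele SD 0.2) the five first merges join
each tissue's A and B samples — the qualitative tissue-major structure —
in at least 9 of 10 seeds. The pseudocount 1 and average linkage are fixed
choices; the correlation metric and linkage of the original analysis are
unstated, so these are explicit substitutions.

# Problem sizes and determinism

All experiment sizes are the package's own choices and are what the
recovery claims refer to: allele-table recovery runs at the default scale
(5 × 1.2 Mb, 1000 gene loci, seed 42); variant recovery on one 1 Mb
chromosome (SNP rate 0.008/bp, 10 % repeats, 60 SVs); the reconstruction
panel and the determinism check on 1 × 300 kb with 40--60 genes and 12
SVs; ASE calibration on 2000 pairs. Every stage is a pure function of its
configuration: `runPipeline()` writes a bundle whose files are
byte-identical across reruns with the same config (the run log contains no
timestamps for exactly this reason).

# Known limitations

* Chaining is single-orientation per block and the SV taxonomy contains no
  inversions or translocations; the generator plants none.
* The unique-anchor aligner is desk-scale (≤ 10 Mb/chromosome); gigabase
  genomes need external alignments via PAF.
* The generator's background is i.i.d. random sequence; real genomes have
  compositional structure (GC skew, gene families, nested repeats) that
  makes anchoring and homology search harder than the simulated regime, so
  recovery rates here are upper bounds on real-data behaviour.
* One isoform per gene; multi-isoform GFF3 is refused at import.
* The binomial ASE test conditions away library-size and locus-level
  effects only insofar as they are shared by both alleles; allele-specific
  mappability bias is not modelled.
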