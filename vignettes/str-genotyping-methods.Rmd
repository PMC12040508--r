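---
title: "Methods: haplotype-resolved STR genotyping and interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-resolved STR genotyping and interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataxia)
```

`strataxia` genotypes short tandem repeat (STR) loci from long reads that
span the repeat, decomposes each allele into motif runs, and interprets
the diploid genotype against locus-specific rules. This vignette is the
package's own account of the method: the model at each stage, the
parameters that matter and their defaults, what the synthetic data
emulate, the numerical choices, and the known limits.

## The measurement model

A locus is defined by its two unique 150-nt flank anchors and a motif
catalog (`str_locus`). Repeat size is measured per read as the
*intervening distance*: both anchors are aligned to the oriented read and
the copy estimate is `round((start_right − end_left) / k)`, with `k` the
canonical motif length and rounding half-away-from-zero so that single
insertions and deletions bias the estimate symmetrically.

Anchor alignment is a *fit* alignment — the anchor aligns end-to-end,
locally in the read, with unit match/mismatch/gap scores — rather than a
plain local alignment. The reason is boundary stability: a local
alignment trims a mismatched anchor edge, which silently shifts the
segment boundary and changes the measured distance; with fit alignment a
substitution anywhere in an anchor leaves the distance untouched.
Identity is alignment matches divided by anchor length (150), and a hit
requires identity ≥ `min_identity` (default 0.80, chosen so that anchors
tolerate ~10–15% read error while 150-nt sequences remain effectively
unique). The orientation of each read is decided by the left anchor
(searched on both strands); the right anchor is then located on the
oriented read. Reads without both anchors are counted but excluded from
size estimation. Coordinates are 0-based half-open throughout.

## Haplotype partitioning

Spanning reads are split into allele clusters by 1-D k-means (Lloyd,
k = 2) on copy estimates, initialized at the observed minimum and maximum
— a deterministic, permutation-invariant initialization. The split is
kept only when the cluster means differ by more than
`max(merge_abs, merge_frac × overall mean)`; otherwise the locus is
reported homozygous-appearing. Defaults are `merge_abs = 5` copies and
`merge_frac = 0.05`. The merge window has to absorb per-read size noise
on homozygous loci (a few copies at the error rates below) yet still
resolve genuinely distinct near-equal alleles; 5% of the mean separates,
for example, biallelic pentamer expansions of 651 and 693 copies (gap 42,
window 33.6) while still collapsing modes ~10 copies apart around a mean
of 200. A wider relative window (e.g. 10%) would merge such biallelic
expansions into a single spurious homozygous call. Phasing uses repeat
length only — flank-SNV phasing is not implemented — so *distinct alleles
of equal length collapse into one homozygous-appearing call*; this is the
main known limitation of the partitioner. A call requires
`min_support = 3` spanning reads, in the spirit of multi-read
verification of interruptions.

## Consensus and polishing

Each cluster's representative sequence is its *medoid* read segment: the
segment whose copy estimate is closest to the cluster median, with ties
broken by highest summed anchor identity, then lexicographically smallest
read id — fully deterministic. The reported allele size is the rounded
cluster median (the median over reads is far more precise than any single
read).

A single read, however, carries errors, and purity-rule classification is
exquisitely sensitive to them: at ~1% combined error essentially no read
over a 1-kb repeat is error-free, so the maximal uninterrupted run
measured on a raw medoid read collapses (a true 348-unit pure GAA tract
measures ~70–100). The consensus is therefore *polished* for purity-rule
loci: every other segment in the cluster is globally aligned to the
medoid backbone and each backbone column — and each insertion site
between columns — is replaced by the majority call across reads, with
ties keeping the backbone. One round at ≥15x support removes essentially
all residual errors (the probability that independent reads share an
error at one column is negligible), restoring exact run structure:
true single-unit interruptions recur in every read and survive the vote,
error-induced ones do not. Polishing is quadratic in segment length and
classification at motif-count loci does not need base-exact sequence, so
it is applied only where the purity rule is in force; this stands in for
the assembly-and-polish loop a production pipeline would run per
haplotype.

## Motif decomposition

The repeat segment is cut into consecutive `k`-nt units from a chosen
frame and each unit is labeled:

1. a catalog motif's reporting form when the unit equals any cyclic
   rotation of it — the canonical motif has priority, then the remaining
   catalog motifs in catalog order (deterministic when motifs overlap,
   e.g. GAA vs GGA);
2. `interrupt:<unit>` when the unit matches no catalog motif but lies
   within Hamming distance 1 of the canonical motif (AGG inside CGG,
   GCA/GGA inside GAA);
3. `other` otherwise.

Consecutive same-label units merge into runs; the run-length encoding is
the allele's sequence bar chart. The frame is the offset in `0..k-1`
maximizing the count of units exactly equal to a catalog motif *as
written* (ties to the smallest offset). Rotation matches cannot be used
here: every unit of a pure tract matches some rotation at every offset,
so only exact-form counting discriminates. Total units times `k`, plus
the frame offset and the final partial unit, always reconstructs the
sequence length exactly.

Loci whose catalog motifs differ in length (pentamer and hexamer motifs
at the same site) are decomposed once per candidate unit length; the
parse with the most exact catalog-motif units wins, and its dominant
catalog motif is the allele's motif call. Mixed alleles are sized by
*total units including interrupting units* — a GAA expansion with
embedded GCA units reports its full unit count, with the pure-run
statistic carrying the pathogenicity signal.

A deliberate conservatism: *any* non-canonical unit breaks a pure run,
including single-error units. On raw reads this underestimates purity —
which is exactly why classification operates on the polished consensus.

## Classification rules

Two interpretation regimes, selected per locus:

* **Purity rule** (e.g. *FGF14*/SCA27B): the measured quantity is the
  maximal uninterrupted canonical run. ≥ 250 is pathogenic; 200–249 is
  intermediate (uncertain significance); an allele whose total units
  exceed the normal range but whose pure run falls short because of
  interruptions or noncanonical motifs is reported
  `non_pathogenic_noncanonical`; otherwise normal. The three bands tile:
  normal ≤ 199, intermediate 200–249, pathogenic ≥ 250. The intermediate
  band is applied to the pure run only, not to total length of
  interrupted alleles.
* **Motif catalog** (e.g. *RFC1*/CANVAS): the measured quantity is total
  copies of the called motif. Pathogenic motifs (AAGGG, ACAGG) at or
  above the locus threshold are pathogenic; benign catalog motifs
  (AAAAG, AAGAG, AAAGGG, AAAGG) are `benign_motif`; motifs outside the
  catalog are `unknown_motif`. AAAGG is a special case: benignity is
  established only for smaller tracts, so above `aaagg_benign_max`
  (default 1000 copies) it is reported `unknown_motif` with a warning.

The locus-level call applies inheritance: at monoallelic (dominant) loci
one pathogenic allele is `positive` (an intermediate best call gives
`intermediate_uncertain`); at biallelic (recessive) loci two pathogenic
alleles are required for `positive` and exactly one gives `carrier`.
Homozygous-appearing calls count as two alleles of the same class.

## The packaged catalog

`default_catalog()` ships 21 spastic-ataxia STR loci: the polyglutamine
SCAs (ATXN1/2/3/7, CACNA1A, TBP, ATN1, PPP2R2B), FXN, FMR1, ATXN8OS,
FGF14, RFC1, THAP11, ZFHX3, and six further literature-standard ataxia
repeat loci (ATXN10, NOP56, BEAN1, DAB1, GLS, JPH3) chosen by the package
authors to round out the panel. Only the *FGF14* bands above are
treated as canonical to this package's validation; all other thresholds
are literature defaults and are marked as such in the catalog file
header. FMR1 uses the premutation range (pathogenic_min 55) because the
ataxia-relevant phenotype (FXTAS) is a premutation disease. The 150-nt
flank anchors in the packaged file are **synthetic** fixed-seed sequences
(the filename says so): they make the catalog self-contained for
simulation and testing, but genotyping real reads requires a catalog with
genomic flanks.

## Synthetic data: what it does and does not emulate

`simulate_reads()` builds each haplotype as shared random flanking
context (default 5 kb per side) + left anchor + allele sequence + right
anchor + context, then draws reads as uniform-start windows of
`min(read_length_mean, locus length)` — the default 30-kb window reflects
high-molecular-weight DNA sheared to ~30-kb fragments, the targeted-assay
regime in which most reads span the repeat. Errors are iid per base,
mutually exclusive: substitution to a uniformly random different base,
single-base insertion, single-base deletion. Strands are flipped with
probability 1/2. Output is Phred+33 FASTQ at constant Q20 plus a
ground-truth record; with a fixed seed the output is byte-identical
across runs, and reads per allele equal `round(coverage_per_allele)`
when the window covers the locus.

The error model deliberately omits real nanopore characteristics —
homopolymer-length errors, sequence-context bias, quality variation,
chimeras — and the simulator does not model off-target reads or
coverage imbalance between haplotypes beyond Poisson-free equal
sampling. Passing tests on these simulations therefore demonstrate the
pipeline's logic (sizing, partitioning, decomposition, classification)
under idealized noise, not performance on real ONT data; in particular,
systematic homopolymer bias could shift size estimates at A/T-rich
motifs in ways the iid model cannot reveal.

Validation problem sizes were chosen as assay-realistic defaults:
40x per allele, substitution/insertion/deletion rates of
0.4%/0.3%/0.3%, and the packaged fixtures — a (GAA)348/(GAA)9
heterozygote, the 616-unit GAA/GCA mixture against (GAA)9, biallelic
(AAGGG)651/693, and compound-heterozygous (AAGGG)1000/(ACAGG)2000. The
interruption positions inside the MIX616 and FMR1_85 fixtures are fixed
package choices (only their totals, maximal pure run, and interruption
counts are externally meaningful).

## Numerical and degenerate-input choices

* Copy rounding: half-away-from-zero (`round_half_away()`), symmetric
  under insertion/deletion noise.
* k-means: Lloyd with min/max initialization; at most 100 iterations;
  a degenerate all-equal input skips clustering entirely.
* Medoid tie-breaks: distance to median, then summed anchor identity,
  then read id — no randomness anywhere in genotyping.
* Empty repeat segments decompose to zero units and classify as normal
  (a deleted or contracted allele is not an expansion).
* Sequences shorter than every catalog motif report zero units with the
  whole length as leftover.
* Zero spanning reads yield a structured no-call report (exit status 0
  at the command line), not an error.
* All simulation randomness flows from a single integer seed through an
  RNG scope that restores the caller's RNG state.

## Variant prioritization

Annotated small variants (VCF via `vcfR`, configurable INFO keys) are
retained when they match any of: (i) ClinVar pathogenic / likely
pathogenic / uncertain; (ii) predicted frameshift; (iii) missense with
REVEL > 0.5 (strict) and ClinVar in the same set or unassigned;
(iv) HIGH/MODERATE impact with the same ClinVar condition — and pass
both gates: MANE Select transcript, and allele frequency absent or
< 0.1 (strict). Criteria membership is evaluated before the gates so an
excluded variant still reports which criteria it would have matched;
most REVEL-qualifying missense variants also match (iv), and both
memberships are reported. ClinVar strings are normalized
case-insensitively, with conflicting-interpretation records mapped to
uncertain. Two retained variants phased into the same phase set are
reported *in trans* when their haplotype assignments differ and *in cis*
when they agree; different phase sets or unphased genotypes give
`unknown` — the package never guesses phase across phase-set boundaries.

## Known limitations

* Equal-length distinct alleles merge (length-only phasing).
* The consensus is a polished single read, not an assembly; at very low
  support (3–5 reads) occasional residual errors survive the majority
  vote, so purity values within a few units of a threshold deserve
  manual review.
* Motif-count loci use the unpolished medoid; their interruption
  annotations (as opposed to copy counts and motif calls) can include
  error-induced single-unit runs.
* The catalog's non-FGF14 thresholds are literature defaults, not
  validated by this package's tests.
* Structural-variant prioritization, methylation, and genome-wide
  analysis are out of scope.
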