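# strataxia

Haplotype-resolved short tandem repeat (STR) genotyping and interpretation
from targeted long reads, for the spastic-ataxia spectrum disorders.

Late-onset ataxias are frequently caused by STR expansions — a deep
intronic GAA expansion in *FGF14* causes SCA27B when an allele carries an
uninterrupted (GAA)≥250 tract, and biallelic pentamer expansions in *RFC1*
(AAGGG, ACAGG) cause CANVAS, while several other *RFC1* motifs (AAAAG,
AAGAG, AAAGGG) are benign regardless of size. Calling these loci therefore
requires more than a length: the repeat must be sized per haplotype, its
sequence decomposed into motif runs, interruptions separated from
sequencing errors, and the result interpreted against locus-specific rules
(purity thresholds, motif catalogs, monoallelic vs biallelic inheritance).
`strataxia` implements that workflow for reads that span the repeat, plus
the rule-based triage of annotated small variants (ClinVar / REVEL /
impact / MANE / allele-frequency gates, with trans/cis phase
determination for compound heterozygotes) used alongside STR genotyping in
a single targeted long-read assay.

## How it works

For a locus with unique 150-nt flank anchors `L` and `R`, each read is
oriented and the repeat segment between the anchors extracted; the
per-read copy estimate is

    copies = round( (start(R) - end(L)) / k )

where `k` is the motif length and rounding is half-away-from-zero.
Spanning reads are partitioned into (up to) two allele clusters by
1-D k-means on copy estimates, with near-equal clusters merged into a
homozygous-appearing call. Each cluster's medoid read (optionally
majority-polished against the cluster) is decomposed into motif runs —
catalog motifs matched rotation-invariantly, units within Hamming
distance 1 of the canonical motif labeled as interruptions — yielding the
total unit count, the maximal uninterrupted canonical run, and a
plot-ready run-length encoding (sequence bar chart). Alleles are then
classified per locus rule: purity-rule loci (*FGF14*) on the maximal pure
canonical run (normal ≤ 199, intermediate 200–249, pathogenic ≥ 250);
motif-catalog loci (*RFC1*) on total copies of the called motif; and the
diploid genotype is resolved through the locus inheritance model
(one pathogenic allele suffices at dominant loci, two are required at
recessive loci).

A read simulator generates diploid samples with arbitrary motif-run
layouts, ~30-kb fragment windows, and an iid substitution/indel error
model, providing ground truth for every stage. A 21-locus ataxia catalog
ships with the package (synthetic flank anchors; supply genomic flanks
for real data).

## Worked example

Simulate a heterozygous *FGF14* carrier — (GAA)348 against the common
(GAA)9 short allele — at 20x per allele with ~1% read error, and genotype
it:

```r
library(strataxia)
catalog <- default_catalog()
fgf14   <- catalog[["FGF14"]]
pair    <- str_fixture("FGF14_HET")
cfg     <- sim_config(coverage_per_allele = 20, substitution_rate = 0.004,
                      insertion_rate = 0.003, deletion_rate = 0.003, seed = 1)
sim  <- simulate_reads(fgf14, pair$allele1, pair$allele2, cfg)
genotype_locus(sim$reads, fgf14)
#> <str_genotype_call> FGF14: positive (heterozygous; 40/40 reads spanning)
#>   allele 1: GAA x 9 (median; MAD 0, n=20) max pure 9, normal
#>   allele 2: GAA x 347.5 (median; MAD 0.5, n=20) max pure 348, pathogenic
```

All 40 reads span both anchors; the two length clusters sit at 9 and
~348 copies, and after majority polishing the expanded allele's maximal
uninterrupted GAA run is the full 348 units — above the 250-copy
threshold, so the locus call is positive (dominant inheritance).

Interrupted expansions are sized but not called pathogenic. The packaged
`MIX616` allele is a 616-unit GAA expansion broken by four single GCA
units:

```r
mix <- decompose_repeat(build_allele_sequence(str_fixture("MIX616")), fgf14)
mix
#> <str_decomposition> 616 units (k=3, frame 0, leftover 0 nt)
#>   motif call GAA; max pure canonical run 195; 4 interruption run(s)
#>    (GAA)195 (interrupt:GCA)1 (GAA)100 (interrupt:GCA)1 (GAA)100
#>    (interrupt:GCA)1 (GAA)100 (interrupt:GCA)1 (GAA)117
classify_allele(fgf14, mix)$category
#> [1] "non_pathogenic_noncanonical"
```

Despite its 616-unit total length, the longest pure GAA run is 195 — below
250 — so the allele is non-pathogenic.

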