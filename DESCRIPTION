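Package: strataxia
Title: Targeted Long-Read Genotyping of Spastic-Ataxia Repeat Expansions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for haplotype-resolved short tandem repeat (STR)
    genotyping from targeted long reads at spastic-ataxia loci. Simulates
    error-bearing long reads over diploid repeat alleles, estimates repeat
    size per read from the intervening distance between unique 150-bp flank
    anchors, partitions reads into allele clusters by repeat length,
    decomposes repeat sequences into motif runs (pure runs, interruptions,
    noncanonical motifs), classifies alleles and loci against an ataxia STR
    catalog (e.g. FGF14 GAA purity thresholds, RFC1 pathogenic vs benign
    pentamer motifs), and triages annotated small variants with
    rule-based prioritization including trans/cis phase determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
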