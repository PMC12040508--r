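# Shared fixtures for the suite. The default catalog is loaded once; the
# noisy simulation settings mirror the study regime the simulator targets
# (40x per allele, ~1% combined error).
the_catalog <- default_catalog()
fgf14 <- the_catalog[["FGF14"]]
rfc1 <- the_catalog[["RFC1"]]
fmr1 <- the_catalog[["FMR1"]]

noisy_cfg <- function(seed, coverage = 40, flank_nt = 5000) {
  sim_config(coverage_per_allele = coverage,
             substitution_rate = 0.004, insertion_rate = 0.003,
             deletion_rate = 0.003, seed = seed, flank_nt = flank_nt)
}

# Decompose a pure canonical tract of n copies and classify it.
classify_pure <- function(locus, n) {
  classify_allele(locus, decompose_repeat(strrep(locus$canonical_motif, n), locus))
}

# A small heterozygous FGF14 simulation reused by several files: short
# flanks keep alignment fast without changing any logic under test.
quick_het_sim <- function(seed = 11, coverage = 8, ...) {
  pair <- str_fixture("FGF14_HET")
  simulate_reads(fgf14, pair$allele1, pair$allele2,
                 sim_config(coverage_per_allele = coverage, seed = seed,
                            flank_nt = 400, ...))
}
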