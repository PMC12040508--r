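test_that("qualifies applies the four criteria and the MANE/AF gates", {
  v <- annotated_variant(consequence = "missense_variant", impact = "MODERATE",
                         revel = 0.6)
  d <- qualifies(v)
  expect_true(d$retained)
  expect_setequal(d$matched_criteria, c("iii", "iv"))

  fs <- annotated_variant(consequence = "frameshift_variant", impact = "HIGH",
                          allele_frequency = 0.0001)
  expect_true("ii" %in% qualifies(fs)$matched_criteria)
  expect_true(qualifies(fs)$retained)

  common <- annotated_variant(consequence = "missense_variant", revel = 0.9,
                              allele_frequency = 0.2)
  dc <- qualifies(common)
  expect_false(dc$retained)
  expect_identical(dc$exclusion_reason, "allele_frequency")
  expect_true(length(dc$matched_criteria) > 0)  # criteria reported despite gate

  syn <- annotated_variant(consequence = "synonymous_variant", impact = "LOW",
                           clinvar_significance = "benign")
  ds <- qualifies(syn)
  expect_false(ds$retained)
  expect_identical(ds$exclusion_reason, "no_criterion_matched")

  # REVEL exactly 0.5 fails the strict criterion-iii inequality
  boundary <- annotated_variant(consequence = "missense_variant",
                                impact = "MODERATE", revel = 0.5)
  db <- qualifies(boundary)
  expect_true(db$retained)
  expect_identical(db$matched_criteria, "iv")

  off_mane <- annotated_variant(consequence = "missense_variant", revel = 0.9,
                                mane_select = FALSE)
  expect_identical(qualifies(off_mane)$exclusion_reason, "not_mane_select")

  # benign ClinVar blocks criteria iii and iv
  benign_missense <- annotated_variant(consequence = "missense_variant",
                                       impact = "MODERATE", revel = 0.9,
                                       clinvar_significance = "likely_benign")
  expect_false(qualifies(benign_missense)$retained)
})

test_that("ClinVar strings normalize case-insensitively with conflicts as uncertain", {
  norm <- strataxia:::normalize_clinvar
  expect_identical(norm("Pathogenic"), "pathogenic")
  expect_identical(norm("Likely_pathogenic"), "likely_pathogenic")
  expect_identical(norm("Uncertain significance"), "uncertain")
  expect_identical(norm("Conflicting_interpretations_of_pathogenicity"), "uncertain")
  expect_identical(norm("Benign/Likely_benign"), "likely_benign")
  expect_identical(norm(NA), "none")
  expect_identical(norm("."), "none")
})

test_that("lowering allele frequency never flips a retained variant to excluded", {
  for (af in c(NA, 0.099, 0.05, 0.001, 0)) {
    v <- annotated_variant(consequence = "frameshift_variant", impact = "HIGH",
                           allele_frequency = af)
    expect_true(qualifies(v)$retained, info = paste("AF", af))
  }
  for (af in c(0.1, 0.15, 0.9)) {
    v <- annotated_variant(consequence = "frameshift_variant", impact = "HIGH",
                           allele_frequency = af)
    expect_false(qualifies(v)$retained, info = paste("AF", af))
  }
})

test_that("filter_variants is order-preserving, total, and idempotent", {
  records <- rbind(
    annotated_variant(pos = 1, consequence = "missense_variant", revel = 0.8),
    annotated_variant(pos = 2, consequence = "synonymous_variant", impact = "LOW"),
    annotated_variant(pos = 3, consequence = "frameshift_variant", impact = "HIGH"),
    annotated_variant(pos = 4, consequence = "missense_variant", revel = 0.2,
                      impact = "LOW"))
  res <- filter_variants(records)
  expect_identical(nrow(res$decisions), 4L)
  expect_identical(res$retained$pos, c(1L, 3L))
  empty <- filter_variants(records[0, ])
  expect_identical(nrow(empty$decisions), 0L)
  again <- filter_variants(res$retained)
  expect_identical(again$retained$pos, res$retained$pos)  # idempotence
})

test_that("phase relations distinguish trans, cis, and unknown", {
  h1 <- annotated_variant(pos = 100, clinvar_significance = "pathogenic",
                          genotype_phase = "haplotype1", phase_set = "100")
  h2 <- annotated_variant(pos = 200, consequence = "frameshift_variant",
                          impact = "HIGH", clinvar_significance = "pathogenic",
                          genotype_phase = "haplotype2", phase_set = "100")
  expect_identical(phase_relation(h1, h2), "trans")
  expect_identical(phase_relation(h2, h1), "trans")  # symmetric
  h1b <- annotated_variant(pos = 300, genotype_phase = "haplotype1",
                           phase_set = "100")
  expect_identical(phase_relation(h1, h1b), "cis")
  other_set <- annotated_variant(pos = 400, genotype_phase = "haplotype2",
                                 phase_set = "999")
  expect_identical(phase_relation(h1, other_set), "unknown")
  unphased <- annotated_variant(pos = 500)
  expect_identical(phase_relation(h1, unphased), "unknown")
})

test_that("annotated VCFs parse into prioritizable records", {
  vcf <- system.file("extdata", "example_annotated.synthetic.vcf",
                     package = "strataxia")
  variants <- read_annotated_vcf(vcf)
  expect_identical(nrow(variants), 12L)
  expect_identical(variants$clinvar_significance[1], "pathogenic")
  expect_true(variants$is_frameshift[2])
  expect_identical(variants$genotype_phase[1:2], c("haplotype1", "haplotype2"))
  expect_identical(variants$phase_set[1:2], c("100", "100"))
  expect_false(variants$mane_select[9])
  expect_true(is.na(variants$allele_frequency[3]))
  expect_identical(variants$clinvar_significance[11], "uncertain")

  res <- cmd_prioritize(vcf)
  expect_identical(nrow(res$decisions), 12L)
  # the two phased pathogenic records are reported in trans
  trans <- res$phase_pairs[res$phase_pairs$relation == "trans", ]
  expect_identical(nrow(trans), 1L)
  expect_setequal(c(trans$pos1, trans$pos2), c(89620045L, 89598310L))
  # record 7 (REVEL 0.5, LOW impact) is excluded; record 6 retained via iv
  expect_false(res$decisions$retained[7])
  expect_true(res$decisions$retained[6])
  expect_false(res$decisions$retained[4])  # AF 0.2 gate
  expect_false(res$decisions$retained[9])  # off MANE Select
})
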