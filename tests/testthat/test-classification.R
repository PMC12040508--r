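test_that("FGF14 allele classification follows the purity rule", {
  expect_identical(classify_pure(fgf14, 274)$category, "pathogenic")
  expect_identical(classify_pure(fgf14, 240)$category, "intermediate")
  expect_identical(classify_pure(fgf14, 9)$category, "normal")
  mix <- classify_allele(fgf14,
    decompose_repeat(build_allele_sequence(str_fixture("MIX616")), fgf14))
  expect_identical(mix$category, "non_pathogenic_noncanonical")
  expect_identical(mix$basis, "max_pure_canonical_run")
  expect_identical(mix$basis_value, 195L)
})

test_that("the FGF14 pure-GAA sweep tiles into normal / intermediate / pathogenic", {
  cats <- vapply(1:400, function(n) classify_pure(fgf14, n)$category, character(1))
  expect_identical(min(which(cats == "pathogenic")), 250L)
  expect_identical(range(which(cats == "intermediate")), c(200L, 249L))
  expect_identical(max(which(cats == "normal")), 199L)
  # monotone severity: normal < intermediate < pathogenic along the sweep
  severity <- c(normal = 1, intermediate = 2, pathogenic = 3)
  expect_true(all(diff(severity[cats]) >= 0))
})

test_that("RFC1 allele classification follows the motif catalog", {
  d_benign <- decompose_repeat(strrep("AAAAG", 800), rfc1)
  expect_identical(classify_allele(rfc1, d_benign)$category, "benign_motif")
  d_path <- decompose_repeat(strrep("AAGGG", 651), rfc1)
  expect_identical(classify_allele(rfc1, d_path)$category, "pathogenic")
  d_acagg <- decompose_repeat(strrep("ACAGG", 2000), rfc1)
  cls <- classify_allele(rfc1, d_acagg)
  expect_identical(cls$category, "pathogenic")
  expect_identical(cls$motif_call, "ACAGG")
  d_small <- decompose_repeat(strrep("AAGGG", 20), rfc1)
  expect_identical(classify_allele(rfc1, d_small)$category, "normal")
  d_foreign <- decompose_repeat(strrep("CCCCT", 300), rfc1)
  expect_identical(classify_allele(rfc1, d_foreign)$category, "unknown_motif")
  # large AAAGG tracts fall outside the established-benign size range
  d_big_aaagg <- decompose_repeat(strrep("AAAGG", 1500), rfc1)
  expect_warning(big <- classify_allele(rfc1, d_big_aaagg), "AAAGG")
  expect_identical(big$category, "unknown_motif")
})

test_that("locus-level calls honor inheritance and are symmetric in allele order", {
  cls <- function(locus, s) classify_allele(locus, decompose_repeat(s, locus))
  p8 <- list(cls(rfc1, strrep("AAGGG", 651)), cls(rfc1, strrep("AAGGG", 693)))
  expect_identical(classify_locus(rfc1, p8, "heterozygous")$diagnostic_status,
                   "positive")
  p9 <- list(cls(rfc1, strrep("AAGGG", 1000)), cls(rfc1, strrep("ACAGG", 2000)))
  expect_identical(classify_locus(rfc1, p9, "heterozygous")$diagnostic_status,
                   "positive")
  carrier <- list(cls(rfc1, strrep("AAGGG", 800)), cls(rfc1, strrep("AAAAG", 600)))
  expect_identical(classify_locus(rfc1, carrier, "heterozygous")$diagnostic_status,
                   "carrier")
  expect_identical(classify_locus(rfc1, rev(carrier), "heterozygous")$diagnostic_status,
                   "carrier")

  fgf_het <- list(classify_pure(fgf14, 348), classify_pure(fgf14, 9))
  expect_identical(classify_locus(fgf14, fgf_het, "heterozygous")$diagnostic_status,
                   "positive")
  expect_identical(classify_locus(fgf14, rev(fgf_het), "heterozygous")$diagnostic_status,
                   "positive")
  biallelic_interm <- list(classify_pure(fgf14, 213), classify_pure(fgf14, 201))
  expect_identical(classify_locus(fgf14, biallelic_interm,
                                  "heterozygous")$diagnostic_status,
                   "intermediate_uncertain")

  # homozygous-appearing counts as two alleles of the same classification
  expect_identical(classify_locus(rfc1, list(cls(rfc1, strrep("AAGGG", 700))),
                                  "homozygous_appearing")$diagnostic_status,
                   "positive")
  expect_identical(classify_locus(rfc1, list(cls(rfc1, strrep("AAGGG", 700))),
                                  "single_allele")$diagnostic_status,
                   "carrier")
  expect_identical(classify_locus(fgf14, list(), NA)$diagnostic_status, "no_call")
})

test_that("a locus without thresholds warns and leaves the allele unclassified", {
  bare <- str_locus("X1", "X1", "test", "CAG", normal_max = 10,
                    pathogenic_min = NA,
                    left_flank = fgf14$left_flank,
                    right_flank = fgf14$right_flank)
  d <- decompose_repeat(strrep("CAG", 40), bare)
  expect_warning(cls <- classify_allele(bare, d), "no thresholds")
  expect_identical(cls$category, "unknown_motif")
})
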