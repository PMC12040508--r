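#!/usr/bin/env Rscript
# Regenerates inst/extdata/ataxia_str_catalog.synthetic_flanks.tsv.
# Flank anchors are synthetic: fixed-seed random 150-mers standing in for
# the unique genomic flanks of each locus. Thresholds other than FGF14's
# are literature defaults (see the methods vignette).
# Run from the repository root: Rscript scripts/build_default_catalog.R

suppressMessages(devtools::load_all(".", quiet = TRUE))

set.seed(20240421)
flank <- function() paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                          collapse = "")

mk <- function(locus_id, gene, disease, motif, path_motifs = motif,
               benign = character(0), normal_max, interm = NULL,
               path_min = NA, inh = "monoallelic", purity = FALSE, ref = 10L) {
  str_locus(locus_id, gene, disease, motif,
            pathogenic_motifs = path_motifs, benign_motifs = benign,
            normal_max = normal_max, intermediate = interm,
            pathogenic_min = path_min, inheritance = inh,
            purity_rule = purity, reference_copies = ref,
            left_flank = flank(), right_flank = flank())
}

catalog <- list(
  mk("ATXN1",   "ATXN1",   "SCA1",    "CAG", normal_max = 35, interm = c(36, 38), path_min = 39, ref = 29),
  mk("ATXN2",   "ATXN2",   "SCA2",    "CAG", normal_max = 31, interm = c(32, 32), path_min = 33, ref = 22),
  mk("ATXN3",   "ATXN3",   "SCA3",    "CAG", normal_max = 44, interm = c(45, 59), path_min = 60, ref = 14),
  mk("CACNA1A", "CACNA1A", "SCA6",    "CAG", normal_max = 18, interm = c(19, 19), path_min = 20, ref = 11),
  mk("ATXN7",   "ATXN7",   "SCA7",    "CAG", normal_max = 33, interm = c(34, 36), path_min = 37, ref = 10),
  mk("ATXN8OS", "ATXN8OS", "SCA8",    "CTG", normal_max = 50, interm = c(51, 79), path_min = 80, ref = 15),
  mk("ATXN10",  "ATXN10",  "SCA10",   "ATTCT", normal_max = 32, path_min = 800, ref = 14),
  mk("PPP2R2B", "PPP2R2B", "SCA12",   "CAG", normal_max = 32, interm = c(33, 50), path_min = 51, ref = 10),
  mk("TBP",     "TBP",     "SCA17",   "CAG", normal_max = 40, interm = c(41, 48), path_min = 49, ref = 38),
  mk("BEAN1",   "BEAN1",   "SCA31",   "TGGAA", normal_max = 10, path_min = 110, ref = 0),
  mk("NOP56",   "NOP56",   "SCA36",   "GGCCTG", normal_max = 14, path_min = 650, ref = 8),
  mk("DAB1",    "DAB1",    "SCA37",   "ATTTC", normal_max = 16, path_min = 31, ref = 0),
  mk("THAP11",  "THAP11",  "SCA51",   "CAG", normal_max = 32, interm = c(33, 44), path_min = 45, ref = 29),
  mk("ZFHX3",   "ZFHX3",   "SCA4",    "GGC", normal_max = 30, path_min = 46, ref = 21),
  mk("FGF14",   "FGF14",   "SCA27B",  "GAA", normal_max = 199, interm = c(200, 249), path_min = 250,
     purity = TRUE, ref = 9),
  mk("RFC1",    "RFC1",    "CANVAS",  "AAGGG",
     path_motifs = c("AAGGG", "ACAGG"),
     benign = c("AAAAG", "AAGAG", "AAAGGG", "AAAGG"),
     normal_max = 399, path_min = 400, inh = "biallelic", ref = 11),
  mk("FXN",     "FXN",     "FRDA",    "GAA", normal_max = 33, interm = c(34, 65), path_min = 66,
     inh = "biallelic", ref = 9),
  mk("ATN1",    "ATN1",    "DRPLA",   "CAG", normal_max = 35, interm = c(36, 47), path_min = 48, ref = 17),
  mk("FMR1",    "FMR1",    "FXTAS",   "CGG", normal_max = 44, interm = c(45, 54), path_min = 55, ref = 30),
  mk("GLS",     "GLS",     "GDPAG",   "GCA", normal_max = 29, path_min = 680, ref = 14),
  mk("JPH3",    "JPH3",    "HDL2",    "CTG", normal_max = 28, interm = c(29, 39), path_min = 40, ref = 14)
)
names(catalog) <- vapply(catalog, `[[`, character(1), "locus_id")

out <- "inst/extdata/ataxia_str_catalog.synthetic_flanks.tsv"
tmp <- tempfile(fileext = ".tsv")
write_catalog(catalog, tmp)
header <- c(
  "# Ataxia STR locus catalog (21 loci).",
  "# Flank anchors are SYNTHETIC fixed-seed 150-mers, not genomic sequence.",
  "# Thresholds other than FGF14's bands are literature defaults; FMR1 uses",
  "# the premutation (FXTAS) range. See the methods vignette."
)
writeLines(c(header, readLines(tmp)), out)
cat("wrote", out, "with", length(catalog), "loci\n")
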