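#' Construct an annotated small-variant record
#'
#' One row per variant with the annotations the prioritization rules need:
#' ClinVar significance, consequence/impact, REVEL, population allele
#' frequency, MANE Select membership, and phased genotype information.
#'
#' @param chrom,pos,ref,alt VCF-convention coordinates (1-based) and alleles.
#' @param consequence consequence string (e.g. `"missense_variant"`).
#' @param impact one of HIGH, MODERATE, LOW, MODIFIER.
#' @param is_missense,is_frameshift flags; default derived from
#'   `consequence`.
#' @param clinvar_significance one of pathogenic, likely_pathogenic,
#'   uncertain, benign, likely_benign, none (free-form ClinVar strings are
#'   normalized; conflicting interpretations map to uncertain).
#' @param revel REVEL score in `[0,1]` or `NA`.
#' @param allele_frequency population AF in `[0,1]` or `NA` (absent).
#' @param mane_select variant annotated on the MANE Select transcript.
#' @param genotype_phase haplotype1, haplotype2, or unphased.
#' @param phase_set phase-set identifier or `NA`.
#' @return one-row data.frame.
#' @export
annotated_variant <- function(chrom = "chr1", pos = 1L, ref = "A", alt = "T",
                              consequence = "missense_variant",
                              impact = c("MODERATE", "HIGH", "LOW", "MODIFIER"),
                              is_missense = grepl("missense", consequence),
                              is_frameshift = grepl("frameshift", consequence),
                              clinvar_significance = "none",
                              revel = NA_real_,
                              allele_frequency = NA_real_,
                              mane_select = TRUE,
                              genotype_phase = c("unphased", "haplotype1", "haplotype2"),
                              phase_set = NA_character_) {
  stopifnot(pos >= 1, !grepl("[^ACGT]", ref), !grepl("[^ACGT]", alt),
            nchar(ref) > 0, nchar(alt) > 0)
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             consequence = consequence, impact = match.arg(impact),
             is_missense = is_missense, is_frameshift = is_frameshift,
             clinvar_significance = normalize_clinvar(clinvar_significance),
             revel = as.numeric(revel),
             allele_frequency = as.numeric(allele_frequency),
             mane_select = mane_select,
             genotype_phase = match.arg(genotype_phase),
             phase_set = as.character(phase_set),
             stringsAsFactors = FALSE)
}

# Normalize free-form ClinVar significance strings (case-insensitive;
# conflicting-interpretation records count as uncertain).
normalize_clinvar <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || s == "" || s == ".") return("none")
    s <- tolower(gsub("[ /|,]+", "_", trimws(s)))
    if (grepl("conflicting", s)) return("uncertain")
    if (grepl("likely_pathogenic", s)) return("likely_pathogenic")
    if (grepl("pathogenic", s)) return("pathogenic")
    if (grepl("uncertain", s)) return("uncertain")
    if (grepl("likely_benign", s)) return("likely_benign")
    if (grepl("benign", s)) return("benign")
    if (s %in% c("none", "not_provided", "na")) return("none")
    "none"
  }, character(1), USE.NAMES = FALSE)
}

CLNSIG_CONSIDERED <- c("pathogenic", "likely_pathogenic", "uncertain")
CLNSIG_OR_NONE <- c(CLNSIG_CONSIDERED, "none")

#' Does a variant qualify for prioritization?
#'
#' A variant is matched against four criteria:
#' (i) ClinVar significance pathogenic / likely pathogenic / uncertain;
#' (ii) predicted frameshift;
#' (iii) missense with REVEL strictly greater than 0.5 and ClinVar
#'       pathogenic / likely pathogenic / uncertain / unassigned;
#' (iv) HIGH or MODERATE impact with the same ClinVar condition.
#' A variant matching any criterion is retained only if it passes the
#' gates: on the MANE Select transcript, and allele frequency absent or
#' strictly below 0.1. Criteria membership is reported even when a gate
#' excludes the variant.
#'
#' @param v one variant (one-row data.frame or list with the fields of
#'   [annotated_variant()]).
#' @return list of class `prioritization_decision`: `retained`,
#'   `matched_criteria` (subset of `c("i","ii","iii","iv")`),
#'   `exclusion_reason` (`NA` when retained).
#' @export
qualifies <- function(v) {
  clnsig <- normalize_clinvar(v$clinvar_significance)
  matched <- character(0)
  if (clnsig %in% CLNSIG_CONSIDERED) matched <- c(matched, "i")
  if (isTRUE(v$is_frameshift)) matched <- c(matched, "ii")
  if (isTRUE(v$is_missense) && !is.na(v$revel) && v$revel > 0.5 &&
      clnsig %in% CLNSIG_OR_NONE) matched <- c(matched, "iii")
  if (v$impact %in% c("HIGH", "MODERATE") && clnsig %in% CLNSIG_OR_NONE) {
    matched <- c(matched, "iv")
  }
  if (length(matched) == 0L) {
    return(decision(FALSE, matched, "no_criterion_matched"))
  }
  if (!isTRUE(v$mane_select)) {
    return(decision(FALSE, matched, "not_mane_select"))
  }
  af <- v$allele_frequency
  if (!is.na(af) && af >= 0.1) {
    return(decision(FALSE, matched, "allele_frequency"))
  }
  decision(TRUE, matched, NA_character_)
}

decision <- function(retained, matched, reason) {
  structure(list(retained = retained, matched_criteria = matched,
                 exclusion_reason = reason),
            class = "prioritization_decision")
}

#' Filter a set of annotated variants
#'
#' Applies [qualifies()] to every record, order-preserving, and returns
#' both the per-record decisions and the retained subset. A malformed
#' record yields a per-record error entry; processing continues.
#'
#' @param records data.frame of variants (rows as in
#'   [annotated_variant()]).
#' @return list with `decisions` (data.frame: row per input record with
#'   retained, matched_criteria comma-joined, exclusion_reason) and
#'   `retained` (the qualifying rows of `records`, in input order).
#' @export
filter_variants <- function(records) {
  n <- nrow(records)
  rows <- lapply(seq_len(n), function(i) {
    d <- tryCatch(qualifies(records[i, ]), error = function(e) {
      decision(FALSE, character(0), paste0("error: ", conditionMessage(e)))
    })
    data.frame(record = i, retained = d$retained,
               matched_criteria = paste(d$matched_criteria, collapse = ","),
               exclusion_reason = d$exclusion_reason,
               stringsAsFactors = FALSE)
  })
  decisions <- if (n) do.call(rbind, rows) else
    data.frame(record = integer(0), retained = logical(0),
               matched_criteria = character(0), exclusion_reason = character(0))
  list(decisions = decisions,
       retained = records[decisions$retained, , drop = FALSE])
}

#' Phase relation of two variants in one sample
#'
#' Two phased variants in the same phase set are *in trans* when their
#' haplotype assignments differ (compound heterozygosity) and *in cis* when
#' they are equal; anything else — either variant unphased, or different
#' phase sets — is `unknown`.
#'
#' @param v1,v2 variants (rows as in [annotated_variant()]).
#' @return `"trans"`, `"cis"`, or `"unknown"`.
#' @export
phase_relation <- function(v1, v2) {
  p1 <- v1$genotype_phase; p2 <- v2$genotype_phase
  s1 <- v1$phase_set; s2 <- v2$phase_set
  if (p1 == "unphased" || p2 == "unphased") return("unknown")
  if (is.na(s1) || is.na(s2) || s1 != s2) return("unknown")
  if (p1 == p2) "cis" else "trans"
}

#' Read annotated variants from a VCF
#'
#' Parses a (VEP/ClinVar-style) annotated VCF into the data.frame the
#' prioritization rules operate on. INFO keys are configurable via
#' `key_map`; phased genotypes with a PS phase-set tag are read from the
#' first sample's FORMAT fields (`1|0` puts the alternate allele on
#' haplotype 1, `0|1` on haplotype 2).
#'
#' @param path VCF file.
#' @param key_map named list of INFO keys: clnsig, revel, af, impact,
#'   consequence, mane.
#' @return data.frame of annotated variants (columns as in
#'   [annotated_variant()]).
#' @export
read_annotated_vcf <- function(path,
                               key_map = list(clnsig = "CLNSIG",
                                              revel = "REVEL",
                                              af = "AF",
                                              impact = "IMPACT",
                                              consequence = "Consequence",
                                              mane = "MANE_SELECT")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_get <- function(key, numeric = FALSE) {
    x <- vcfR::extract.info(vcf, element = key, as.numeric = numeric)
    if (is.null(x)) rep(NA, nrow(fix)) else x
  }
  consequence <- info_get(key_map$consequence)
  consequence[is.na(consequence)] <- ""
  impact <- toupper(info_get(key_map$impact))
  impact[!impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")] <- "MODIFIER"
  mane_raw <- info_get(key_map$mane)
  mane <- !is.na(mane_raw) & toupper(mane_raw) %in% c("1", "YES", "TRUE", "Y")
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"), error = function(e) NULL)
  ps <- tryCatch(vcfR::extract.gt(vcf, element = "PS"), error = function(e) NULL)
  n <- nrow(fix)
  phase <- rep("unphased", n)
  phase_set <- rep(NA_character_, n)
  if (!is.null(gt) && ncol(gt) >= 1L) {
    g <- gt[, 1L]
    phase[!is.na(g) & g == "1|0"] <- "haplotype1"
    phase[!is.na(g) & g == "0|1"] <- "haplotype2"
    if (!is.null(ps)) phase_set <- as.character(ps[, 1L])
    phase_set[phase == "unphased"] <- NA_character_
  }
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    consequence = consequence, impact = impact,
    is_missense = grepl("missense", consequence, ignore.case = TRUE),
    is_frameshift = grepl("frameshift", consequence, ignore.case = TRUE),
    clinvar_significance = normalize_clinvar(info_get(key_map$clnsig)),
    revel = suppressWarnings(as.numeric(info_get(key_map$revel, numeric = TRUE))),
    allele_frequency = suppressWarnings(as.numeric(info_get(key_map$af, numeric = TRUE))),
    mane_select = mane, genotype_phase = phase, phase_set = phase_set,
    stringsAsFactors = FALSE)
}
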