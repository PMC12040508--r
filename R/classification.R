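#' Classify a single repeat allele
#'
#' Applies the locus interpretation rule to a decomposition (computed on
#' the allele consensus):
#'
#' * **Purity-rule loci** (FGF14-style): the measured quantity is the
#'   maximal uninterrupted canonical run. At or above `pathogenic_min` the
#'   allele is `pathogenic`; within the intermediate band it is
#'   `intermediate`; an allele whose total units exceed `normal_max` but
#'   whose pure run falls short because of interrupting or noncanonical
#'   units is `non_pathogenic_noncanonical`; anything else is `normal`.
#' * **Motif-catalog loci** (RFC1-style): the measured quantity is the
#'   total copies of the called motif. A pathogenic motif at or above
#'   `pathogenic_min` is `pathogenic` (below: `intermediate` in the band,
#'   else `normal`); a benign catalog motif is `benign_motif`; a motif not
#'   in the catalog is `unknown_motif`. Large AAAGG tracts are of uncertain
#'   significance: above `aaagg_benign_max` copies they are reported
#'   `unknown_motif` with a warning rather than `benign_motif`.
#'
#' @param locus an [str_locus].
#' @param decomposition an `str_decomposition` from [decompose_repeat()].
#' @param aaagg_benign_max copy count up to which an AAAGG allele is still
#'   called benign (default 1000; literature supports benignity only for
#'   smaller AAAGG expansions).
#' @return list of class `allele_classification`: `category`, `basis`
#'   (`"max_pure_canonical_run"` or `"motif_copies"`), `basis_value`,
#'   `motif_call`.
#' @export
classify_allele <- function(locus, decomposition, aaagg_benign_max = 1000) {
  stopifnot(inherits(decomposition, "str_decomposition"))
  d <- decomposition
  if (is.na(locus$pathogenic_min) && is.null(locus$intermediate)) {
    warning("locus ", locus$locus_id, " has no thresholds; allele unclassified",
            call. = FALSE)
    return(allele_class("unknown_motif", "motif_copies",
                        d$total_units, d$motif_call))
  }
  if (locus$purity_rule) {
    pure <- d$max_pure_canonical_run
    category <-
      if (!is.na(locus$pathogenic_min) && pure >= locus$pathogenic_min) "pathogenic"
      else if (!is.null(locus$intermediate) &&
               pure >= locus$intermediate[1] && pure <= locus$intermediate[2]) "intermediate"
      else if (d$total_units > locus$normal_max && pure < d$total_units)
        "non_pathogenic_noncanonical"
      else "normal"
    return(allele_class(category, "max_pure_canonical_run", pure, d$motif_call))
  }
  motif <- d$motif_call
  if (d$total_units == 0L) {
    return(allele_class("normal", "motif_copies", 0L, locus$canonical_motif))
  }
  if (motif %in% locus$pathogenic_motifs) {
    copies <- unname(d$composition[motif])
    category <-
      if (!is.na(locus$pathogenic_min) && copies >= locus$pathogenic_min) "pathogenic"
      else if (!is.null(locus$intermediate) &&
               copies >= locus$intermediate[1] && copies <= locus$intermediate[2]) "intermediate"
      else "normal"
    return(allele_class(category, "motif_copies", copies, motif))
  }
  if (motif %in% locus$benign_motifs) {
    copies <- unname(d$composition[motif])
    if (motif == "AAAGG" && copies > aaagg_benign_max) {
      warning("AAAGG tract of ", copies, " copies exceeds the size range ",
              "with established benignity; reporting unknown_motif", call. = FALSE)
      return(allele_class("unknown_motif", "motif_copies", copies, motif))
    }
    return(allele_class("benign_motif", "motif_copies", copies, motif))
  }
  allele_class("unknown_motif", "motif_copies", d$total_units, motif)
}

allele_class <- function(category, basis, basis_value, motif_call) {
  structure(list(category = category, basis = basis,
                 basis_value = as.integer(basis_value),
                 motif_call = motif_call),
            class = "allele_classification")
}

#' Combine allele classifications into a locus-level call
#'
#' Applies the inheritance rule. Monoallelic (dominant) loci: any
#' pathogenic allele makes the locus `positive`; otherwise an intermediate
#' allele gives `intermediate_uncertain`; else `negative`. Biallelic
#' (recessive) loci: two pathogenic alleles are required for `positive`;
#' exactly one gives `carrier`; else `negative`. A homozygous-appearing
#' call counts as two alleles of the same classification.
#'
#' @param locus an [str_locus].
#' @param alleles list of 1-2 `allele_classification` objects.
#' @param zygosity `"heterozygous"`, `"homozygous_appearing"`, or
#'   `"single_allele"`.
#' @return list of class `locus_genotype`: `locus_id`, `alleles`,
#'   `zygosity`, `diagnostic_status` in
#'   `{positive, carrier, intermediate_uncertain, negative, no_call}`.
#' @export
classify_locus <- function(locus, alleles, zygosity) {
  if (length(alleles) == 0L) {
    return(structure(list(locus_id = locus$locus_id, alleles = list(),
                          zygosity = NA_character_,
                          diagnostic_status = "no_call"),
                     class = "locus_genotype"))
  }
  effective <- alleles
  if (identical(zygosity, "homozygous_appearing") && length(alleles) == 1L) {
    effective <- c(alleles, alleles)
  }
  categories <- vapply(effective, `[[`, character(1), "category")
  n_path <- sum(categories == "pathogenic")
  status <- if (locus$inheritance == "monoallelic") {
    if (n_path >= 1L) "positive"
    else if (any(categories == "intermediate")) "intermediate_uncertain"
    else "negative"
  } else {
    if (n_path >= 2L) "positive"
    else if (n_path == 1L) "carrier"
    else "negative"
  }
  structure(list(locus_id = locus$locus_id, alleles = alleles,
                 zygosity = zygosity, diagnostic_status = status),
            class = "locus_genotype")
}

#' @export
print.locus_genotype <- function(x, ...) {
  cat(sprintf("<locus_genotype> %s: %s (%s)\n", x$locus_id,
              x$diagnostic_status, x$zygosity %||% "NA"))
  for (a in x$alleles) {
    cat(sprintf("  allele: %s, %s=%d, motif %s\n",
                a$category, a$basis, a$basis_value, a$motif_call))
  }
  invisible(x)
}
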