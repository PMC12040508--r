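#' STR locus definitions and the packaged ataxia catalog
#'
#' A locus definition carries everything needed to genotype and interpret one
#' short tandem repeat site: the canonical repeat motif (in its reporting
#' form, e.g. GAA for FGF14, AAGGG for RFC1), any additional pathogenic or
#' benign motifs, copy-number thresholds, the inheritance requirement
#' (monoallelic vs biallelic), whether pathogenicity is judged on the maximal
#' uninterrupted canonical run (purity rule, FGF14) or on total copies of the
#' called motif (RFC1), and the two unique 150-nt flank anchors used to
#' locate the repeat in reads.
#'
#' @param locus_id unique short identifier.
#' @param gene,disease annotation strings.
#' @param canonical_motif DNA string; its length defines `k`.
#' @param pathogenic_motifs,benign_motifs character vectors of DNA motifs
#'   (may differ in length from `k` at RFC1-style loci).
#' @param normal_max largest copy number considered normal.
#' @param intermediate inclusive `c(lo, hi)` copy interval of uncertain
#'   significance, or `NULL`.
#' @param pathogenic_min smallest pathogenic copy number, or `NA`.
#' @param inheritance `"monoallelic"` or `"biallelic"`.
#' @param purity_rule logical; classify on the maximal uninterrupted
#'   canonical run rather than total motif copies.
#' @param reference_copies copies of the canonical motif in the toy
#'   reference built by [build_locus_reference()].
#' @param left_flank,right_flank 150-nt anchor sequences.
#' @return An object of class `str_locus`.
#' @export
str_locus <- function(locus_id, gene, disease, canonical_motif,
                      pathogenic_motifs = canonical_motif,
                      benign_motifs = character(0),
                      normal_max, intermediate = NULL, pathogenic_min = NA,
                      inheritance = c("monoallelic", "biallelic"),
                      purity_rule = FALSE, reference_copies = 10L,
                      left_flank, right_flank) {
  locus <- structure(list(
    locus_id = as.character(locus_id),
    gene = as.character(gene),
    disease = as.character(disease),
    k = nchar(canonical_motif),
    canonical_motif = toupper(canonical_motif),
    pathogenic_motifs = toupper(pathogenic_motifs),
    benign_motifs = toupper(benign_motifs),
    normal_max = as.integer(normal_max),
    intermediate = if (is.null(intermediate) || all(is.na(intermediate))) NULL
                   else as.integer(intermediate),
    pathogenic_min = as.integer(pathogenic_min),
    inheritance = match.arg(inheritance),
    purity_rule = isTRUE(purity_rule),
    reference_copies = as.integer(reference_copies),
    left_flank = toupper(left_flank),
    right_flank = toupper(right_flank)
  ), class = "str_locus")
  validate_locus(locus)
  locus
}

ANCHOR_NT <- 150L

validate_locus <- function(locus) {
  motifs <- c(locus$canonical_motif, locus$pathogenic_motifs, locus$benign_motifs)
  bad <- grepl("[^ACGT]", motifs)
  if (any(bad)) {
    stop("locus ", locus$locus_id, ": motif(s) with non-ACGT characters: ",
         paste(motifs[bad], collapse = ", "), call. = FALSE)
  }
  if (nchar(locus$canonical_motif) != locus$k) {
    stop("locus ", locus$locus_id, ": canonical motif length != k", call. = FALSE)
  }
  if (nchar(locus$left_flank) != ANCHOR_NT || nchar(locus$right_flank) != ANCHOR_NT) {
    stop("locus ", locus$locus_id, ": flank anchors must be exactly ",
         ANCHOR_NT, " nt", call. = FALSE)
  }
  if (grepl("[^ACGT]", locus$left_flank) || grepl("[^ACGT]", locus$right_flank)) {
    stop("locus ", locus$locus_id, ": flank anchors must be ACGT only", call. = FALSE)
  }
  if (!is.null(locus$intermediate)) {
    lo <- locus$intermediate[1]; hi <- locus$intermediate[2]
    if (length(locus$intermediate) != 2L || lo > hi) {
      stop("locus ", locus$locus_id, ": intermediate range must be c(lo, hi), lo <= hi",
           call. = FALSE)
    }
    if (!is.na(locus$pathogenic_min) && hi >= locus$pathogenic_min) {
      stop("locus ", locus$locus_id,
           ": intermediate range must lie strictly below pathogenic_min", call. = FALSE)
    }
    if (lo <= locus$normal_max) {
      stop("locus ", locus$locus_id,
           ": intermediate range must lie strictly above normal_max", call. = FALSE)
    }
  }
  invisible(locus)
}

#' @export
print.str_locus <- function(x, ...) {
  cat(sprintf("<str_locus> %s (%s, %s)\n", x$locus_id, x$gene, x$disease))
  cat(sprintf("  motif %s (k=%d)  inheritance %s  purity_rule %s\n",
              x$canonical_motif, x$k, x$inheritance, x$purity_rule))
  cat(sprintf("  thresholds: normal<=%d  intermediate %s  pathogenic>=%s\n",
              x$normal_max,
              if (is.null(x$intermediate)) "-" else paste(x$intermediate, collapse = "-"),
              if (is.na(x$pathogenic_min)) "-" else x$pathogenic_min))
  invisible(x)
}

CATALOG_COLUMNS <- c(
  "locus_id", "gene", "disease", "k", "canonical_motif", "pathogenic_motifs",
  "benign_motifs", "normal_max", "intermediate_lo", "intermediate_hi",
  "pathogenic_min", "inheritance", "purity_rule", "reference_copies",
  "left_flank", "right_flank"
)

#' Load an STR locus catalog
#'
#' Reads a catalog of STR locus definitions from TSV (fixed column set, see
#' Details) or from its JSON mirror, validates every entry, and returns a
#' `str_catalog` (a named list of [str_locus] objects in file order).
#'
#' @details TSV columns: `locus_id, gene, disease, k, canonical_motif,
#'   pathogenic_motifs` (comma-joined), `benign_motifs` (comma-joined),
#'   `normal_max, intermediate_lo, intermediate_hi, pathogenic_min,
#'   inheritance, purity_rule, reference_copies, left_flank, right_flank`.
#'   Empty cells mean "absent". Lines starting with `#` are comments.
#'   The packaged default catalog (`default_catalog()`) covers 21 ataxia
#'   STR loci; its flank anchors are synthetic stand-ins generated with a
#'   fixed seed, not genomic sequence.
#'
#' @param path catalog file (`.tsv`/`.txt` or `.json`).
#' @return A `str_catalog`: named list of `str_locus` definitions.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, comment.char = "#", colClasses = "character",
                     check.names = FALSE)
  }
  missing_cols <- setdiff(CATALOG_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$locus_id)) {
    stop("duplicate locus_id in catalog: ",
         paste(unique(df$locus_id[duplicated(df$locus_id)]), collapse = ", "),
         call. = FALSE)
  }
  blank <- function(x) is.na(x) | x == ""
  split_motifs <- function(x) {
    if (blank(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
  }
  loci <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    interm <- if (blank(row$intermediate_lo) || blank(row$intermediate_hi)) NULL
              else c(as.integer(row$intermediate_lo), as.integer(row$intermediate_hi))
    str_locus(
      locus_id = row$locus_id, gene = row$gene, disease = row$disease,
      canonical_motif = row$canonical_motif,
      pathogenic_motifs = split_motifs(row$pathogenic_motifs),
      benign_motifs = split_motifs(row$benign_motifs),
      normal_max = as.integer(row$normal_max),
      intermediate = interm,
      pathogenic_min = if (blank(row$pathogenic_min)) NA_integer_
                       else as.integer(row$pathogenic_min),
      inheritance = row$inheritance,
      purity_rule = toupper(row$purity_rule) %in% c("TRUE", "T", "1", "YES"),
      reference_copies = as.integer(row$reference_copies),
      left_flank = row$left_flank, right_flank = row$right_flank
    )
  })
  names(loci) <- df$locus_id
  structure(loci, class = "str_catalog")
}

#' Write an STR locus catalog
#'
#' Serializes a catalog back to the TSV dialect read by [load_catalog()]
#' (or to JSON when `path` ends in `.json`). `load_catalog(write_catalog(x))`
#' reproduces every field value.
#'
#' @param catalog a `str_catalog` or list of `str_locus` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- do.call(rbind, lapply(catalog, function(l) {
    data.frame(
      locus_id = l$locus_id, gene = l$gene, disease = l$disease, k = l$k,
      canonical_motif = l$canonical_motif,
      pathogenic_motifs = paste(l$pathogenic_motifs, collapse = ","),
      benign_motifs = paste(l$benign_motifs, collapse = ","),
      normal_max = l$normal_max,
      intermediate_lo = if (is.null(l$intermediate)) "" else l$intermediate[1],
      intermediate_hi = if (is.null(l$intermediate)) "" else l$intermediate[2],
      pathogenic_min = if (is.na(l$pathogenic_min)) "" else l$pathogenic_min,
      inheritance = l$inheritance,
      purity_rule = l$purity_rule,
      reference_copies = l$reference_copies,
      left_flank = l$left_flank, right_flank = l$right_flank,
      stringsAsFactors = FALSE
    )
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = FALSE)
  } else {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Packaged default catalog of 21 ataxia STR loci
#'
#' Loads the catalog shipped with the package: 21 loci implicated in
#' spastic-ataxia spectrum disorders (FGF14, RFC1, FMR1, the polyglutamine
#' SCAs, and others). Copy-number thresholds other than FGF14's bands are
#' literature defaults; the 150-nt flank anchors are synthetic stand-ins
#' (fixed-seed random sequences), suitable for simulation and testing but
#' not for locating loci in real genomes — supply a catalog with genomic
#' flanks for real data.
#'
#' @return A `str_catalog` of 21 loci.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "ataxia_str_catalog.synthetic_flanks.tsv",
                           package = "strataxia", mustWork = TRUE))
}

#' Match a repeat unit to a catalog motif, rotation-invariantly
#'
#' A sequenced repeat unit may be any cyclic rotation of the catalog motif
#' depending on where the counting frame starts (AAG is a rotation of GAA).
#' `canonical_form()` returns the catalog motif's reporting form if `unit`
#' equals any cyclic rotation of it; the canonical motif takes priority over
#' other catalog motifs on ties, then pathogenic motifs in catalog order,
#' then benign motifs. Only motifs of the same length as `unit` are
#' considered. Returns `"other"` when nothing matches.
#'
#' @param unit DNA string (one repeat unit).
#' @param locus an [str_locus].
#' @return A catalog motif string, or `"other"`.
#' @export
canonical_form <- function(unit, locus) {
  unit <- toupper(unit)
  for (motif in locus_motifs(locus)) {
    if (nchar(motif) == nchar(unit) && unit %in% motif_rotations(motif)) {
      return(motif)
    }
  }
  "other"
}

# Catalog motifs in labeling priority order (canonical, pathogenic, benign),
# de-duplicated keeping first occurrence.
locus_motifs <- function(locus) {
  unique(c(locus$canonical_motif, locus$pathogenic_motifs, locus$benign_motifs))
}
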