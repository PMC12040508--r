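#' Genotype one STR locus from long reads
#'
#' End-to-end per-locus workflow: extract repeat segments between the flank
#' anchors ([extract_all()]), partition spanning reads into allele clusters
#' by repeat length ([partition_by_length()]), take a consensus segment per
#' allele ([build_consensus()]), decompose it into motif runs
#' ([decompose_repeat()]), classify each allele and the diploid genotype
#' ([classify_allele()], [classify_locus()]).
#'
#' @param reads reads (see [extract_all()] for accepted forms).
#' @param locus an [str_locus].
#' @param min_identity minimum anchor identity.
#' @param min_support minimum spanning reads for a call.
#' @param merge_abs,merge_frac homozygosity merge window (see
#'   [partition_by_length()]).
#' @return list of class `str_genotype_call`: the `locus_genotype`
#'   (`$result`), per-allele detail (`$alleles`: support, median/MAD copy
#'   estimate, consensus length, motif call, max pure run, category,
#'   barplot encoding), the segment table (`$segments`), read summary, and
#'   the parameters used.
#' @export
genotype_locus <- function(reads, locus, min_identity = 0.8, min_support = 3,
                           merge_abs = 5, merge_frac = 0.05) {
  params <- list(min_identity = min_identity, min_support = min_support,
                 merge_abs = merge_abs, merge_frac = merge_frac)
  segments <- suppressWarnings(extract_all(reads, locus, min_identity))
  summary <- attr(segments, "summary")
  part <- partition_by_length(segments, min_support = min_support,
                              merge_abs = merge_abs, merge_frac = merge_frac)
  if (part$status != "ok") {
    result <- classify_locus(locus, list(), NA_character_)
    return(structure(list(result = result, alleles = list(),
                          segments = segments, read_summary = summary,
                          no_call_reason = part$reason, params = params),
                     class = "str_genotype_call"))
  }
  alleles <- lapply(part$clusters, function(cl) {
    cons <- build_consensus(cl, segments, polish = locus$purity_rule)
    decomp <- decompose_repeat(cons$consensus_sequence, locus)
    cls <- classify_allele(locus, decomp)
    list(allele_index = cl$allele_index,
         support = cons$support,
         copies_median = cons$copies_median,
         copies_mad = cons$copies_mad,
         copies_reported = cons$copies_reported,
         medoid_read_id = cons$medoid_read_id,
         consensus_length = nchar(cons$consensus_sequence),
         motif_call = cls$motif_call,
         max_pure_canonical_run = decomp$max_pure_canonical_run,
         total_units = decomp$total_units,
         interruption_runs = decomp$interruption_runs,
         category = cls$category,
         classification = cls,
         decomposition = decomp,
         barplot = barplot_encoding(decomp))
  })
  result <- classify_locus(locus,
                           lapply(alleles, `[[`, "classification"),
                           part$zygosity)
  structure(list(result = result, alleles = alleles, segments = segments,
                 read_summary = summary, no_call_reason = NA_character_,
                 params = params),
            class = "str_genotype_call")
}

#' @export
print.str_genotype_call <- function(x, ...) {
  r <- x$result
  cat(sprintf("<str_genotype_call> %s: %s (%s; %d/%d reads spanning)\n",
              r$locus_id, r$diagnostic_status, r$zygosity %||% "NA",
              x$read_summary$n_spanning, x$read_summary$n_reads))
  for (a in x$alleles) {
    cat(sprintf("  allele %d: %s x %g (median; MAD %g, n=%d) max pure %d, %s\n",
                a$allele_index, a$motif_call, a$copies_median, a$copies_mad,
                a$support, a$max_pure_canonical_run, a$category))
  }
  invisible(x)
}

#' Simulate reads for a fixture or allele pair and write them out
#'
#' Thin wrapper over [simulate_reads()] + [write_simulated_reads()].
#'
#' @param locus an [str_locus].
#' @param pair `list(allele1, allele2)` of [allele_spec]s, or a diploid
#'   fixture name understood by [str_fixture()].
#' @param cfg a [sim_config].
#' @param out_dir output directory (created if needed).
#' @return invisible list of written paths (`fastq`, `truth`).
#' @export
cmd_simulate <- function(locus, pair, cfg, out_dir) {
  if (is.character(pair)) pair <- str_fixture(pair)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_reads(locus, pair$allele1, pair$allele2, cfg)
  fastq <- file.path(out_dir, paste0(locus$locus_id, ".simulated.fastq"))
  truth <- file.path(out_dir, paste0(locus$locus_id, ".truth.json"))
  write_simulated_reads(sim, fastq, truth)
  invisible(list(fastq = fastq, truth = truth))
}

#' Genotype a locus and write JSON + TSV reports
#'
#' Runs [genotype_locus()] and serializes the result: a JSON report with
#' all intermediate quantities and the run parameters (plus catalog
#' checksum and package version, for reproducibility), and a TSV allele
#' table. Zero spanning reads produce a `no_call` report, not an error.
#'
#' @param reads reads or FASTQ/FASTA path.
#' @param catalog a `str_catalog` (or catalog file path).
#' @param locus_id locus to genotype.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param ... passed to [genotype_locus()].
#' @return the `str_genotype_call`, invisibly when writing.
#' @export
cmd_genotype <- function(reads, catalog, locus_id, out_dir = NULL, ...) {
  catalog_path <- NA_character_
  if (is.character(catalog)) {
    catalog_path <- catalog
    catalog <- load_catalog(catalog)
  }
  if (!locus_id %in% names(catalog)) {
    stop("locus '", locus_id, "' not in catalog", call. = FALSE)
  }
  call <- genotype_locus(reads, catalog[[locus_id]], ...)
  if (is.null(out_dir)) return(call)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- genotype_report(call, catalog_path)
  jsonlite::write_json(report,
                       file.path(out_dir, paste0(locus_id, ".genotype.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  allele_df <- allele_table(call)
  write.table(allele_df, file.path(out_dir, paste0(locus_id, ".alleles.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(call)
}

genotype_report <- function(call, catalog_path = NA_character_) {
  checksum <- if (!is.na(catalog_path) && file.exists(catalog_path))
    unname(tools::md5sum(catalog_path)) else NA_character_
  list(locus_id = call$result$locus_id,
       diagnostic_status = call$result$diagnostic_status,
       zygosity = call$result$zygosity,
       no_call_reason = call$no_call_reason,
       read_summary = call$read_summary,
       alleles = lapply(call$alleles, function(a)
         a[c("allele_index", "support", "copies_median", "copies_mad",
             "copies_reported", "consensus_length", "motif_call",
             "max_pure_canonical_run", "total_units", "interruption_runs",
             "category")]),
       barplots = lapply(call$alleles, `[[`, "barplot"),
       params = call$params,
       catalog_md5 = checksum,
       tool_version = as.character(utils::packageVersion("strataxia")))
}

allele_table <- function(call) {
  if (length(call$alleles) == 0L) {
    return(data.frame(locus_id = character(0), allele_index = integer(0),
                      support = integer(0), copies_median = numeric(0),
                      copies_mad = numeric(0), motif_call = character(0),
                      max_pure_canonical_run = integer(0),
                      total_units = integer(0), category = character(0)))
  }
  do.call(rbind, lapply(call$alleles, function(a) {
    data.frame(locus_id = call$result$locus_id,
               allele_index = a$allele_index, support = a$support,
               copies_median = a$copies_median, copies_mad = a$copies_mad,
               motif_call = a$motif_call,
               max_pure_canonical_run = a$max_pure_canonical_run,
               total_units = a$total_units, category = a$category,
               stringsAsFactors = FALSE)
  }))
}

#' Prioritize annotated variants from a VCF and write decisions
#'
#' Reads an annotated VCF ([read_annotated_vcf()]), applies the
#' prioritization rules ([filter_variants()]), and — when two or more
#' retained variants share a gene-agnostic phase set — reports their
#' pairwise phase relations (trans/cis). Writes a decisions TSV and a TSV
#' of retained variants when `out_dir` is given.
#'
#' @param vcf_path annotated VCF.
#' @param key_map INFO key mapping (see [read_annotated_vcf()]).
#' @param out_dir output directory or `NULL`.
#' @return list with `variants`, `decisions`, `retained`, `phase_pairs`
#'   (data.frame of retained-variant pairs sharing a phase set, with their
#'   relation).
#' @export
cmd_prioritize <- function(vcf_path, key_map = NULL, out_dir = NULL) {
  variants <- if (is.null(key_map)) read_annotated_vcf(vcf_path)
              else read_annotated_vcf(vcf_path, key_map)
  res <- filter_variants(variants)
  retained <- res$retained
  pairs <- list()
  if (nrow(retained) >= 2L) {
    idx <- which(res$decisions$retained)
    for (i in seq_len(length(idx) - 1L)) {
      for (j in (i + 1L):length(idx)) {
        rel <- phase_relation(variants[idx[i], ], variants[idx[j], ])
        if (rel != "unknown") {
          pairs[[length(pairs) + 1L]] <- data.frame(
            record1 = idx[i], record2 = idx[j],
            pos1 = variants$pos[idx[i]], pos2 = variants$pos[idx[j]],
            relation = rel, stringsAsFactors = FALSE)
        }
      }
    }
  }
  phase_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(record1 = integer(0), record2 = integer(0),
               pos1 = integer(0), pos2 = integer(0), relation = character(0))
  out <- list(variants = variants, decisions = res$decisions,
              retained = retained, phase_pairs = phase_pairs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(cbind(variants[, c("chrom", "pos", "ref", "alt")],
                      res$decisions[, c("retained", "matched_criteria",
                                        "exclusion_reason")]),
                file.path(out_dir, "prioritization.decisions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(retained, file.path(out_dir, "prioritization.retained.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(phase_pairs)) {
      write.table(phase_pairs, file.path(out_dir, "prioritization.phase_pairs.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
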