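#' Diploid repeat-allele specification
#'
#' An allele is described by an ordered list of motif runs, e.g. a mixed
#' GAA/GCA expansion is a GAA run, a single GCA interruption, another GAA
#' run, and so on. The total unit count is the sum of run copies; this is
#' how mixed alleles are sized (interrupting units count toward the total).
#'
#' @param runs list of `c(motif, copies)` pairs, or a two-column
#'   data.frame with columns `motif` and `copies`.
#' @param label free-text label; the reserved label `"null_allele"` allows
#'   an empty run list.
#' @return An `allele_spec` object.
#' @examples
#' allele_spec(list(c("GAA", 3)))
#' @export
allele_spec <- function(runs, label = "allele") {
  if (is.data.frame(runs)) {
    runs <- lapply(seq_len(nrow(runs)), function(i)
      c(runs$motif[i], runs$copies[i]))
  }
  if (length(runs) == 0L && !identical(label, "null_allele")) {
    stop("runs must be non-empty unless label is 'null_allele'", call. = FALSE)
  }
  parsed <- lapply(runs, function(r) {
    motif <- toupper(as.character(r[[1]]))
    copies <- as.integer(r[[2]])
    if (grepl("[^ACGT]", motif) || nchar(motif) == 0L) {
      stop("invalid motif in allele spec: '", motif, "'", call. = FALSE)
    }
    if (is.na(copies) || copies < 1L) {
      stop("run copies must be a positive integer (motif ", motif, ")",
           call. = FALSE)
    }
    list(motif = motif, copies = copies)
  })
  total_nt <- sum(vapply(parsed, function(r) nchar(r$motif) * r$copies, numeric(1)))
  structure(list(runs = parsed, label = label, total_nt = as.integer(total_nt),
                 total_units = sum(vapply(parsed, `[[`, integer(1), "copies"))),
            class = "allele_spec")
}

#' @export
print.allele_spec <- function(x, ...) {
  cat(sprintf("<allele_spec> %s: %s (%d units, %d nt)\n", x$label,
              paste(vapply(x$runs, function(r)
                sprintf("(%s)%d", r$motif, r$copies), character(1)),
                collapse = " "),
              x$total_units, x$total_nt))
  invisible(x)
}

#' Build the DNA sequence of an allele spec
#'
#' @param spec an [allele_spec].
#' @return DNA string: the concatenation of the runs in order.
#' @export
build_allele_sequence <- function(spec) {
  stopifnot(inherits(spec, "allele_spec"))
  paste(vapply(spec$runs, function(r) strrep(r$motif, r$copies), character(1)),
        collapse = "")
}

#' Packaged allele fixtures
#'
#' Named diploid (or single-allele) layouts used throughout the test suite
#' and worked examples:
#' \describe{
#'   \item{MIX616}{mixed GAA/GCA expansion of 616 total units with four
#'     single-GCA interruptions; maximal uninterrupted GAA run 195.}
#'   \item{FMR1_85}{CGG expansion of 85 units with two AGG interruptions.}
#'   \item{MIX616_HET}{MIX616 paired with a (GAA)9 short allele.}
#'   \item{FGF14_HET}{(GAA)348 paired with (GAA)9.}
#'   \item{RFC1_P8}{biallelic (AAGGG)651 / (AAGGG)693.}
#'   \item{RFC1_P9}{compound heterozygous (AAGGG)1000 / (ACAGG)2000.}
#' }
#' Interruption positions within MIX616 and FMR1_85 are fixed choices of
#' this package (only totals and run counts are externally constrained).
#'
#' @param name fixture name (see above).
#' @return An `allele_spec` (MIX616, FMR1_85) or a list
#'   `list(allele1, allele2)` of two `allele_spec`s.
#' @export
str_fixture <- function(name) {
  switch(name,
    MIX616 = allele_spec(list(
      c("GAA", 195), c("GCA", 1), c("GAA", 100), c("GCA", 1),
      c("GAA", 100), c("GCA", 1), c("GAA", 100), c("GCA", 1),
      c("GAA", 117)), label = "MIX616"),
    FMR1_85 = allele_spec(list(
      c("CGG", 10), c("AGG", 1), c("CGG", 10), c("AGG", 1),
      c("CGG", 63)), label = "FMR1_85"),
    MIX616_HET = list(allele1 = str_fixture("MIX616"),
                      allele2 = allele_spec(list(c("GAA", 9)), label = "GAA9")),
    FGF14_HET = list(allele1 = allele_spec(list(c("GAA", 348)), label = "GAA348"),
                     allele2 = allele_spec(list(c("GAA", 9)), label = "GAA9")),
    RFC1_P8 = list(allele1 = allele_spec(list(c("AAGGG", 651)), label = "AAGGG651"),
                   allele2 = allele_spec(list(c("AAGGG", 693)), label = "AAGGG693")),
    RFC1_P9 = list(allele1 = allele_spec(list(c("AAGGG", 1000)), label = "AAGGG1000"),
                   allele2 = allele_spec(list(c("ACAGG", 2000)), label = "ACAGG2000")),
    stop("unknown fixture: ", name, call. = FALSE)
  )
}

#' Build a toy reference record for a locus
#'
#' Constructs `flank_nt` random bases + left anchor + canonical motif x
#' `reference_copies` + right anchor + `flank_nt` random bases. The random
#' context is regenerated if it happens to duplicate an anchor, so each
#' anchor occurs exactly once.
#'
#' @param locus an [str_locus].
#' @param flank_nt random context length on each side.
#' @param seed integer seed (the output is a pure function of it).
#' @return A named [Biostrings::DNAStringSet] of length 1 (FASTA-ready).
#' @export
build_locus_reference <- function(locus, flank_nt = 5000, seed = 1) {
  with_private_seed(seed, {
    repeat_part <- strrep(locus$canonical_motif, locus$reference_copies)
    for (attempt in 1:25) {
      seqchr <- paste0(random_dna(flank_nt), locus$left_flank, repeat_part,
                       locus$right_flank, random_dna(flank_nt))
      s <- DNAString(seqchr)
      if (countPattern(locus$left_flank, s) == 1L &&
          countPattern(locus$right_flank, s) == 1L) {
        out <- DNAStringSet(s)
        names(out) <- locus$locus_id
        return(out)
      }
    }
    stop("could not build a reference with unique anchors for ",
         locus$locus_id, call. = FALSE)
  })
}

#' Read-simulation configuration
#'
#' Defaults emulate the targeted assay regime this package is built around:
#' high-molecular-weight DNA sheared to ~30-kb fragments, so that reads over
#' a repeat locus usually span it, with an iid per-base substitution /
#' single-base-insertion / single-base-deletion error model.
#'
#' @param coverage_per_allele expected spanning-read count per allele.
#' @param read_length_mean fragment length in nt (default 30000).
#' @param substitution_rate,insertion_rate,deletion_rate per-base
#'   probabilities in `[0, 1)`, mutually exclusive per base.
#' @param seed integer; fixed seed gives byte-identical output.
#' @param flank_nt unique flanking context included on each side of the
#'   repeat (default 5000 nt).
#' @return A `sim_config` object.
#' @export
sim_config <- function(coverage_per_allele, read_length_mean = 30000,
                       substitution_rate = 0, insertion_rate = 0,
                       deletion_rate = 0, seed = 1, flank_nt = 5000) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1) {
    stop("error rates must lie in [0, 1) and sum below 1", call. = FALSE)
  }
  if (coverage_per_allele <= 0) stop("coverage_per_allele must be > 0", call. = FALSE)
  structure(list(coverage_per_allele = coverage_per_allele,
                 read_length_mean = as.integer(read_length_mean),
                 substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 seed = as.integer(seed),
                 flank_nt = as.integer(flank_nt)),
            class = "sim_config")
}

# Apply the iid error model to one sequence. Per base: delete, substitute
# (uniform different base), or insert one uniform base after it.
apply_errors <- function(seqchr, sub, ins, del) {
  if (sub + ins + del == 0) return(seqchr)
  x <- strsplit(seqchr, "", fixed = TRUE)[[1]]
  n <- length(x)
  u <- runif(n)
  is_del <- u < del
  is_sub <- u >= del & u < del + sub
  is_ins <- u >= del + sub & u < del + sub + ins
  if (any(is_sub)) {
    idx <- match(x[is_sub], DNA_BASES)
    shift <- sample.int(3L, sum(is_sub), replace = TRUE)
    x[is_sub] <- DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  if (any(is_ins)) {
    x[is_ins] <- paste0(x[is_ins], sample(DNA_BASES, sum(is_ins), replace = TRUE))
  }
  if (any(is_del)) x[is_del] <- ""
  paste(x, collapse = "")
}

#' Simulate long reads over a diploid repeat locus
#'
#' Builds the full locus sequence for each allele (shared random flanking
#' context + left anchor + allele repeat + right anchor + context), draws
#' reads as windows of length `min(read_length_mean, locus length)` with
#' uniform start, applies the error model, flips each read to the minus
#' strand with probability 1/2, and emits reads plus a ground-truth record.
#'
#' @param locus an [str_locus].
#' @param allele1,allele2 [allele_spec]s for the two haplotypes.
#' @param cfg a [sim_config].
#' @return A list with `reads` (a [Biostrings::QualityScaledDNAStringSet],
#'   constant Q20) and `truth` (locus id, allele specs, and a per-read
#'   data.frame with the source allele and whether the sampled window spans
#'   both anchors).
#' @export
simulate_reads <- function(locus, allele1, allele2, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_private_seed(cfg$seed, {
    ctx_left <- random_dna(cfg$flank_nt)
    ctx_right <- random_dna(cfg$flank_nt)
    hap_seq <- function(spec) paste0(ctx_left, locus$left_flank,
                                     build_allele_sequence(spec),
                                     locus$right_flank, ctx_right)
    haps <- list(hap_seq(allele1), hap_seq(allele2))
    reads <- character(0); qids <- character(0)
    truth_rows <- list()
    for (a in 1:2) {
      L <- nchar(haps[[a]])
      wlen <- min(cfg$read_length_mean, L)
      n_reads <- as.integer(round_half_away(cfg$coverage_per_allele * L / wlen))
      # anchor intervals on this haplotype (1-based inclusive)
      left_anchor <- c(cfg$flank_nt + 1L, cfg$flank_nt + ANCHOR_NT)
      right_start <- L - cfg$flank_nt - ANCHOR_NT + 1L
      right_anchor <- c(right_start, right_start + ANCHOR_NT - 1L)
      for (r in seq_len(n_reads)) {
        start <- if (L > wlen) sample.int(L - wlen + 1L, 1L) else 1L
        end <- start + wlen - 1L
        window <- substr(haps[[a]], start, end)
        spans <- start <= left_anchor[1] && end >= right_anchor[2]
        read <- apply_errors(window, cfg$substitution_rate,
                             cfg$insertion_rate, cfg$deletion_rate)
        minus <- runif(1) < 0.5
        if (minus) read <- revcomp_chr(read)
        rid <- sprintf("a%d_r%03d", a, r)
        reads <- c(reads, read); qids <- c(qids, rid)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          read_id = rid, allele = a, window_start = start, window_end = end,
          strand = if (minus) "-" else "+", spans_both_anchors = spans,
          stringsAsFactors = FALSE)
      }
    }
    dss <- DNAStringSet(reads)
    names(dss) <- qids
    quals <- PhredQuality(vapply(nchar(reads), function(n)
      strrep("5", n), character(1)))  # constant Q20
    out_reads <- QualityScaledDNAStringSet(dss, quals)
    list(reads = out_reads,
         truth = list(locus_id = locus$locus_id,
                      allele1 = allele1, allele2 = allele2,
                      reads = do.call(rbind, truth_rows)))
  })
}

#' Write simulated reads and truth to disk
#'
#' @param sim result of [simulate_reads()].
#' @param fastq_path output FASTQ (Phred+33).
#' @param truth_path optional JSON truth record.
#' @return `fastq_path`, invisibly.
#' @export
write_simulated_reads <- function(sim, fastq_path, truth_path = NULL) {
  writeXStringSet(sim$reads, fastq_path, format = "fastq",
                  qualities = sim$reads@quality)
  if (!is.null(truth_path)) {
    truth <- sim$truth
    spec_df <- function(s) data.frame(
      motif = vapply(s$runs, `[[`, character(1), "motif"),
      copies = vapply(s$runs, `[[`, integer(1), "copies"))
    jsonlite::write_json(
      list(locus_id = truth$locus_id,
           allele1 = spec_df(truth$allele1), allele2 = spec_df(truth$allele2),
           reads = truth$reads),
      truth_path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(fastq_path)
}
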