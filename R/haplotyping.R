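#' Partition spanning reads into allele clusters by repeat length
#'
#' One-dimensional k-means (Lloyd, k = 2, centers initialized at the
#' minimum and maximum observed copy estimate) splits reads into two
#' length clusters. The split is kept only when the cluster means differ by
#' more than `max(merge_abs, merge_frac * overall mean)`; otherwise all
#' reads form a single homozygous-appearing cluster. Allele index 1 is the
#' shorter allele.
#'
#' @param segments data.frame from [extract_all()] (needs
#'   `copies_estimate`, `read_id`; `identity_left`/`identity_right` are used
#'   for downstream medoid tie-breaks).
#' @param min_support minimum spanning segments for any call (default 3).
#' @param merge_abs,merge_frac homozygosity merge window: clusters closer
#'   than `max(merge_abs, merge_frac * mean)` copies are merged (defaults 5
#'   copies and 5% — wide enough to absorb size noise on homozygous loci,
#'   narrow enough to resolve near-equal biallelic expansions such as
#'   651/693 pentamer alleles).
#' @return A list of class `haplotype_partition`: `clusters` (list of
#'   cluster lists with allele_index, read_ids, support, copies_median,
#'   copies_mad — unscaled median absolute deviation), `zygosity`
#'   (`"heterozygous"` or `"homozygous_appearing"`), `status` (`"ok"` or
#'   `"no_call"`), `reason`.
#' @export
partition_by_length <- function(segments, min_support = 3,
                                merge_abs = 5, merge_frac = 0.05) {
  n <- nrow(segments)
  if (n < min_support) {
    return(structure(list(clusters = list(), zygosity = NA_character_,
                          status = "no_call",
                          reason = sprintf("only %d spanning reads (min_support %d)",
                                           n, min_support)),
                     class = "haplotype_partition"))
  }
  est <- segments$copies_estimate
  assign <- rep(1L, n)
  if (min(est) < max(est)) {
    km <- suppressWarnings(
      kmeans(est, centers = matrix(c(min(est), max(est)), ncol = 1),
             algorithm = "Lloyd", iter.max = 100))
    m <- as.numeric(km$centers)
    if (abs(m[1] - m[2]) > max(merge_abs, merge_frac * mean(est))) {
      assign <- as.integer(km$cluster)
    }
  }
  ids <- sort(unique(assign))
  clusters <- lapply(ids, function(cl) {
    idx <- which(assign == cl)
    list(read_ids = segments$read_id[idx],
         support = length(idx),
         copies_median = median(est[idx]),
         copies_mad = median(abs(est[idx] - median(est[idx]))),
         segment_idx = idx)
  })
  clusters <- clusters[order(vapply(clusters, `[[`, numeric(1), "copies_median"))]
  for (i in seq_along(clusters)) clusters[[i]]$allele_index <- i
  structure(list(clusters = clusters,
                 zygosity = if (length(clusters) == 2L) "heterozygous"
                            else "homozygous_appearing",
                 status = "ok", reason = NA_character_),
            class = "haplotype_partition")
}

#' Build a per-allele consensus repeat segment
#'
#' The consensus is the medoid read segment: the segment whose copy
#' estimate is closest to the cluster median, breaking ties by highest
#' summed anchor identity, then by lexicographically smallest read id.
#' Reported copies are the rounded cluster median. A single representative
#' read stands in for assembly/polishing; decomposition downstream is
#' tolerant of its residual errors.
#'
#' With `polish = TRUE` the medoid is additionally polished by per-column
#' majority vote: every other segment in the cluster is globally aligned to
#' the backbone and each backbone column (and each insertion between
#' columns) is replaced by the majority call across reads, ties going to
#' the backbone. At typical coverage this removes essentially all residual
#' read errors, which matters wherever classification depends on the exact
#' base sequence (maximal uninterrupted runs at purity-rule loci): a single
#' error inside a long canonical tract would otherwise break it in two.
#'
#' @param cluster one cluster from [partition_by_length()].
#' @param segments the segment data.frame the partition was computed on.
#' @param polish majority-polish the medoid against the cluster's other
#'   segments (recommended for purity-rule loci; quadratic in segment
#'   length, so left off for very long motif-count alleles where
#'   classification uses copy counts rather than exact sequence).
#' @return list with `consensus_sequence`, `copies_reported`,
#'   `medoid_read_id`, `support`, `copies_median`, `copies_mad`.
#' @export
build_consensus <- function(cluster, segments, polish = FALSE) {
  idx <- cluster$segment_idx
  stopifnot(length(idx) >= 1L)
  sub <- segments[idx, , drop = FALSE]
  dist_to_median <- abs(sub$copies_estimate - cluster$copies_median)
  id_sum <- sub$identity_left + sub$identity_right
  ord <- order(dist_to_median, -id_sum, sub$read_id)
  medoid <- sub[ord[1L], ]
  consensus <- medoid$sequence
  if (polish && nrow(sub) > 1L && nchar(consensus) > 0L) {
    others <- sub$sequence[sub$read_id != medoid$read_id]
    others <- others[nchar(others) > 0L]
    if (length(others)) consensus <- polish_backbone(consensus, others)
  }
  list(consensus_sequence = consensus,
       copies_reported = as.integer(round_half_away(cluster$copies_median)),
       medoid_read_id = medoid$read_id,
       support = cluster$support,
       copies_median = cluster$copies_median,
       copies_mad = cluster$copies_mad)
}

# One round of majority polishing: align each read segment globally to the
# backbone, vote per backbone column (base or deletion) and per insertion
# site. Ties keep the backbone call, so the result is deterministic and
# independent of read order.
polish_backbone <- function(backbone, others) {
  L <- nchar(backbone)
  n_votes <- length(others) + 1L  # backbone votes for itself everywhere
  base_votes <- list()  # per column: table of characters
  col_chars <- matrix("", nrow = length(others), ncol = L)
  ins_after <- vector("list", length(others))
  for (i in seq_along(others)) {
    aln <- pairwiseAlignment(
      DNAString(others[i]), DNAString(backbone), type = "global",
      substitutionMatrix = nucleotideSubstitutionMatrix(1, -1),
      gapOpening = 1, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    k <- 0L
    ins <- character(L + 1L)  # ins[k + 1] = bases inserted after column k
    for (j in seq_along(s)) {
      if (s[j] == "-") {
        ins[k + 1L] <- paste0(ins[k + 1L], p[j])
      } else {
        k <- k + 1L
        col_chars[i, k] <- p[j]
      }
    }
    ins_after[[i]] <- ins
  }
  majority <- function(votes, backbone_call) {
    votes <- c(votes, backbone_call)
    tab <- sort(table(votes), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (backbone_call %in% top) backbone_call else top[1L]
  }
  bb <- strsplit(backbone, "")[[1]]
  out_cols <- vapply(seq_len(L), function(k)
    majority(col_chars[, k], bb[k]), character(1))
  out_cols[out_cols == "-"] <- ""
  out_ins <- vapply(seq_len(L + 1L), function(k)
    majority(vapply(ins_after, `[[`, character(1), k), ""), character(1))
  paste0(paste0(out_ins[1L],
                paste0(out_cols, out_ins[-1L], collapse = "")), collapse = "")
}
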