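#' Choose the repeat counting frame
#'
#' A repeat segment may start mid-motif; the frame offset in `0..k-1` is
#' chosen to maximize the number of k-nt units exactly equal to a catalog
#' motif of length `k` in its reporting form (rotations do not count —
#' every rotation of a pure tract matches some rotation, so only exact
#' equality discriminates between frames), with ties broken by the
#' smallest offset.
#'
#' @param sequence DNA string, length >= k.
#' @param locus an [str_locus].
#' @param k unit length; defaults to the canonical motif length.
#' @return Integer offset in `0..k-1`.
#' @export
choose_frame <- function(sequence, locus, k = locus$k) {
  sequence <- toupper(as.character(sequence))
  len <- nchar(sequence)
  if (len < k) stop("sequence shorter than motif length k", call. = FALSE)
  motifs <- locus_motifs(locus)
  allowed <- motifs[nchar(motifs) == k]
  counts <- vapply(0:(k - 1L), function(off) {
    n_units <- (len - off) %/% k
    if (n_units == 0L) return(0L)
    starts <- off + (seq_len(n_units) - 1L) * k + 1L
    units <- substring(sequence, starts, starts + k - 1L)
    sum(units %in% allowed)
  }, integer(1))
  which.max(counts) - 1L  # which.max takes the first maximum: smallest offset
}

#' Decompose a repeat sequence into motif runs
#'
#' Cuts the sequence into consecutive k-nt units from the chosen frame and
#' labels each unit: a catalog motif's reporting form when the unit matches
#' any cyclic rotation of it (canonical motif first, then other catalog
#' motifs in catalog order); `"interrupt:<unit>"` when the unit matches no
#' catalog motif but lies within Hamming distance 1 of the canonical motif;
#' `"other"` otherwise. Consecutive same-label units merge into runs.
#'
#' For loci whose catalog motifs differ in length (RFC1-style pentamer vs
#' hexamer motifs), decomposition is run once per candidate unit length and
#' the parse maximizing exact catalog-motif units is reported.
#'
#' Any non-canonical unit — including a single sequencing-error unit —
#' breaks a pure run, so `max_pure_canonical_run` on noisy single reads is
#' conservative; classification therefore operates on the consensus
#' segment.
#'
#' @param sequence DNA string (empty allowed).
#' @param locus an [str_locus].
#' @return An object of class `str_decomposition`: `runs` (data.frame
#'   motif_label, copies, unit_start_index), `total_units`, `k`,
#'   `frame_offset`, `leftover_nt`, `max_pure_canonical_run`,
#'   `interruption_runs` (non-canonical runs flanked on both sides by
#'   canonical runs), `composition` (named total copies per label), and
#'   `motif_call` (catalog motif with most copies, or `"other"`).
#' @export
decompose_repeat <- function(sequence, locus) {
  sequence <- toupper(as.character(sequence))
  len <- nchar(sequence)
  ks <- unique(nchar(locus_motifs(locus)))  # canonical length first
  parses <- lapply(ks, function(k) {
    if (len < k) return(NULL)
    parse_with_k(sequence, locus, k)
  })
  parses <- Filter(Negate(is.null), parses)
  if (length(parses) == 0L) {  # empty or shorter than every motif
    return(structure(list(
      runs = data.frame(motif_label = character(0), copies = integer(0),
                        unit_start_index = integer(0)),
      total_units = 0L, k = locus$k, frame_offset = 0L,
      leftover_nt = as.integer(len), max_pure_canonical_run = 0L,
      interruption_runs = 0L, composition = integer(0),
      motif_call = locus$canonical_motif), class = "str_decomposition"))
  }
  scores <- vapply(parses, `[[`, integer(1), "catalog_units")
  best <- parses[[which.max(scores)]]  # tie -> canonical motif length
  structure(best[setdiff(names(best), "catalog_units")],
            class = "str_decomposition")
}

parse_with_k <- function(sequence, locus, k) {
  len <- nchar(sequence)
  off <- choose_frame(sequence, locus, k)
  n_units <- (len - off) %/% k
  starts <- off + (seq_len(n_units) - 1L) * k + 1L
  units <- substring(sequence, starts, starts + k - 1L)

  catalog <- locus_motifs(locus)
  catalog_k <- catalog[nchar(catalog) == k]
  lookup <- unlist(lapply(catalog_k, function(m) {
    rot <- motif_rotations(m)
    stats::setNames(rep(m, length(rot)), rot)
  }))
  lookup <- lookup[!duplicated(names(lookup))]  # priority order kept
  labels <- unname(lookup[units])
  unmatched <- is.na(labels)
  if (any(unmatched) && k == locus$k) {
    canon_chars <- strsplit(locus$canonical_motif, "")[[1]]
    near <- vapply(units[unmatched], function(u) {
      sum(strsplit(u, "")[[1]] != canon_chars) <= 1L
    }, logical(1))
    labels[unmatched][near] <- paste0("interrupt:", units[unmatched][near])
  }
  labels[is.na(labels)] <- "other"

  r <- rle(labels)
  run_ends <- cumsum(r$lengths)
  runs <- data.frame(motif_label = r$values, copies = r$lengths,
                     unit_start_index = c(0L, run_ends[-length(run_ends)]),
                     stringsAsFactors = FALSE)
  is_canon <- runs$motif_label == locus$canonical_motif
  max_pure <- if (any(is_canon)) max(runs$copies[is_canon]) else 0L
  n_runs <- nrow(runs)
  interior <- if (n_runs >= 3L) {
    idx <- 2:(n_runs - 1L)
    idx[!is_canon[idx] & is_canon[idx - 1L] & is_canon[idx + 1L]]
  } else integer(0)
  comp <- tapply(runs$copies, runs$motif_label, sum)
  comp <- stats::setNames(as.integer(comp), names(comp))
  in_catalog <- names(comp) %in% catalog_k
  motif_call <- if (any(in_catalog)) {
    cand <- comp[in_catalog]
    # most copies; ties resolved by catalog priority order
    top <- names(cand)[cand == max(cand)]
    catalog_k[match(TRUE, catalog_k %in% top)]
  } else "other"

  list(runs = runs, total_units = length(units), k = as.integer(k),
       frame_offset = as.integer(off),
       leftover_nt = as.integer((len - off) %% k),
       max_pure_canonical_run = as.integer(max_pure),
       interruption_runs = length(interior),
       composition = comp, motif_call = motif_call,
       # k-selection score: units exactly equal to a catalog motif as
       # written (rotation matches don't discriminate between unit lengths)
       catalog_units = sum(units %in% catalog_k))
}

#' @export
print.str_decomposition <- function(x, ...) {
  cat(sprintf("<str_decomposition> %d units (k=%d, frame %d, leftover %d nt)\n",
              x$total_units, x$k, x$frame_offset, x$leftover_nt))
  cat(sprintf("  motif call %s; max pure canonical run %d; %d interruption run(s)\n",
              x$motif_call, x$max_pure_canonical_run, x$interruption_runs))
  if (nrow(x$runs)) {
    cat("  ", paste(sprintf("(%s)%d", x$runs$motif_label, x$runs$copies),
                    collapse = " "), "\n")
  }
  invisible(x)
}

#' Run-length encoding of a decomposition for sequence bar plots
#'
#' Lossless serialization of the motif runs, one `(motif_label, copies)`
#' row per run in order — the data behind a sequence bar chart of an STR
#' allele.
#'
#' @param result an `str_decomposition` from [decompose_repeat()].
#' @return data.frame with columns `motif_label`, `copies`.
#' @export
barplot_encoding <- function(result) {
  stopifnot(inherits(result, "str_decomposition"))
  result$runs[, c("motif_label", "copies")]
}
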