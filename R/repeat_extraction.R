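#' Locate a 150-nt flank anchor in a read
#'
#' Best alignment of the anchor (and its reverse complement) against the
#' read, with unit match/mismatch/gap scores; the anchor aligns end-to-end
#' ("fit" alignment, local in the read), so a mismatched anchor edge does
#' not shift the reported boundary. A hit is reported only if identity
#' (alignment matches / anchor length) reaches `min_identity`.
#' Orientation records which strand of the anchor matched; ties between
#' strands are broken by higher identity, then smaller start, then forward.
#'
#' @param read DNA string (character or [Biostrings::DNAString]).
#' @param anchor 150-nt anchor sequence.
#' @param min_identity minimum identity in (0.5, 1]; default 0.80 tolerates
#'   roughly 10-15% read error while 150-nt anchors stay unique.
#' @return A list with `start`, `end` (0-based half-open read coordinates),
#'   `orientation` (`"forward"`/`"reverse"`), `identity`, `score`; or `NULL`
#'   when no alignment reaches `min_identity`.
#' @export
locate_anchor <- function(read, anchor, min_identity = 0.8) {
  read <- as.character(read)
  anchor <- as.character(anchor)
  if (nchar(read) == 0L) return(NULL)
  if (min_identity <= 0.5 || min_identity > 1) {
    stop("min_identity must lie in (0.5, 1]", call. = FALSE)
  }
  hits <- list(
    align_anchor(read, anchor, "forward"),
    align_anchor(read, revcomp_chr(anchor), "reverse")
  )
  hits <- Filter(function(h) h$identity >= min_identity, hits)
  if (length(hits) == 0L) return(NULL)
  if (length(hits) == 2L) {
    a <- hits[[1]]; b <- hits[[2]]
    pick <- if (a$score != b$score) a$score > b$score
            else if (a$identity != b$identity) a$identity > b$identity
            else if (a$start != b$start) a$start < b$start
            else TRUE  # forward wins exact ties
    hits <- hits[if (pick) 1L else 2L]
  }
  hits[[1]]
}

# One-strand fit alignment (anchor global, read local): the whole anchor is
# aligned, so segment endpoints stay put when edge bases mismatch — a
# substitution inside an anchor then never changes the intervening distance.
# Coordinates are 0-based half-open on the read.
align_anchor <- function(read, anchor_oriented, orientation) {
  aln <- pairwiseAlignment(
    DNAString(anchor_oriented), DNAString(read), type = "global-local",
    substitutionMatrix = nucleotideSubstitutionMatrix(match = 1, mismatch = -1),
    gapOpening = 1, gapExtension = 1)
  s <- start(subject(aln))
  w <- width(subject(aln))
  list(start = s - 1L, end = s - 1L + w,
       orientation = orientation,
       identity = nmatch(aln) / nchar(anchor_oriented),
       score = Biostrings::score(aln))
}

#' Extract the repeat segment between two anchor hits
#'
#' The read must already be oriented so the left anchor precedes the right
#' one; the repeat segment is the intervening sequence
#' `read[left$end : right$start]` (0-based half-open), and the per-read copy
#' estimate is the intervening distance divided by the motif length,
#' rounded half away from zero. Overlapping anchors yield a rejected,
#' non-spanning segment.
#'
#' @param read oriented DNA string.
#' @param left_hit,right_hit anchor hits from [locate_anchor()], in read
#'   coordinates of the oriented read.
#' @param k motif length in nt.
#' @param read_id identifier carried into the result.
#' @return A one-row data.frame (class `repeat_segment` semantics): read_id,
#'   spanning, distance_nt, copies_estimate, sequence, identity_left,
#'   identity_right.
#' @export
extract_segment <- function(read, left_hit, right_hit, k, read_id = "read") {
  read <- as.character(read)
  if (right_hit$start < left_hit$end) {
    return(data.frame(read_id = read_id, spanning = FALSE,
                      distance_nt = NA_integer_, copies_estimate = NA_real_,
                      sequence = NA_character_,
                      identity_left = left_hit$identity,
                      identity_right = right_hit$identity,
                      stringsAsFactors = FALSE))
  }
  distance <- right_hit$start - left_hit$end
  data.frame(read_id = read_id, spanning = TRUE,
             distance_nt = as.integer(distance),
             copies_estimate = round_half_away(distance / k),
             sequence = substr(read, left_hit$end + 1L, right_hit$start),
             identity_left = left_hit$identity,
             identity_right = right_hit$identity,
             stringsAsFactors = FALSE)
}

#' Extract repeat segments from all reads at a locus
#'
#' For each read, finds the left anchor on either strand, orients the read
#' so the left anchor precedes the right, finds the right anchor on the
#' oriented read, and extracts the intervening repeat segment. Reads without
#' both anchors are excluded from size estimation but counted in the
#' summary attached as attribute `"summary"`.
#'
#' @param reads a [Biostrings::DNAStringSet], named character vector, or a
#'   FASTA/FASTQ path.
#' @param locus an [str_locus].
#' @param min_identity minimum anchor identity (see [locate_anchor()]).
#' @return data.frame of spanning segments (columns as in
#'   [extract_segment()] plus `orientation`), with attribute `summary` =
#'   list(n_reads, n_spanning). Zero spanning reads give an empty
#'   data.frame with a warning.
#' @export
extract_all <- function(reads, locus, min_identity = 0.8) {
  reads <- as_read_set(reads)
  segs <- list()
  n_reads <- length(reads)
  for (i in seq_len(n_reads)) {
    read <- as.character(reads[[i]])
    rid <- names(reads)[i] %||% sprintf("read%03d", i)
    hit_l <- locate_anchor(read, locus$left_flank, min_identity)
    if (is.null(hit_l)) next
    oriented <- read
    if (hit_l$orientation == "reverse") {
      L <- nchar(read)
      oriented <- revcomp_chr(read)
      hit_l <- list(start = L - hit_l$end, end = L - hit_l$start,
                    orientation = "forward", identity = hit_l$identity,
                    score = hit_l$score)
    }
    hit_r <- align_anchor(oriented, locus$right_flank, "forward")
    if (hit_r$identity < min_identity) next
    seg <- extract_segment(oriented, hit_l, hit_r, locus$k, read_id = rid)
    seg$orientation <- if (identical(as.character(reads[[i]]), oriented))
      "forward" else "reverse"
    segs[[length(segs) + 1L]] <- seg
  }
  out <- if (length(segs)) do.call(rbind, segs) else empty_segments()
  out <- out[out$spanning, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- list(n_reads = n_reads, n_spanning = nrow(out))
  if (nrow(out) == 0L) {
    warning("no spanning reads at locus ", locus$locus_id, call. = FALSE)
  }
  out
}

empty_segments <- function() {
  data.frame(read_id = character(0), spanning = logical(0),
             distance_nt = integer(0), copies_estimate = numeric(0),
             sequence = character(0), identity_left = numeric(0),
             identity_right = numeric(0), orientation = character(0),
             stringsAsFactors = FALSE)
}

# Accept DNAStringSet / QualityScaledDNAStringSet / character vector / file
# path (FASTA or FASTQ decided by extension).
as_read_set <- function(reads) {
  if (inherits(reads, "DNAStringSet")) return(reads)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    return(readDNAStringSet(reads, format = fmt))
  }
  if (is.character(reads)) {
    out <- DNAStringSet(reads)
    if (!is.null(names(reads))) names(out) <- names(reads)
    return(out)
  }
  stop("unsupported reads input", call. = FALSE)
}
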