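DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Symmetric rounding used for copy-number estimates: 0.5 always rounds away
#' from zero, so insertions and deletions of the same magnitude bias the
#' estimate equally (unlike banker's rounding in [base::round()]).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_away(100.5)  # 101
#' round_half_away(100.33) # 100
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Reverse complement of a plain character DNA string.
revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

# Random DNA string of length n using the current RNG stream.
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# All cyclic rotations of a motif string, as a character vector.
motif_rotations <- function(motif) {
  k <- nchar(motif)
  if (k == 0L) return(character(0))
  doubled <- paste0(motif, motif)
  vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L), character(1))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Evaluate an expression with a private RNG stream seeded at `seed`,
# restoring the caller's RNG state afterwards.
with_private_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a
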