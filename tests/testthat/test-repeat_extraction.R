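# Independent ungapped-scan oracle: best anchor placement by Hamming
# matches over every offset of the read (both strands).
scan_oracle <- function(read, anchor) {
  best <- list(matches = -1L)
  for (oriented in c(anchor, strataxia:::revcomp_chr(anchor))) {
    ac <- strsplit(oriented, "")[[1]]
    rc <- strsplit(read, "")[[1]]
    for (off in 0:(nchar(read) - nchar(anchor))) {
      m <- sum(rc[off + seq_along(ac)] == ac)
      if (m > best$matches) best <- list(matches = m, start = off,
                                         forward = oriented == anchor)
    }
  }
  best
}

test_that("locate_anchor finds exact, mutated, and reverse-strand anchors", {
  anchor <- fgf14$left_flank
  withr::with_seed(101, {
    tail_seq <- strataxia:::random_dna(850)
    read <- paste0(anchor, tail_seq)
    hit <- locate_anchor(read, anchor)
    expect_identical(hit$start, 0L)
    expect_identical(hit$end, 150L)
    expect_identical(hit$identity, 1)
    expect_identical(hit$orientation, "forward")

    # anchor with 2 substitutions embedded at offset 500 of a 2-kb read
    mutated <- anchor
    substr(mutated, 40, 40) <- chartr("ACGT", "CGTA",substr(mutated, 40, 40))
    substr(mutated, 90, 90) <- chartr("ACGT", "CGTA",substr(mutated, 90, 90))
    read2 <- paste0(strataxia:::random_dna(500), mutated,
                    strataxia:::random_dna(1350))
    oracle <- scan_oracle(read2, anchor)
    expect_identical(oracle$start, 500L)
    expect_identical(oracle$matches, 148L)
    hit2 <- locate_anchor(read2, anchor)
    expect_identical(hit2$start, 500L)
    expect_equal(hit2$identity, 148 / 150)

    # reverse strand: the same anchor on the minus strand is recovered
    read3 <- paste0(strataxia:::random_dna(300),
                    strataxia:::revcomp_chr(anchor),
                    strataxia:::random_dna(200))
    hit3 <- locate_anchor(read3, anchor)
    expect_identical(hit3$orientation, "reverse")
    expect_identical(hit3$start, 300L)

    # unrelated read: no hit above threshold
    expect_null(locate_anchor(strataxia:::random_dna(1000), anchor))
    expect_null(locate_anchor("", anchor))
  })
  expect_error(locate_anchor("ACGT", anchor, min_identity = 0.4), "min_identity")
})

test_that("extract_segment computes the intervening distance and rounds half away", {
  left <- list(start = 0L, end = 100L, identity = 1, orientation = "forward")
  right <- list(start = 400L, end = 550L, identity = 1, orientation = "forward")
  read <- strrep("A", 600)
  seg <- extract_segment(read, left, right, k = 3)
  expect_true(seg$spanning)
  expect_identical(seg$distance_nt, 300L)
  expect_identical(seg$copies_estimate, 100)
  # distance 301, k 3 -> round(100.33) = 100
  right301 <- list(start = 401L, end = 551L, identity = 1)
  expect_identical(extract_segment(read, left, right301, 3)$copies_estimate, 100)
  # round-half-away: distance 301 with k 2 -> 150.5 -> 151
  expect_identical(extract_segment(read, left, right301, 2)$copies_estimate, 151)
  # overlapping anchors are rejected
  bad <- extract_segment(read, list(start = 0L, end = 450L, identity = 1),
                         right, 3)
  expect_false(bad$spanning)
})

test_that("extract_all excludes non-spanning reads and is strand-invariant", {
  sim <- quick_het_sim(seed = 21, coverage = 6)
  segs <- extract_all(sim$reads, fgf14)
  expect_identical(attr(segs, "summary")$n_spanning, 12L)
  flipped <- Biostrings::reverseComplement(Biostrings::DNAStringSet(sim$reads))
  names(flipped) <- names(sim$reads)
  segs_flip <- extract_all(flipped, fgf14)
  ord <- function(d) d[order(d$read_id), c("read_id", "distance_nt", "copies_estimate")]
  expect_identical(ord(segs_flip), ord(segs))

  # reads containing only the left flank never span
  withr::with_seed(5, {
    left_only <- paste0(strataxia:::random_dna(200), fgf14$left_flank,
                        strrep("GAA", 30))
  })
  expect_warning(none <- extract_all(c(r1 = left_only), fgf14), "no spanning")
  expect_identical(nrow(none), 0L)
  expect_identical(attr(none, "summary")$n_reads, 1L)
})

test_that("substitution-only noise never changes the copy estimate", {
  pair <- str_fixture("FGF14_HET")
  sim <- simulate_reads(fgf14, pair$allele1, pair$allele2,
                        sim_config(coverage_per_allele = 10,
                                   substitution_rate = 0.02, seed = 31,
                                   flank_nt = 400))
  segs <- extract_all(sim$reads, fgf14)
  expect_setequal(unique(segs$copies_estimate), c(9, 348))
})
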