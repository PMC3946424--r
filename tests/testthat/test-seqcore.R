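test_that("reverse complement follows Watson-Crick pairing and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("ANG"), "CNT")
  expect_equal(reverse_complement(""), "")
  expect_error(reverse_complement("ACGU"), "non-DNA")
  expect_error(reverse_complement("ACRT"), "non-DNA")
  # lower case is accepted and uppercased on ingestion
  expect_equal(reverse_complement("acgt"), "ACGT")

  set.seed(101)
  seqs <- random_dna(200, sample(0:60, 200, TRUE),
                     alphabet = c("A", "C", "G", "T", "N"))
  expect_identical(reverse_complement(reverse_complement(seqs)), seqs)
})

test_that("terminal palindrome length matches a brute-force oracle", {
  expect_equal(terminal_palindrome_length("ACGTACCCCCTACGT"), 5L)
  expect_equal(terminal_palindrome_length("AAAA"), 0L)
  expect_equal(terminal_palindrome_length("TTAA"), 2L)  # capped at floor(n/2)
  expect_equal(terminal_palindrome_length(""), 0L)
  # N never counts as complementary
  expect_equal(terminal_palindrome_length("NACGTN"), 0L)

  set.seed(102)
  seqs <- random_dna(2000, sample(2:200, 2000, TRUE),
                     alphabet = c("A", "C", "G", "T", "N"),
                     prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
  expect_identical(terminal_palindrome_length(seqs),
                   as.integer(brute_palindrome(seqs)))
})

test_that("palindrome matches are nested: every k below L also matches", {
  set.seed(103)
  seqs <- random_dna(300, sample(8:80, 300, TRUE))
  L <- terminal_palindrome_length(seqs)
  for (r in which(L > 0)) {
    s <- seqs[r]
    n <- nchar(s)
    for (k in seq_len(L[r])) {
      expect_identical(substr(s, n - k + 1L, n),
                       reverse_complement(substr(s, 1L, k)))
    }
    if (L[r] < n %/% 2) {
      k <- L[r] + 1L
      expect_false(substr(s, n - k + 1L, n) ==
                     reverse_complement(substr(s, 1L, k)))
    }
  }
})

test_that("clipping removes the 3' palindrome once, only when >= min_clip", {
  r <- read_set("ACGTACCCCCTACGT", quality = "IIIIIIIIIIABCDE")
  out <- clip_palindrome(r)
  expect_equal(out$reads$sequence, "ACGTACCCCC")
  expect_equal(out$reads$quality, "IIIIIIIIII")   # qualities clipped in sync
  expect_equal(out$calls$clip_length, 5L)
  expect_true(out$calls$clipped)

  # palindrome of exactly 3 is below the default threshold of 4
  s3 <- "ACGAAAAAACGT"
  expect_equal(terminal_palindrome_length(s3), 3L)
  out3 <- clip_palindrome(read_set(s3))
  expect_equal(out3$reads$sequence, s3)
  expect_false(out3$calls$clipped)
  expect_equal(out3$calls$clip_length, 0L)

  out0 <- clip_palindrome(read_set("AAAA"))
  expect_equal(out0$reads$sequence, "AAAA")

  # property: 5' prefix untouched, length shrinks by exactly clip_length
  set.seed(104)
  seqs <- random_dna(500, sample(10:120, 500, TRUE))
  rs <- read_set(seqs)
  cl <- clip_palindrome(rs)
  keep <- nchar(seqs) - cl$calls$clip_length
  expect_identical(cl$reads$sequence, substr(seqs, 1, keep))
  expect_identical(nchar(cl$reads$sequence), keep)
})

test_that("random uniform reads carry palindromes >= 4 at about (1/4)^4", {
  set.seed(105)
  n <- 2e5
  seqs <- random_dna(n, 70)
  frac <- mean(terminal_palindrome_length(seqs) >= 4)
  p0 <- 0.25^4
  ci <- p0 + c(-1, 1) * 2.58 * sqrt(p0 * (1 - p0) / n)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("GC content counts every base in the denominator", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content(strrep("ACGT", 5)), 0.5)
  expect_equal(gc_content("ACGN"), 0.5)   # N dilutes but never counts as GC
  expect_error(gc_content(""), "empty")
})

test_that("melting temperature follows the basic formula, Wallace below 14 bp", {
  expect_equal(melting_temperature(strrep("ACGT", 5)), 51.78)
  expect_equal(melting_temperature(strrep("G", 20)), 64.9 + 41 * 3.6 / 20)
  # composition-only: shuffling leaves Tm unchanged
  set.seed(106)
  s <- random_dna(1, 40)
  sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(melting_temperature(s), melting_temperature(sh))
  # strictly increasing in GC at fixed length
  tms <- melting_temperature(c("ATATATATATATATAT", "ATATATATATATATAG",
                               "GTATATATATATATAG"))
  expect_true(all(diff(tms) > 0))
  # Wallace rule below 14 bases, with a warning
  expect_warning(tm13 <- melting_temperature("GGGGGGGGGGGGG"), "Wallace")
  expect_equal(tm13, 4 * 13)
  expect_warning(expect_equal(melting_temperature("ATGC"), 2 * 2 + 4 * 2))
})

test_that("dinucleotide repeat span reports tandem hetero-2-mer runs only", {
  expect_equal(dinucleotide_repeat_span("ACACACGG"), 6L)
  expect_equal(dinucleotide_repeat_span("AAAAAA"), 0L)   # homopolymer excluded
  expect_equal(dinucleotide_repeat_span("TTACGT"), 0L)
  expect_equal(dinucleotide_repeat_span("ACACA"), 4L)    # partial copy ignored
  expect_equal(dinucleotide_repeat_span("GGTGTGTGTCC"), 8L)
  expect_equal(dinucleotide_repeat_span(c("ACAC", "AC")), c(4L, 0L))
})

test_that("duplicate fraction is (total - distinct) / total", {
  expect_equal(duplicate_fraction(c("AAAA", "CCCC", "GGGG")), 0)
  expect_equal(duplicate_fraction(c("AAAA", "AAAA", "CCCC")), 1 / 3)
  expect_equal(duplicate_fraction(rep("ACGT", 10)), 9 / 10)
  expect_error(duplicate_fraction(character(0)), "at least one")
})
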