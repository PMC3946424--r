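#' Reverse complement of DNA sequences
#'
#' Watson-Crick complement, reversed.  `N` maps to `N`; characters outside
#' `{A,C,G,T,N}` are rejected.  The operation is an involution.
#'
#' @param seq character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  seq <- check_dna(seq)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

#' Terminal interrupted-palindrome length
#'
#' Returns, for each read, the largest `L <= floor(n/2)` such that the last
#' `L` bases are the reverse complement of the first `L` bases.
#' Equivalently, the count of consecutive end pairs `(seq[t], seq[n-1-t])`
#' (0-based, from the outside in) that are Watson-Crick complementary,
#' stopping at the first non-complementary pair.  Positions holding `N`
#' never count as complementary.  An empty sequence yields 0.
#'
#' @param seq character vector of DNA sequences.
#' @return Integer vector of palindrome lengths.
#' @examples
#' terminal_palindrome_length("ACGTACCCCCTACGT")  # 5
#' terminal_palindrome_length("AAAA")             # 0
#' @export
terminal_palindrome_length <- function(seq) {
  seq <- check_dna(seq)
  cpp_palindrome_length(seq)
}

#' Detect terminal palindromes in a read set
#'
#' One call row per read: the read length, the detected palindrome length
#' `L`, whether the read would be clipped at the given threshold, and the
#' resulting clip length (`L` if clipped, else 0).
#'
#' @param reads read-set tibble (see [read_set()]).
#' @param min_clip minimum palindrome length that triggers clipping
#'   (default 4, i.e. palindromes longer than 3 bp).
#' @return Tibble with columns `read_id`, `read_length`,
#'   `palindrome_length`, `clipped`, `clip_length`.
#' @export
detect_palindromes <- function(reads, min_clip = 4L) {
  reads <- assert_read_set(reads)
  stopifnot(min_clip >= 1)
  L <- cpp_palindrome_length(check_dna(reads$sequence))
  clipped <- L >= min_clip
  tibble::tibble(
    read_id = reads$id,
    read_length = nchar(reads$sequence),
    palindrome_length = L,
    clipped = clipped,
    clip_length = ifelse(clipped, L, 0L)
  )
}

#' Clip terminal palindromes from the 3' end
#'
#' Reads whose terminal palindrome length `L` is at least `min_clip` lose
#' their last `L` bases (and the matching quality characters) in a single
#' pass; all other reads are returned unchanged.  The 5' end is never
#' modified.  Clipping is not iterated: the per-read call table carries a
#' `residual` flag marking reads whose re-detected palindrome after the
#' clip is still `>= min_clip`.
#'
#' @inheritParams detect_palindromes
#' @return A list with `reads` (the clipped read set) and `calls` (the
#'   per-read call tibble of [detect_palindromes()] plus `residual`).
#' @examples
#' clip_palindrome(read_set("ACGTACCCCCTACGT"))$reads$sequence  # "ACGTACCCCC"
#' @export
clip_palindrome <- function(reads, min_clip = 4L) {
  reads <- assert_read_set(reads)
  calls <- detect_palindromes(reads, min_clip)
  keep <- nchar(reads$sequence) - calls$clip_length
  out <- reads
  out$sequence <- substr(reads$sequence, 1L, keep)
  out$quality <- ifelse(is.na(reads$quality), NA_character_,
                        substr(reads$quality, 1L, keep))
  calls$residual <- cpp_palindrome_length(out$sequence) >= min_clip &
    calls$clipped
  list(reads = out, calls = calls)
}

#' GC content
#'
#' Fraction of G and C bases; `N` counts in the denominator, so a read's GC
#' content is relative to its full length.
#'
#' @param seq character vector of non-empty DNA sequences.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- check_dna(seq, allow_empty = FALSE)
  gc <- nchar(gsub("[^GC]", "", seq))
  gc / nchar(seq)
}

#' Oligonucleotide melting temperature
#'
#' For sequences longer than 13 bases, the salt-unadjusted basic formula
#' \deqn{T_m = 64.9 + 41 (GC - 16.4) / n} where `GC` is the G+C count and
#' `n` the length.  For sequences of 13 bases or fewer, the Wallace rule
#' \eqn{2(A+T) + 4(G+C)} is used, with a warning (the basic formula is not
#' calibrated at those lengths).  `N` counts toward length (and toward A/T
#' under the Wallace rule's weak term).
#'
#' @param seq character vector of non-empty DNA sequences.
#' @return Numeric vector of temperatures in degrees Celsius.
#' @examples
#' melting_temperature(strrep("ACGT", 5))  # 51.78
#' @export
melting_temperature <- function(seq) {
  seq <- check_dna(seq, allow_empty = FALSE)
  n <- nchar(seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  out <- 64.9 + 41 * (gc - 16.4) / n
  short <- n <= 13
  if (any(short)) {
    warning("sequences of <= 13 bases scored with the Wallace rule ",
            "2(A+T) + 4(G+C)")
    out[short] <- 2 * (n[short] - gc[short]) + 4 * gc[short]
  }
  out
}

#' Longest dinucleotide tandem-repeat span
#'
#' Length in bases of the longest tandem run of a 2-mer whose two bases
#' differ (e.g. `ACACAC`).  Homopolymer runs do not count, and a run needs
#' at least two complete copies (4 bases); otherwise 0 is reported.
#'
#' @param seq character vector of DNA sequences.
#' @return Integer vector of spans in bases.
#' @examples
#' dinucleotide_repeat_span("ACACACGG")  # 6
#' @export
dinucleotide_repeat_span <- function(seq) {
  seq <- check_dna(seq)
  dinucs <- c(t(outer(DNA_BASES, DNA_BASES, paste0)))
  dinucs <- dinucs[substr(dinucs, 1, 1) != substr(dinucs, 2, 2)]
  best <- integer(length(seq))
  for (d in dinucs) {
    hits <- gregexpr(paste0("(?:", d, "){2,}"), seq, perl = TRUE)
    span <- vapply(hits, function(m) {
      if (m[1] == -1L) 0L else max(attr(m, "match.length"))
    }, integer(1))
    best <- pmax(best, span)
  }
  best
}

#' Duplicate fraction of a read collection
#'
#' Fraction of reads that are exact sequence copies of another read:
#' `(total - distinct) / total`.  This is a sequence-identity surrogate for
#' alignment-based duplicate marking and needs no reference genome.
#'
#' @param reads read-set tibble or character vector of sequences.
#' @return A single fraction in `[0, 1)`.
#' @examples
#' duplicate_fraction(c("AAAA", "AAAA", "CCCC"))  # 1/3
#' @export
duplicate_fraction <- function(reads) {
  seqs <- if (is.data.frame(reads)) assert_read_set(reads)$sequence
          else check_dna(reads)
  if (length(seqs) == 0) stop("`reads` must contain at least one read")
  (length(seqs) - length(unique(seqs))) / length(seqs)
}
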