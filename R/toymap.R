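#' Map reads to a small genome by exhaustive ungapped scan
#'
#' Every ungapped placement of each read over both strands is scored by
#' mismatch count; the best placement wins (ties: leftmost, + strand
#' first).  A read is mapped iff its best mismatch fraction is at most
#' `max_mismatch_frac` and the best placement is unique at that count
#' (uniqueness stands in for a mapping-quality filter).  Reads longer than
#' the genome are unmapped.  Intended for synthetic genomes only: the scan
#' is exhaustive.
#'
#' @param reads read-set tibble or character vector of sequences.
#' @param genome a [generate_genome()] object or DNA string.
#' @param max_mismatch_frac maximum mismatch fraction for a mapped read.
#' @return Tibble with `read_id`, `mapped`, `pos` (0-based, + strand),
#'   `strand` (`+`/`-`), `mismatches`.
#' @export
map_reads <- function(reads, genome, max_mismatch_frac = 0.03) {
  if (is.character(reads)) reads <- read_set(reads)
  reads <- assert_read_set(reads)
  gseq <- as_genome_sequence(genome)
  res <- cpp_map_reads(check_dna(reads$sequence), gseq, max_mismatch_frac)
  tibble::tibble(
    read_id = reads$id,
    mapped = res$mapped,
    pos = res$pos,
    strand = ifelse(is.na(res$strand), NA_character_,
                    ifelse(res$strand > 0, "+", "-")),
    mismatches = res$mismatches
  )
}

#' @rdname map_reads
#' @param read a single sequence or one-row read set.
#' @export
map_read <- function(read, genome, max_mismatch_frac = 0.03) {
  map_reads(read, genome, max_mismatch_frac)
}

#' Fraction of reads that align
#'
#' Mapped reads divided by either the collapsed-read count (the reads
#' actually mapped) or a supplied untrimmed pair count; both denominators
#' are reported to avoid committing to one convention.
#'
#' @param reads read-set tibble or character vector.
#' @param genome genome object or DNA string.
#' @param max_mismatch_frac mapping threshold.
#' @param n_untrimmed_pairs optional denominator for the pair-relative
#'   fraction.
#' @return List with `n_mapped`, `frac_of_reads` and (when a pair count is
#'   given) `frac_of_pairs`.
#' @export
alignability <- function(reads, genome, max_mismatch_frac = 0.03,
                         n_untrimmed_pairs = NULL) {
  if (is.character(reads)) reads <- read_set(reads)
  reads <- assert_read_set(reads)
  if (nrow(reads) == 0) stop("`reads` must contain at least one read")
  aln <- map_reads(reads, genome, max_mismatch_frac)
  out <- list(n_mapped = sum(aln$mapped),
              frac_of_reads = mean(aln$mapped))
  if (!is.null(n_untrimmed_pairs)) {
    out$frac_of_pairs <- out$n_mapped / n_untrimmed_pairs
  }
  out
}

#' Per-position substitution profile at read ends
#'
#' For mapped reads, compares each read against the genome slice it
#' aligned to (orienting the reference to the read strand) and reports,
#' for 5' offsets `1..k` and 3' offsets `-1..-k`, the rate of C-to-T,
#' G-to-A and all other substitutions among aligned bases — the classic
#' damage-plot layout used to diagnose deamination (5' C-to-T), its
#' complement (3' G-to-A), and artificial 3' fill-in (elevated "other").
#'
#' @param alignments tibble from [map_reads()].
#' @param reads the read set that was mapped (row-aligned by `read_id`).
#' @param genome genome object or DNA string.
#' @param k number of offsets profiled from each end.
#' @return Tibble with `end` (`"5p"`/`"3p"`), `offset` (1-based from the
#'   respective end), `class` (`"C>T"`, `"G>A"`, `"other"`), `rate`, and
#'   the aligned-base denominator `n`.
#' @export
positional_mismatch_profile <- function(alignments, reads, genome, k = 25L) {
  reads <- assert_read_set(reads)
  gseq <- as_genome_sequence(genome)
  stopifnot(nrow(alignments) == nrow(reads))
  idx <- which(alignments$mapped)
  counts <- array(0, dim = c(2L, k, 3L),
                  dimnames = list(c("5p", "3p"), NULL,
                                  c("C>T", "G>A", "other")))
  denom <- matrix(0, 2L, k, dimnames = list(c("5p", "3p"), NULL))
  for (r in idx) {
    s <- reads$sequence[r]
    len <- nchar(s)
    ref <- substr(gseq, alignments$pos[r] + 1L, alignments$pos[r] + len)
    if (alignments$strand[r] == "-") ref <- reverse_complement(ref)
    rb <- strsplit(s, "", fixed = TRUE)[[1]]
    gb <- strsplit(ref, "", fixed = TRUE)[[1]]
    for (end in 1:2) {
      kk <- min(k, len)
      off <- seq_len(kk)
      p <- if (end == 1) off else len - off + 1L
      denom[end, off] <- denom[end, off] + 1
      mm <- which(rb[p] != gb[p])
      for (t in mm) {
        cls <- if (gb[p[t]] == "C" && rb[p[t]] == "T") "C>T"
               else if (gb[p[t]] == "G" && rb[p[t]] == "A") "G>A"
               else "other"
        counts[end, off[t], cls] <- counts[end, off[t], cls] + 1
      }
    }
  }
  grid <- expand.grid(end = c("5p", "3p"), offset = seq_len(k),
                      class = c("C>T", "G>A", "other"),
                      stringsAsFactors = FALSE)
  ei <- match(grid$end, c("5p", "3p"))
  ci <- match(grid$class, c("C>T", "G>A", "other"))
  grid$n <- denom[cbind(ei, grid$offset)]
  grid$rate <- ifelse(grid$n > 0,
                      counts[cbind(ei, grid$offset, ci)] / grid$n,
                      NA_real_)
  tibble::as_tibble(grid[order(grid$end, grid$class, grid$offset),
                         c("end", "offset", "class", "rate", "n")])
}
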