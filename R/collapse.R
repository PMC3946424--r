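#' Parameters for adapter trimming and pair collapsing
#'
#' Defaults follow common practice for merging short degraded-DNA
#' fragments: a minimum overlap of 11 bases, at most a 0.33 per-base
#' mismatch rate inside the overlap, a 25 bp minimum merged length, and
#' trimming of terminal N runs.
#'
#' @param min_overlap minimum forward/reverse overlap (bases).
#' @param max_mismatch_rate maximum mismatch fraction allowed in the
#'   overlap (and, during adapter trimming, in the adapter match).
#' @param min_length minimum merged read length; shorter products are
#'   discarded.
#' @param trim_ns strip leading/trailing N runs during adapter trimming.
#' @return A list of class `collapse_params`.
#' @export
collapse_params <- function(min_overlap = 11L, max_mismatch_rate = 0.33,
                            min_length = 25L, trim_ns = TRUE) {
  stopifnot(min_overlap >= 1, max_mismatch_rate > 0, max_mismatch_rate < 1,
            min_length >= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate,
                 min_length = as.integer(min_length),
                 trim_ns = isTRUE(trim_ns)),
            class = "collapse_params")
}

#' Trim 3' adapter sequence from reads
#'
#' Removes the longest 3' suffix of each read that matches a prefix of the
#' adapter with a per-base mismatch rate at most `max_mismatch_rate`
#' (candidate suffixes are compared in register with the adapter start, so
#' the suffix length never exceeds the adapter length).  Ties go to the
#' longer trim.  With `trim_ns`, leading and trailing N runs are removed
#' afterwards.  Reads with no acceptable match are returned unchanged.
#'
#' @param reads read-set tibble.
#' @param adapter adapter sequence (DNA string).
#' @param max_mismatch_rate maximum mismatch fraction in the adapter match.
#' @param trim_ns strip terminal N runs after adapter removal.
#' @return The trimmed read set.
#' @export
trim_adapter <- function(reads, adapter, max_mismatch_rate = 0.33,
                         trim_ns = TRUE) {
  reads <- assert_read_set(reads)
  adapter <- check_dna(adapter, allow_empty = FALSE, arg = "adapter")
  if (length(adapter) != 1) stop("`adapter` must be a single sequence")
  b <- cpp_trim_bounds(check_dna(reads$sequence), adapter,
                       max_mismatch_rate, isTRUE(trim_ns))
  out <- reads
  out$sequence <- substr(reads$sequence, b[, 1] + 1L, b[, 2])
  out$quality <- ifelse(is.na(reads$quality), NA_character_,
                        substr(reads$quality, b[, 1] + 1L, b[, 2]))
  out
}

#' Collapse forward/reverse read pairs into single reads
#'
#' The reverse complement of each reverse read is slid against its forward
#' mate over all offsets; the placement with the best identity score
#' (matches minus mismatches) wins, ties going to the longer overlap and
#' then the smaller offset.  A pair is collapsed iff
#' the best overlap spans at least `min_overlap` bases with a mismatch
#' fraction at most `max_mismatch_rate`, and the merged product is at
#' least `min_length` bases.  At a disagreement the higher-quality base is
#' kept (equal qualities: the forward base; an N always loses to a called
#' base); the merged quality at every position is the best available
#' score.  Reads should be adapter-trimmed first.
#'
#' @param fwd,rev read-set tibbles of equal length (mates row-aligned).
#' @param params a [collapse_params()] object.
#' @return Tibble with one row per input pair: `id`, `sequence`, `quality`
#'   (NA where not collapsed), `collapsed`, `overlap`, `mismatches`.
#' @export
collapse_pairs <- function(fwd, rev, params = collapse_params()) {
  fwd <- assert_read_set(fwd, "fwd")
  rev <- assert_read_set(rev, "rev")
  if (nrow(fwd) != nrow(rev)) stop("`fwd` and `rev` must pair up row-wise")
  if (any(!nzchar(fwd$sequence)) || any(!nzchar(rev$sequence))) {
    stop("pair members must be non-empty")
  }
  stopifnot(inherits(params, "collapse_params"))
  fq <- fill_quality(fwd)
  rq <- fill_quality(rev)
  res <- cpp_collapse_pairs(check_dna(fwd$sequence), fq,
                            check_dna(rev$sequence), rq,
                            params$min_overlap, params$max_mismatch_rate,
                            params$min_length)
  tibble::tibble(id = fwd$id,
                 sequence = as.character(res$sequence),
                 quality = as.character(res$quality),
                 collapsed = res$collapsed,
                 overlap = res$overlap,
                 mismatches = res$mismatches)
}

#' Collapse a single read pair
#'
#' Convenience wrapper around [collapse_pairs()] for one pair.
#'
#' @param forward,reverse one-row read sets or single sequences.
#' @param params a [collapse_params()] object.
#' @return A one-row collapse result tibble; `collapsed` is `FALSE` when
#'   the pair is rejected.
#' @export
collapse_pair <- function(forward, reverse, params = collapse_params()) {
  if (is.character(forward)) forward <- read_set(forward)
  if (is.character(reverse)) reverse <- read_set(reverse)
  collapse_pairs(forward, reverse, params)
}

# Phred+33 placeholder (Q40) for reads lacking qualities.
fill_quality <- function(reads) {
  q <- reads$quality
  miss <- is.na(q)
  q[miss] <- strrep("I", nchar(reads$sequence[miss]))
  q
}
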