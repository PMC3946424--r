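#' Interrupted-palindrome content of a read set
#'
#' Percentage of reads whose terminal palindrome length is at least
#' `min_report_len`.  The default threshold of 4 counts palindromes
#' longer than three base pairs, the convention used when quantifying
#' the hairpin artifact against its chance background of
#' \eqn{(1/4)^4 \approx 0.39\%}.
#'
#' @param reads read-set tibble or character vector of sequences.
#' @param min_report_len minimum palindrome length counted (bases).
#' @return Percentage in `[0, 100]`.
#' @export
palindrome_content <- function(reads, min_report_len = 4L) {
  seqs <- if (is.data.frame(reads)) assert_read_set(reads)$sequence
          else check_dna(reads)
  if (length(seqs) == 0) stop("`reads` must contain at least one read")
  L <- cpp_palindrome_length(seqs)
  100 * mean(L >= min_report_len)
}

#' Subsample reads uniformly without replacement
#'
#' Draws `n` reads uniformly without replacement, reproducibly under
#' `seed`.  When a paired mate set is supplied, pairs are sampled jointly
#' (same rows from both).  Requests larger than the read count return all
#' reads with a warning.
#'
#' @param reads read-set tibble (read 1 when paired).
#' @param n number of reads (pairs) to keep.
#' @param seed integer seed.
#' @param mate optional second read set sampled jointly with `reads`.
#' @return A read-set tibble, or a list `r1`/`r2` when `mate` is given.
#' @export
subsample_reads <- function(reads, n = 1e6, seed = NULL, mate = NULL) {
  reads <- assert_read_set(reads)
  stopifnot(n >= 1)
  if (!is.null(mate)) {
    mate <- assert_read_set(mate, "mate")
    if (nrow(mate) != nrow(reads)) stop("`mate` must pair up with `reads`")
  }
  total <- nrow(reads)
  if (n >= total) {
    if (n > total) warning("fewer than ", n, " reads available; keeping all")
    keep <- seq_len(total)
  } else {
    keep <- sort(with_seed(seed, sample.int(total, n)))
  }
  if (is.null(mate)) reads[keep, ] else
    list(r1 = reads[keep, ], r2 = mate[keep, ])
}

#' Summarize a library of collapsed reads
#'
#' Library-level report: read counts, mean length, GC, palindrome content,
#' the palindrome length histogram, and length / GC / melting-temperature
#' / duplication statistics stratified by palindrome status (reads with
#' `L > 3` versus the rest) — the stratification in which hairpin-artifact
#' reads show shorter lengths, lower GC, lower Tm and higher clonality.
#'
#' @param collapsed_reads read-set tibble of collapsed reads.
#' @param untrimmed_pair_count optional raw pair count behind the library;
#'   enables `pct_collapsed`.
#' @param min_report_len palindrome length counted as artifact-bearing.
#' @param library_id label carried into the summary.
#' @return A list of class `library_summary`; see fields in the examples.
#' @export
summarize_library <- function(collapsed_reads, untrimmed_pair_count = NULL,
                              min_report_len = 4L, library_id = "library") {
  reads <- assert_read_set(collapsed_reads)
  if (nrow(reads) == 0) stop("`collapsed_reads` must contain reads")
  L <- cpp_palindrome_length(check_dna(reads$sequence))
  has_pal <- L >= min_report_len
  gc <- gc_content(reads$sequence)
  tm <- suppressWarnings(melting_temperature(reads$sequence))
  len <- nchar(reads$sequence)
  hist_tab <- table(factor(L, levels = 0:max(L)))
  strat <- function(x, f) {
    c(palindrome = if (any(has_pal)) f(x[has_pal]) else NA_real_,
      clean = if (any(!has_pal)) f(x[!has_pal]) else NA_real_)
  }
  dup <- c(
    palindrome = if (any(has_pal))
      duplicate_fraction(reads$sequence[has_pal]) else NA_real_,
    clean = if (any(!has_pal))
      duplicate_fraction(reads$sequence[!has_pal]) else NA_real_
  )
  out <- list(
    library_id = library_id,
    n_collapsed = nrow(reads),
    n_pairs_untrimmed = untrimmed_pair_count,
    pct_collapsed = if (is.null(untrimmed_pair_count)) NULL else
      100 * nrow(reads) / untrimmed_pair_count,
    mean_length = mean(len),
    gc_pct = 100 * mean(gc),
    palindrome_content_pct = 100 * mean(has_pal),
    palindrome_length_histogram = hist_tab,
    mean_length_by_status = strat(len, mean),
    gc_pct_by_status = 100 * strat(gc, mean),
    mean_tm_by_status = strat(tm, mean),
    duplicate_fraction_by_status = dup
  )
  structure(out, class = "library_summary")
}

#' @export
print.library_summary <- function(x, ...) {
  cat(sprintf("<library_summary> %s\n", x$library_id))
  cat(sprintf("  collapsed reads: %d", x$n_collapsed))
  if (!is.null(x$pct_collapsed)) {
    cat(sprintf(" (%.1f%% of %d pairs)", x$pct_collapsed,
                x$n_pairs_untrimmed))
  }
  cat("\n")
  cat(sprintf("  mean length %.1f bp, GC %.1f%%\n", x$mean_length,
              x$gc_pct))
  cat(sprintf("  interrupted palindrome content: %.2f%%\n",
              x$palindrome_content_pct))
  s <- function(v) sprintf("%.2f (palindrome) vs %.2f (clean)",
                           v[["palindrome"]], v[["clean"]])
  cat("  mean length by status: ", s(x$mean_length_by_status), "\n",
      "  GC% by status:          ", s(x$gc_pct_by_status), "\n",
      "  mean Tm by status:     ", s(x$mean_tm_by_status), "\n",
      "  dup fraction by status:", s(x$duplicate_fraction_by_status), "\n",
      sep = "")
  invisible(x)
}

#' Write per-read palindrome calls to TSV
#'
#' One row per read: id, length, palindrome length, clip decision, clip
#' length, GC and melting temperature.
#'
#' @param reads read-set tibble.
#' @param path output TSV path.
#' @param min_clip clip threshold passed to [detect_palindromes()].
#' @return The calls tibble, invisibly.
#' @export
write_palindrome_tsv <- function(reads, path, min_clip = 4L) {
  reads <- assert_read_set(reads)
  calls <- detect_palindromes(reads, min_clip)
  calls$gc <- gc_content(reads$sequence)
  calls$tm <- suppressWarnings(melting_temperature(reads$sequence))
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(calls)
}
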