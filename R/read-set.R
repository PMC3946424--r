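#' Construct a read set
#'
#' A read set is the package's unit of FASTQ-like data: a tibble with one
#' row per read and columns `id`, `sequence` (uppercase DNA over
#' `{A,C,G,T,N}`) and `quality` (Phred+33 encoded string of the same length
#' as the sequence, or `NA` when qualities are unavailable).  All exported
#' functions that take "reads" accept this tibble.
#'
#' @param sequence character vector of DNA sequences.
#' @param id read identifiers; defaults to `read_1 ... read_n`.
#' @param quality optional character vector of Phred+33 quality strings.
#' @return A tibble with columns `id`, `sequence`, `quality`.
#' @examples
#' read_set(c("ACGT", "GGGA"))
#' @export
read_set <- function(sequence, id = NULL, quality = NULL) {
  sequence <- check_dna(sequence, arg = "sequence")
  n <- length(sequence)
  if (is.null(id)) id <- sprintf("read_%d", seq_len(n))
  if (is.null(quality)) quality <- rep(NA_character_, n)
  if (length(id) != n || length(quality) != n) {
    stop("`id` and `quality` must have the same length as `sequence`")
  }
  has_q <- !is.na(quality)
  if (any(nchar(quality[has_q]) != nchar(sequence[has_q]))) {
    stop("quality strings must have the same length as their sequences")
  }
  tibble::tibble(id = as.character(id), sequence = sequence,
                 quality = as.character(quality))
}

assert_read_set <- function(reads, arg = "reads") {
  if (!is.data.frame(reads) ||
      !all(c("id", "sequence") %in% names(reads))) {
    stop("`", arg, "` must be a read-set tibble with columns ",
         "id, sequence[, quality]; see read_set()")
  }
  if (is.null(reads$quality)) reads$quality <- NA_character_
  tibble::as_tibble(reads)
}

#' Read a FASTQ file into a read set
#'
#' Four-line FASTQ records (optionally gzip-compressed) are parsed with
#' Biostrings; qualities are kept as Phred+33 strings.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @return A read-set tibble (see [read_set()]).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  read_set(sequence = unname(as.character(x)),
           id = sub("\\s.*$", "", names(x)),
           quality = unname(as.character(q)))
}

#' Write a read set to FASTQ
#'
#' @param reads read-set tibble.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- assert_read_set(reads)
  q <- reads$quality
  # reads without qualities get a flat high-quality placeholder (Q40)
  miss <- is.na(q)
  q[miss] <- vapply(nchar(reads$sequence[miss]),
                    function(n) strrep("I", n), character(1))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(q),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
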