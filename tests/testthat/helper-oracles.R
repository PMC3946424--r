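# Shared helpers: random-sequence generation and independent oracles.
# Oracles are deliberately implemented by a different route than the
# package internals (string algebra via Biostrings / base R).

# n random DNA sequences with lengths `lens` (recycled), drawn from
# `alphabet` with probabilities `prob`.
random_dna <- function(n, lens, alphabet = c("A", "C", "G", "T"),
                       prob = NULL) {
  lens <- rep_len(lens, n)
  big <- paste(sample(alphabet, sum(lens), replace = TRUE, prob = prob),
               collapse = "")
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

# Brute-force terminal-palindrome oracle: the longest common suffix of the
# sequence and its reverse complement (with N made non-self-matching),
# capped at floor(n/2).  Equivalent to testing every k for "last k bases
# == revcomp(first k bases)".
brute_palindrome <- function(seqs) {
  rcx <- chartr("N", "X", as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs))))
  mapply(function(s, r) {
    a <- rev(charToRaw(s))
    b <- rev(charToRaw(r))
    bad <- which(a != b)
    min(length(a) %/% 2L, if (length(bad)) bad[1] - 1L else length(a))
  }, seqs, rcx, USE.NAMES = FALSE)
}

# Brute-force hairpin-stem oracle for short strands: enumerate every
# (i, j, m) and apply the selection rule smallest i, largest m, largest j.
brute_hairpin <- function(s, min_stem = 4L, max_fill = 20L, min_loop = 3L) {
  n <- nchar(s)
  best <- NULL
  for (i in 0:min(max_fill, n)) {
    for (m in min_stem:max(min_stem, (n - i - min_loop) %/% 2)) {
      if (i + 2 * m + min_loop > n) next
      top <- reverse_complement(substr(s, i + 1L, i + m))
      for (j in (i + m + min_loop):(n - m)) {
        if (substr(s, j + 1L, j + m) == top && !grepl("N", top)) {
          cand <- c(i = i, j = j, m = m)
          if (is.null(best) ||
              cand["i"] < best["i"] ||
              (cand["i"] == best["i"] && cand["m"] > best["m"]) ||
              (cand["i"] == best["i"] && cand["m"] == best["m"] &&
                 cand["j"] > best["j"])) {
            best <- cand
          }
        }
      }
    }
  }
  best
}

# Brute-force ungapped mapping oracle: score every placement on both
# strands in R; mapped iff the best mismatch fraction passes and is
# uniquely achieved.
brute_map <- function(read, genome, max_frac = 0.03) {
  G <- nchar(genome)
  len <- nchar(read)
  if (len == 0 || len > G) return(list(mapped = FALSE))
  gb <- strsplit(genome, "")[[1]]
  score <- function(q) {
    qb <- strsplit(q, "")[[1]]
    vapply(0:(G - len), function(p) sum(qb != gb[(p + 1):(p + len)]),
           integer(1))
  }
  mp <- score(read)
  mr <- score(reverse_complement(read))
  allmm <- c(mp, mr)
  bmm <- min(allmm)
  nbest <- sum(allmm == bmm)
  if (bmm > floor(max_frac * len + 1e-9) || nbest != 1) {
    return(list(mapped = FALSE, mismatches = bmm, nbest = nbest))
  }
  if (which.min(allmm) <= length(mp)) {
    list(mapped = TRUE, pos = which.min(mp) - 1L, strand = "+",
         mismatches = bmm)
  } else {
    list(mapped = TRUE, pos = which.min(mr) - 1L, strand = "-",
         mismatches = bmm)
  }
}

# Error-free read pair from a fragment: forward read and reverse read of
# `read_len` bases (whole fragment when shorter), no adapters.
fragment_pair <- function(frag, read_len = 100L) {
  len <- nchar(frag)
  list(r1 = substr(frag, 1L, min(len, read_len)),
       r2 = reverse_complement(substr(frag, max(1L, len - read_len + 1L),
                                      len)))
}
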