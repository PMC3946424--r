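#' Standard read-through adapter pair
#'
#' The adapter sequences that appear at the 3' end of short-insert reads:
#' read 1 runs into the P7-side adapter, read 2 into the P5-side adapter.
#' Used as defaults by [sequence_library()] and for trimming simulated
#' reads.
#'
#' @return Named list with elements `p7` and `p5`.
#' @export
illumina_adapters <- function() {
  list(p7 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
       p5 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA")
}

#' Generate a synthetic genome
#'
#' I.i.d. bases with `P(G) = P(C) = gc_target / 2` and
#' `P(A) = P(T) = (1 - gc_target) / 2`, reproducible under `seed`.
#'
#' @param length genome length in bases (at least 1000).
#' @param gc_target target GC fraction, strictly inside (0, 1).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `synthetic_genome` holding `sequence`,
#'   `gc_target` and `seed`.
#' @export
generate_genome <- function(length, gc_target = 0.40, seed = NULL) {
  stopifnot(length >= 1000)
  if (!is.numeric(gc_target) || gc_target <= 0 || gc_target >= 1) {
    stop("`gc_target` must lie strictly inside (0, 1)")
  }
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  seq <- with_seed(seed, paste(
    sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
  structure(list(sequence = seq, gc_target = gc_target, seed = seed,
                 length = as.integer(length)),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d bp, target GC %.2f, observed GC %.3f\n",
              x$length, x$gc_target, gc_content(x$sequence)))
  invisible(x)
}

as_genome_sequence <- function(genome) {
  if (inherits(genome, "synthetic_genome")) return(genome$sequence)
  check_dna(genome, allow_empty = FALSE, arg = "genome")
}

#' Draw degraded-DNA fragments from a genome
#'
#' Fragment lengths follow a log-normal with the given mean and shape
#' (`sdlog`), truncated to `[20, genome length]`, mimicking the short
#' length distribution of historic/ancient extracts; start positions and
#' strands are uniform.
#'
#' @param genome a [generate_genome()] object or DNA string.
#' @param n number of fragments.
#' @param mean_len mean fragment length in bases (at least 20).
#' @param shape log-normal `sdlog`.
#' @param seed integer seed.
#' @return Tibble with columns `start`, `end` (0-based half-open, + strand
#'   coordinates), `strand`, `length`, `sequence` (reverse-complemented on
#'   `-`), `tm` (degrees Celsius).
#' @export
draw_fragments <- function(genome, n, mean_len = 70, shape = 0.35,
                           seed = NULL) {
  gseq <- as_genome_sequence(genome)
  G <- nchar(gseq)
  stopifnot(mean_len >= 20, n >= 0)
  if (n == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), length = integer(),
                          sequence = character(), tm = numeric()))
  }
  with_seed(seed, {
    meanlog <- log(mean_len) - shape^2 / 2
    len <- pmin(pmax(as.integer(round(rlnorm(n, meanlog, shape))), 20L), G)
    start <- vapply(G - len, function(m) sample.int(m + 1L, 1L) - 1L,
                    integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seq <- substr(rep(gseq, n), start + 1L, start + len)
    seq[strand == "-"] <- reverse_complement(seq[strand == "-"])
    tibble::tibble(start = start, end = start + len, strand = strand,
                   length = len, sequence = seq,
                   tm = melting_temperature(seq))
  })
}

#' Apply terminal cytosine deamination damage
#'
#' Each C at 5' position `p` (0-based) flips to T with probability
#' `rate_5prime * decay_per_base^p`; G flips to A with the mirrored
#' probability from the 3' end.  This emulates the elevated C-to-T /
#' G-to-A substitution rates at fragment ends of ancient DNA.
#'
#' @param fragments fragment tibble from [draw_fragments()] or a character
#'   vector of sequences.
#' @param rate_5prime terminal flip probability, in `[0, 1]`.
#' @param decay_per_base per-base geometric decay of the rate, in `[0, 1]`.
#' @param seed integer seed.
#' @return The input with mutated sequences (and, for fragment tibbles,
#'   recomputed `tm`).
#' @export
apply_deamination <- function(fragments, rate_5prime = 0.02,
                              decay_per_base = 0.5, seed = NULL) {
  stopifnot(rate_5prime >= 0, rate_5prime <= 1,
            decay_per_base >= 0, decay_per_base <= 1)
  is_df <- is.data.frame(fragments)
  seqs <- if (is_df) fragments$sequence else check_dna(fragments)
  out <- with_seed(seed, vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(b)
    if (n == 0) return(s)
    p5 <- rate_5prime * decay_per_base^(seq_len(n) - 1)
    p3 <- rev(p5)
    hitC <- b == "C" & runif(n) < p5
    hitG <- b == "G" & runif(n) < p3
    b[hitC] <- "T"
    b[hitG] <- "A"
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE))
  if (is_df) {
    fragments$sequence <- out
    fragments$tm <- melting_temperature(out)
    fragments
  } else {
    out
  }
}

#' Library-preparation protocol
#'
#' Bundles the protocol features that govern hairpin-artifact formation:
#' the adapter scheme (only forked adapters can ligate onto a hairpin-loop
#' stem and make it amplifiable), the hottest temperature the template
#' sees before ligation (A-tailing step and optional post-A-tailing
#' inactivation hold), a logistic model of strand denaturation around the
#' fragment melting temperature, the stem-search bounds, and PCR settings.
#'
#' Presets: `"forked_AT"` mirrors a TruSeq-like protocol (37 degC
#' A-tailing, 70 degC inactivation hold, forked adapters); `"blunt"` a
#' blunt-end ligation protocol without forked adapters; and
#' `"stem_loop_blunt"` a Microplex-like single-tube protocol (no step
#' above 55 degC, stem-loop adapters ligated blunt).
#'
#' @param name preset name: `"forked_AT"`, `"blunt"` or
#'   `"stem_loop_blunt"`.
#' @param ... preset fields to override, e.g. `pcr_cycles = 10`,
#'   `denature_prob = 1` (a numeric `denature_prob` fixes the denaturation
#'   probability; `NA`, the default, couples it to the fragment Tm).
#' @return A list of class `library_protocol`.
#' @section Fields:
#' \describe{
#'   \item{adapter_scheme}{`forked_AT`, `blunt` or `stem_loop_blunt`.}
#'   \item{atail_temp, post_atail_hold}{step temperatures, degC (0 = no
#'     hold); their maximum is the denaturation-relevant temperature.}
#'   \item{ligation_temp}{degC at which the hairpin stem must survive.}
#'   \item{denature_midpoint_offset, denature_slope}{logistic
#'     denaturation: `plogis((step - tm - offset) * slope)`.}
#'   \item{denature_prob}{fixed denaturation probability, or `NA` for the
#'     Tm-coupled logistic.}
#'   \item{hairpin_stability_bonus}{degC added to the Wallace-rule stem Tm
#'     to reflect the intramolecular stability of a loop-closed stem.}
#'   \item{min_stem, max_fill, min_loop}{stem-search bounds (bases).}
#'   \item{pcr_cycles, length_bias_strength}{PCR duplication intensity and
#'     the strength of its preference for short, AT-rich templates.}
#'   \item{error_rate}{default sequencing substitution rate per base.}
#' }
#' @export
library_protocol <- function(name = c("forked_AT", "blunt",
                                      "stem_loop_blunt"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    adapter_scheme = name,
    atail_temp = 37,
    post_atail_hold = 0,
    ligation_temp = 30,
    denature_midpoint_offset = -2,
    denature_slope = 0.5,
    denature_prob = NA_real_,
    hairpin_stability_bonus = 20,
    min_stem = 4L,
    max_fill = 20L,
    min_loop = 3L,
    pcr_cycles = 14L,
    length_bias_strength = 6,
    error_rate = 0.001
  )
  preset <- switch(name,
    forked_AT = list(post_atail_hold = 70, pcr_cycles = 18L),
    blunt = list(atail_temp = 25, ligation_temp = 25),
    stem_loop_blunt = list(atail_temp = 37, ligation_temp = 25)
  )
  base[names(preset)] <- preset
  override <- list(...)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown)) stop("unknown protocol fields: ",
                            paste(unknown, collapse = ", "))
  base[names(override)] <- override
  stopifnot(base$min_stem >= 1, base$max_fill >= 0, base$min_loop >= 0,
            base$pcr_cycles >= 0, base$error_rate >= 0,
            is.na(base$denature_prob) ||
              (base$denature_prob >= 0 && base$denature_prob <= 1))
  structure(base, class = "library_protocol")
}

#' @export
print.library_protocol <- function(x, ...) {
  cat(sprintf(paste0(
    "<library_protocol> %s (%s adapters)\n",
    "  temps: A-tail %g degC, hold %g degC, ligation %g degC\n",
    "  denaturation: %s\n",
    "  stem search: min_stem %d, max_fill %d, min_loop %d\n",
    "  PCR: %d cycles, length bias %g; error rate %g\n"),
    x$name, x$adapter_scheme, x$atail_temp, x$post_atail_hold,
    x$ligation_temp,
    if (is.na(x$denature_prob))
      sprintf("logistic((T - Tm - %g) * %g)", x$denature_midpoint_offset,
              x$denature_slope)
    else sprintf("fixed p = %g", x$denature_prob),
    x$min_stem, x$max_fill, x$min_loop, x$pcr_cycles,
    x$length_bias_strength, x$error_rate))
  invisible(x)
}

#' Probability that a fragment denatures at a given step temperature
#'
#' Logistic in the gap between step temperature and fragment melting
#' temperature: `plogis((step_temp - tm - offset) * slope)`.  Monotone
#' increasing in `step_temp` and decreasing in `tm`, so short, AT-rich
#' fragments denature preferentially.  A protocol with a fixed
#' `denature_prob` returns that value.
#'
#' @param tm fragment melting temperature(s), degC.
#' @param step_temp step temperature, degC.
#' @param protocol a [library_protocol()].
#' @return Probability vector in `[0, 1]`.
#' @export
denature_probability <- function(tm, step_temp,
                                 protocol = library_protocol("forked_AT")) {
  stopifnot(inherits(protocol, "library_protocol"))
  if (!is.na(protocol$denature_prob)) {
    return(rep(protocol$denature_prob, length(tm)))
  }
  plogis((step_temp - tm - protocol$denature_midpoint_offset) *
           protocol$denature_slope)
}

#' Find a hairpin stem in a single strand
#'
#' Searches for 0-based `(i, j, m)` with fill `i <= max_fill`, stem length
#' `m >= min_stem`, a loop of at least `min_loop` bases between the two
#' stem halves, and `strand[j..j+m-1]` equal to the reverse complement of
#' `strand[i..i+m-1]` — i.e. a 3'-proximal region annealed back onto a
#' 5'-proximal region.  Selection among candidates: smallest `i`, then
#' largest `m`, then largest `j`.
#'
#' @param strand single DNA string.
#' @param min_stem minimum stem length (bases).
#' @param max_fill maximum 5' offset `i` of the stem (bases); this becomes
#'   the fill-in length of the artifact.
#' @param min_loop minimum unpaired loop length (bases).
#' @return Named integer vector `c(i, j, m)`, or `NULL` when no stem
#'   exists.
#' @examples
#' find_hairpin("TTACGAAAAATCGT", min_stem = 4)  # i = 2, j = 10, m = 4
#' @export
find_hairpin <- function(strand, min_stem = 4L, max_fill = 20L,
                         min_loop = 3L) {
  strand <- check_dna(strand, arg = "strand")
  if (length(strand) != 1) stop("`strand` must be a single sequence")
  stopifnot(min_stem >= 1)
  hit <- cpp_find_hairpin(strand, as.integer(min_stem),
                          as.integer(max_fill), as.integer(min_loop))
  if (hit[1] < 0) return(NULL)
  setNames(hit, c("i", "j", "m"))
}

#' Form the interrupted-palindrome artifact from a hairpin
#'
#' Models the enzymatic resolution of a hairpin loop: the unannealed 3'
#' tail beyond the stem is chewed back by 3'-to-5' exonuclease activity,
#' then the recessed 3' end is filled in by polymerase using the 5' end of
#' the same strand as template.  The product is
#' `strand[0..j+m-1] + revcomp(strand[0..i-1])` (0-based), whose terminal
#' palindrome length is guaranteed to be at least `i + m`: the stem
#' section (`m` bases) is genomic, the fill-in (`i` bases) artificial.
#'
#' @param strand single DNA string.
#' @param i,j,m a valid stem triple as returned by [find_hairpin()].
#' @param min_loop minimum loop length used for validation.
#' @return The artifact molecule (DNA string).
#' @examples
#' form_artifact("TTACGAAAAATCGT", 2, 10, 4)  # "TTACGAAAAATCGTAA"
#' @export
form_artifact <- function(strand, i, j, m, min_loop = 3L) {
  strand <- check_dna(strand, arg = "strand")
  if (length(strand) != 1) stop("`strand` must be a single sequence")
  n <- nchar(strand)
  i <- as.integer(i); j <- as.integer(j); m <- as.integer(m)
  if (i < 0 || m < 1 || j < i + m + min_loop || j + m > n) {
    stop("invalid stem triple (i, j, m) for this strand")
  }
  stem5 <- substr(strand, i + 1L, i + m)
  stem3 <- substr(strand, j + 1L, j + m)
  if (stem3 != reverse_complement(stem5) || grepl("N", stem5)) {
    stop("stem sections are not reverse complementary")
  }
  fill <- if (i > 0) reverse_complement(substr(strand, 1L, i)) else ""
  paste0(substr(strand, 1L, j + m), fill)
}

# Wallace-rule stem melting temperature, 2(A+T) + 4(G+C); used for stems
# of at most 13 bp.  Longer stems fall back to the basic formula.
stem_tm <- function(seq) {
  n <- nchar(seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  ifelse(n <= 13, 2 * (n - gc) + 4 * gc, 64.9 + 41 * (gc - 16.4) / n)
}

#' Build a sequencing library from fragments under a protocol
#'
#' Per fragment: (1) the strand denatures into ssDNA with
#' [denature_probability()] at the hottest pre-ligation step
#' (`max(atail_temp, post_atail_hold)`); (2) a denatured strand that forms
#' a hairpin ([find_hairpin()]) whose stem is stable at the ligation
#' temperature (Wallace-rule stem Tm plus the intramolecular stability
#' bonus at least `ligation_temp`) is resolved into an artifact molecule
#' ([form_artifact()]); (3) a molecule is amplifiable iff it stayed
#' double-stranded, or it is a hairpin under the `forked_AT` adapter
#' scheme — only forked adapters ligate onto the hairpin stem, so under
#' `blunt` or `stem_loop_blunt` schemes hairpins (and all other ssDNA) are
#' dropped; (4) PCR duplication adds copies with a Poisson count whose
#' mean is a logistic function of molecule length and GC content,
#' favouring short, AT-rich templates when `length_bias_strength > 0`.
#'
#' @param fragments fragment tibble from [draw_fragments()].
#' @param protocol a [library_protocol()].
#' @param seed integer seed.
#' @return List with `molecules` (tibble `molecule_id`, `sequence`,
#'   `length`) and `truths` (per-molecule ground truth: fragment
#'   coordinates, `is_artifact`, `fill_len`, `stem_len`, `artifact_len`,
#'   `duplicate_of`), row-aligned.
#' @export
build_library <- function(fragments, protocol, seed = NULL) {
  stopifnot(inherits(protocol, "library_protocol"))
  n <- nrow(fragments)
  with_seed(seed, {
    hot <- max(protocol$atail_temp, protocol$post_atail_hold)
    p_den <- denature_probability(fragments$tm, hot, protocol)
    denatured <- runif(n) < p_den

    seqs <- fragments$sequence
    mol_seq <- character(n)
    keep <- logical(n)
    is_artifact <- logical(n)
    fill_len <- integer(n)
    stem_len <- integer(n)
    for (k in seq_len(n)) {
      if (!denatured[k]) {            # stays dsDNA: always amplifiable
        mol_seq[k] <- seqs[k]
        keep[k] <- TRUE
        next
      }
      hit <- cpp_find_hairpin(seqs[k], protocol$min_stem,
                              protocol$max_fill, protocol$min_loop)
      if (hit[1] < 0) next            # ssDNA without a hairpin: lost
      stem <- substr(seqs[k], hit[1] + 1L, hit[1] + hit[3])
      if (stem_tm(stem) + protocol$hairpin_stability_bonus <
            protocol$ligation_temp) next  # stem melts before ligation
      if (protocol$adapter_scheme != "forked_AT") next  # no adapter fits
      mol_seq[k] <- form_artifact(seqs[k], hit[1], hit[2], hit[3],
                                  protocol$min_loop)
      keep[k] <- TRUE
      is_artifact[k] <- TRUE
      fill_len[k] <- hit[1]
      stem_len[k] <- hit[3]
    }

    idx <- which(keep)
    if (length(idx) == 0) {
      empty <- tibble::tibble(molecule_id = character(),
                              sequence = character(), length = integer())
      return(list(molecules = empty,
                  truths = tibble::tibble(molecule_id = character())))
    }
    mol_len <- nchar(mol_seq[idx])
    mol_gc <- ifelse(mol_len > 0, gc_content(mol_seq[idx]), 0)
    # PCR duplication: Poisson extra copies, logistic bias toward short,
    # AT-rich molecules.
    mu0 <- 0.04 * protocol$pcr_cycles
    z <- (median(mol_len) - mol_len) / median(mol_len) +
      (median(mol_gc) - mol_gc)
    mu <- mu0 * 2 * plogis(protocol$length_bias_strength * z)
    copies <- 1L + rpois(length(idx), mu)

    rep_idx <- rep(idx, copies)
    copy_no <- sequence(copies)
    orig_id <- sprintf("mol_%06d", rep_idx)
    mol_id <- ifelse(copy_no == 1L, orig_id,
                     sprintf("%s_dup%d", orig_id, copy_no - 1L))
    fl <- fill_len[rep_idx]
    sl <- stem_len[rep_idx]
    truths <- tibble::tibble(
      molecule_id = mol_id,
      frag_start = fragments$start[rep_idx],
      frag_end = fragments$end[rep_idx],
      strand = fragments$strand[rep_idx],
      is_artifact = is_artifact[rep_idx],
      fill_len = fl,
      stem_len = sl,
      artifact_len = fl + sl,
      duplicate_of = ifelse(copy_no == 1L, NA_character_, orig_id)
    )
    molecules <- tibble::tibble(
      molecule_id = mol_id,
      sequence = mol_seq[rep_idx],
      length = nchar(mol_seq[rep_idx])
    )
    list(molecules = molecules, truths = truths)
  })
}

#' Sequence a library into paired reads
#'
#' Read 1 is the first `read_len` bases of each molecule, running through
#' the P7-side adapter (and then padding N bases, emulating signal loss)
#' when the molecule is shorter than the read; read 2 likewise from the
#' reverse complement with the P5-side adapter.  Substitution errors are
#' i.i.d. at `error_rate` over template and adapter bases; qualities are
#' drawn from a fixed high-quality profile (Q35-Q40), with Q2 on padding.
#'
#' @param molecules molecule tibble from [build_library()] (or the list it
#'   returns).
#' @param read_len read length in bases.
#' @param error_rate per-base substitution probability.
#' @param adapters list with `p7` and `p5` adapter strings.
#' @param seed integer seed.
#' @return List with read sets `r1` and `r2` (ids = molecule ids) and, if
#'   available, the pass-through `truths` tibble.
#' @export
sequence_library <- function(molecules, read_len = 100L, error_rate = 0.001,
                             adapters = illumina_adapters(), seed = NULL) {
  truths <- NULL
  if (is.list(molecules) && !is.data.frame(molecules) &&
      !is.null(molecules$molecules)) {
    truths <- molecules$truths
    molecules <- molecules$molecules
  }
  stopifnot(is.data.frame(molecules), read_len >= 1, error_rate >= 0,
            error_rate <= 1)
  with_seed(seed, {
    r1 <- synth_reads(molecules$sequence, read_len, error_rate, adapters$p7)
    r2 <- synth_reads(reverse_complement(molecules$sequence), read_len,
                      error_rate, adapters$p5)
    out <- list(
      r1 = read_set(r1$seq, id = molecules$molecule_id, quality = r1$qual),
      r2 = read_set(r2$seq, id = molecules$molecule_id, quality = r2$qual)
    )
    if (!is.null(truths)) out$truths <- truths
    out
  })
}

# One mate for every template: template + adapter read-through + N
# padding, truncated to read_len, with iid substitution errors on called
# bases.  Uses the active RNG stream.
synth_reads <- function(templates, read_len, error_rate, adapter) {
  n <- length(templates)
  called <- pmin(nchar(templates) + nchar(adapter), read_len)
  full <- substr(paste0(templates, adapter), 1L, read_len)
  seqs <- vapply(seq_len(n), function(k) {
    paste0(full[k], strrep("N", read_len - called[k]))
  }, character(1))
  if (error_rate > 0) {
    mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = read_len)
    callable <- row(mat) <= rep(called, each = read_len)
    hit <- callable & matrix(runif(n * read_len) < error_rate, nrow = read_len)
    if (any(hit)) {
      cur <- mat[hit]
      mat[hit] <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L),
                         character(1), USE.NAMES = FALSE)
    }
    seqs <- apply(mat, 2, paste, collapse = "")
  }
  quals <- vapply(seq_len(n), function(k) {
    q <- sample(35:40, called[k], replace = TRUE)
    paste0(intToUtf8(q + 33L, multiple = FALSE),
           strrep("#", read_len - called[k]))
  }, character(1))
  list(seq = seqs, qual = quals)
}

#' Simulate a complete library end to end
#'
#' Convenience wrapper: genome, fragments, optional deamination, library
#' construction and paired-read sequencing under a single seed.
#'
#' @param n_fragments number of template fragments.
#' @param protocol a [library_protocol()].
#' @param genome optional pre-built genome; built from `genome_length` /
#'   `gc_target` when `NULL`.
#' @param genome_length,gc_target genome parameters when `genome` is NULL.
#' @param mean_len,shape fragment length distribution.
#' @param deamination_rate 5'-terminal C-to-T rate (0 disables damage).
#' @param read_len,error_rate sequencing parameters; `error_rate = NULL`
#'   uses the protocol default.
#' @param seed integer seed driving every random step.
#' @return List with `genome`, `fragments`, `molecules`, `truths`, `r1`,
#'   `r2` and the `protocol` used.
#' @export
simulate_library <- function(n_fragments = 5000, protocol =
                               library_protocol("forked_AT"),
                             genome = NULL, genome_length = 50000,
                             gc_target = 0.40, mean_len = 70, shape = 0.35,
                             deamination_rate = 0, read_len = 100L,
                             error_rate = NULL, seed = 1L) {
  with_seed(seed, {
    if (is.null(genome)) genome <- generate_genome(genome_length, gc_target)
    fragments <- draw_fragments(genome, n_fragments, mean_len, shape)
    if (deamination_rate > 0) {
      fragments <- apply_deamination(fragments, deamination_rate)
    }
    lib <- build_library(fragments, protocol)
    if (is.null(error_rate)) error_rate <- protocol$error_rate
    reads <- sequence_library(lib, read_len = read_len,
                              error_rate = error_rate)
    list(genome = genome, fragments = fragments,
         molecules = lib$molecules, truths = lib$truths,
         r1 = reads$r1, r2 = reads$r2, protocol = protocol)
  })
}

#' Trim and collapse the paired reads of a simulated library
#'
#' Trims the mate-specific read-through adapters and collapses each pair;
#' the collapsed read inherits its molecule id, so ground truth can be
#' joined back by `molecule_id`.
#'
#' @param sim result of [simulate_library()] (or any list with `r1`,
#'   `r2`).
#' @param params a [collapse_params()] object.
#' @param adapters adapter pair used during sequencing.
#' @return Read-set tibble of collapsed reads (rejected pairs dropped).
#' @export
collapse_library <- function(sim, params = collapse_params(),
                             adapters = illumina_adapters()) {
  r1 <- trim_adapter(sim$r1, adapters$p7, params$max_mismatch_rate,
                     params$trim_ns)
  r2 <- trim_adapter(sim$r2, adapters$p5, params$max_mismatch_rate,
                     params$trim_ns)
  ok <- nzchar(r1$sequence) & nzchar(r2$sequence)
  merged <- collapse_pairs(r1[ok, ], r2[ok, ], params)
  merged <- merged[merged$collapsed, c("id", "sequence", "quality")]
  tibble::as_tibble(merged)
}
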