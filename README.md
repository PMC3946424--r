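# palinclip

Detection, clipping and mechanistic simulation of **3′-terminal
interrupted-palindrome artifacts** in sequencing reads from degraded
(historic or ancient) DNA.

## The problem

Libraries built from highly fragmented DNA with certain protocols — low
enzymatic step temperatures, a hot post-A-tailing hold, and **forked
(Y-shaped) adapters** — can contain reads whose last bases are a perfect
reverse complement of their first bases, separated by ordinary sequence: an
*interrupted palindrome*. The 5′ section and the inner part of the 3′
palindrome are genomic; only the outermost 3′ bases are artificial. The
mechanism is a hairpin loop in single-stranded DNA: a short natural inverted
repeat anneals the 3′ region back onto the 5′ region, 3′→5′ exonucleases
chew back any unannealed tail, and a polymerase fills in the recessed 3′
end using the 5′ end of the *same strand* as template. Forked adapters can
ligate onto the double-stranded stem, so the construct amplifies. The
artificial 3′ bases inflate mismatch rates, and mismatch-bounded aligners
drop the reads — the artifact silently suppresses the yield of endogenous
DNA.

For a read of length *n*, the detector reports

```
L = max { k ≤ ⌊n/2⌋ :  read[n−k+1 … n] = revcomp(read[1 … k]) }
```

i.e. the count of consecutive complementary end pairs, stopping at the
first non-complementary pair (N never pairs). Reads with `L ≥ 4`
(palindromes *longer than three base pairs*, against a chance background of
(1/4)⁴ ≈ 0.39 %) are flagged, and clipping removes the last `L` bases —
never touching the 5′ end. Melting temperatures use the salt-unadjusted
basic formula `Tm = 64.9 + 41·(GC − 16.4)/n` (Wallace rule `2(A+T)+4(G+C)`
below 14 bp).

The package also provides:

* an overlap **collapser** for short-insert read pairs (minimum overlap 11,
  mismatch rate ≤ 0.33, minimum length 25, N-trimming — the classic
  settings for degraded DNA), with best-score placement and max-quality
  merging;
* a generative **hairpin simulator**: synthetic genome → log-normal
  fragments → Tm-coupled logistic denaturation → stem search
  (fill `i`, stem `m`, loop ≥ 3) → chew-back + fill-in → adapter-scheme
  gating (forked vs blunt vs stem-loop) → length/GC-biased PCR duplication
  → paired 100 bp reads with per-molecule ground truth;
* a small exhaustive **mapper** (ungapped, both strands, mismatch fraction
  ≤ 0.03, unique-best rule) and a per-position substitution profiler
  (C→T / G→A / other by read-end offset) to reproduce the alignment-gain
  and damage-pattern diagnostics on synthetic data;
* library **summaries** (palindrome content, length histograms, GC / Tm /
  clonality stratified by palindrome status), FASTQ(.gz) I/O, subsampling,
  and a CLI (`inst/cli/palinclip`) with `simulate`, `collapse`, `detect`,
  `clip`, `stats` and `subsample` subcommands.

## Worked example

```r
library(palinclip)

# the canonical hairpin: fill i = 2, stem m = 4, loop of 4
find_hairpin("TTACGAAAAATCGT", min_stem = 4)
#>  i  j  m
#>  2 10  4
form_artifact("TTACGAAAAATCGT", 2, 10, 4)
#> [1] "TTACGAAAAATCGTAA"        # terminal palindrome length 6 = i + m

# simulate a forked-adapter library, merge pairs, summarize
sim   <- simulate_library(2000, library_protocol("forked_AT"), seed = 42)
reads <- collapse_library(sim)
summarize_library(reads, untrimmed_pair_count = nrow(sim$r1),
                  library_id = "forked_AT demo")
#> <library_summary> forked_AT demo
#>   collapsed reads: 2580 (90.0% of 2866 pairs)
#>   mean length 59.3 bp, GC 40.2%
#>   interrupted palindrome content: 56.71%
#>   mean length by status: 44.51 (palindrome) vs 78.60 (clean)
#>   GC% by status:          38.32 (palindrome) vs 42.72 (clean)
#>   mean Tm by status:     64.05 (palindrome) vs 73.03 (clean)
#>   dup fraction by status:0.48 (palindrome) vs 0.21 (clean)

clip <- clip_palindrome(reads)                   # 1463 of 2580 reads clipped
alignability(reads, sim$genome)$n_mapped         #> 1555
alignability(clip$reads, sim$genome)$n_mapped    #> 2549
```

More than half of the simulated forked-adapter reads carry a palindrome
longer than 3 bp; palindrome-bearing reads are shorter, AT-richer, lower in
melting temperature and more clonal than clean reads; and clipping the
3′ palindrome recovers most of the alignment loss (1555 → 2549 mapped reads
here). Under the blunt or stem-loop protocols the hairpin constructs cannot
ligate, and the palindrome content collapses to the ≈ 0.4 % chance
background.

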