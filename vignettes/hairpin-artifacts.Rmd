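---
title: "Interrupted palindromes from hairpin loops: model, detector and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrupted palindromes from hairpin loops: model, detector and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palinclip)
```

## The artifact and its detector

Degraded-DNA sequencing reads can end in a perfect reverse complement of
their own beginning — an *interrupted palindrome*. The anatomy matters: the
5′ section and the inner part of the 3′ palindrome are genuine genomic
sequence (they align to a reference), while the outermost 3′ bases are an
artificial polymerase fill-in. The generating mechanism is a hairpin loop in
single-stranded DNA (ssDNA): a naturally occurring short inverted repeat
lets the molecule fold back on itself, a 3′→5′ exonuclease removes any
unannealed 3′ tail, and a polymerase extends the recessed 3′ end using the
5′ end of the same strand as template. If the library's adapters can ligate
onto the resulting double-stranded stem — which forked (Y-shaped) adapter
schemes can, and blunt-end schemes cannot — the construct amplifies and is
sequenced.

For a read of length $n$ the detector reports

$$L \;=\; \max\{\,k \le \lfloor n/2\rfloor :
  \text{read}[n-k+1..n] = \operatorname{revcomp}(\text{read}[1..k])\,\}.$$

Because a suffix match at $k$ implies a match at every $k' < k$, $L$ equals
the count of consecutive complementary outside-in end pairs, which is how
the compiled scanner computes it. Three conventions, all deliberate:

* **Cap at $\lfloor n/2\rfloor$.** A palindrome "at both ends" presupposes
  two disjoint sections; without the cap a fully self-complementary read
  would let the sections overlap.
* **N never pairs.** Uncalled bases would otherwise inflate artifact calls
  exactly where base calling is least trustworthy.
* **Single-pass clipping.** `clip_palindrome()` removes the last $L$ bases
  (and their qualities) once, only when $L \ge$ `min_clip` (default 4,
  i.e. palindromes *longer than three* base pairs), and never touches the
  5′ end. Iterating the clip would conflate chance re-detection with the
  mechanism; instead the per-read call table carries a `residual` flag for
  reads whose re-detected $L$ is still above threshold.

Against i.i.d. uniform bases, $P(L \ge 4) = (1/4)^4 \approx 0.39\%$; that
analytic background is what the blunt-scheme simulations and the reporting
threshold are judged against.

Melting temperature uses the salt-unadjusted basic formula
$T_m = 64.9 + 41\,(GC - 16.4)/n$ for $n > 13$; for 13 bp and shorter the
Wallace rule $2(A{+}T) + 4(G{+}C)$ is used with a warning, since the basic
formula is not calibrated there. GC content counts N in the denominator
(a read's GC is relative to its full length). The duplicate fraction is
$(\text{reads} - \text{distinct sequences})/\text{reads}$ — a
sequence-identity surrogate for alignment-based duplicate marking that
needs no reference and is exactly reproducible.

## Pair collapsing

Short fragments are read through by both mates, so the forward read and the
reverse complement of the reverse read are slid against each other over all
offsets. The accepted placement maximizes the identity score
(matches − mismatches), with ties going to the longer overlap and then the
smaller offset. We deliberately do **not** use "fewest mismatches" as the
primary key: a chance one-base overlap with zero mismatches would then
always defeat a long true overlap carrying a single sequencing error, and
no merged read could ever contain a corrected disagreement. A pair is
collapsed iff the best overlap spans ≥ `min_overlap` (11) bases with a
mismatch fraction ≤ `max_mismatch_rate` (0.33) and the merged product is
≥ `min_length` (25) bases — the standard parameterization for degraded-DNA
merging. At a disagreement the higher-quality base wins (equal qualities:
forward; an N always loses to a called base), and the merged quality at
every position is the best available contributing score.

Adapter trimming removes the longest 3′ suffix matching a prefix of the
adapter in register at ≤ the mismatch rate. Terminal N runs are stripped
*before* that match (an uncalled tail would otherwise hide the adapter from
the suffix comparison) and again after it.

## The generative simulator

`simulate_library()` chains the steps a molecule experiences:

1. **Genome** — i.i.d. bases at a target GC (default 0.40, matching the
   35–45 % range typical of the motivating libraries); lengths of 10–50 kb
   keep the exhaustive mapper practical.
2. **Fragments** — log-normal lengths (mean 70 bp, `sdlog` 0.35, truncated
   at 20 bp), uniform start and strand: the short-fragment regime of
   historic extracts. Optional terminal deamination (C→T from the 5′ end,
   G→A mirrored at the 3′ end, geometrically decaying inward) is off by
   default and, when on, is applied before library construction — damage
   precedes preparation.
3. **Denaturation** — each fragment becomes ssDNA with probability
   $\operatorname{logistic}\big((T_{step} - T_m - \delta)\,s\big)$ at the
   hottest pre-ligation step (max of the A-tailing temperature and the
   post-A-tailing hold). Defaults $\delta = -2$ °C, $s = 0.5$ /°C were
   calibrated once so that the forked-adapter preset lands mid-way in the
   40–80 % artifact-content band and were not revisited. The `forked_AT`
   preset holds at 70 °C after 37 °C A-tailing; the blunt and
   stem-loop presets never exceed 37 °C, so almost nothing denatures.
   Setting `denature_prob` overrides the logistic with a fixed rate, which
   is how the rate-sweep experiments span 0–80 %.
4. **Hairpin** — the stem search returns the smallest fill $i \le$
   `max_fill` (20), then the longest stem $m \ge$ `min_stem` (4), then the
   most 3′-proximal partner $j$, requiring an unpaired loop of at least 3
   bases (a steric minimum). The artifact molecule is
   `strand[1..j+m] + revcomp(strand[1..i])`: chew-back of the tail beyond
   the stem, then fill-in of $i$ artificial bases. Its terminal palindrome
   is $\ge i + m$ by construction.
5. **Stem stability and ligation** — the stem must survive ligation:
   Wallace-rule stem $T_m$ plus a `hairpin_stability_bonus` (default
   +20 °C) must reach `ligation_temp` (default 30 °C). The spec of a
   hairpin's stability by an intermolecular duplex rule alone would forbid
   every short stem (a 4–6 bp Wallace $T_m$ is 8–24 °C); the bonus models
   the huge effective local concentration of a loop-closed stem while
   keeping a GC-dependent cutoff. Amplifiability then gates on the adapter
   scheme: double-stranded molecules always amplify; hairpins amplify only
   under `forked_AT`; all other ssDNA is lost.
6. **PCR** — extra copies per molecule are Poisson with mean
   $0.04 \cdot \text{cycles} \cdot 2\,\operatorname{logistic}(\beta z)$,
   where $z$ combines the molecule's relative length deficit and GC deficit
   against the library median and $\beta$ is `length_bias_strength`
   (default 6). Only the *direction* of the resulting clonality contrast is
   asserted anywhere; absolute fold enrichment is not a claim.
7. **Sequencing** — each mate is the first 100 bases of the (reverse
   complemented) molecule, running through the mate-specific adapter and
   then N padding when the template is exhausted (signal loss), with i.i.d.
   substitution errors on called bases and a fixed high-quality profile
   (Q35–40; Q2 on padding). The simulated molecule does not carry the
   single A-tail base: it matters for ligation chemistry but would break
   the terminal palindrome at the last base, contrary to the read-level
   artifact the mechanism produces.

Everything flows from one seed: identical configurations give identical
FASTQ bytes.

### What the simulator does *not* emulate

Indels and cycle-dependent error profiles; uracil-intolerant polymerase
chemistry; single-stranded library protocols; real-genome repeat structure
(genomes are i.i.d., so mapping ambiguity is rarer than in practice);
hairpin-formation kinetics and ligation efficiency (all such rates are
configurable knobs, not measured claims). Passing tests on these synthetic
libraries validates the *bookkeeping and the directions* of the protocol
contrasts, not field accuracy on real libraries.

## Toy mapper

The mapper scores every ungapped placement of a read on both strands of the
genome and keeps the best by mismatch count (ties: leftmost, + strand
first); a read maps iff its best mismatch fraction is ≤ 0.03 and the best
placement is unique at that count. Uniqueness stands in for a
mapping-quality floor; no quality model is attempted, and gaps are ignored
(fragments here are short and ungapped placements dominate). This is a
deliberate stand-in for a production aligner, usable only on small
synthetic genomes. The per-position substitution profiler orients the
reference slice to the read strand and reports C→T, G→A and "other" rates
for offsets 1–25 from each end — artificial 3′ fill-in shows up as an
"other" excess confined to the 3′ end, deamination as C→T at 5′ offsets
(G→A at 3′), which is how the two phenomena are told apart.

## Problem sizes and numerical choices

The test suite validates the detector against a brute-force oracle
(longest common suffix of the read and its reverse complement) on $10^5$
random reads of 2–200 bp, the chance background on $10^6$ uniform 70-mers
against the 99 % binomial interval around $(1/4)^4$, mechanism recovery on
$10^4$ fragments over a uniform 10 kb genome, scheme contrasts on 6 000
fragments per protocol, the collapse round trip on $10^4$ error-free pairs
from 25–189 bp fragments, and the alignment-gain linearity across nine
libraries spanning denaturation rates 0–0.8. Mismatch-rate comparisons use
a $10^{-9}$ slack against floating-point boundary cases; all tie-breaks
(stem selection, overlap placement, equal-quality bases, equal-mismatch
placements) are fixed and documented so every pipeline is byte-stable
under its seed.

Degenerate inputs: empty sequences yield $L = 0$ and are rejected where a
denominator is needed (GC, Tm, duplicate fraction, content); `gc_target`
must lie strictly inside (0, 1); reads longer than the genome are unmapped;
subsampling more reads than exist returns everything with a warning.

## Known limitations

* **Loop-boundary extension.** When the selected stem's loop is only 3–4
  bases, the two bases flanking the loop can be complementary by chance
  (probability ≈ 1/4), and the detector then reads a palindrome one base
  longer than the mechanistic fill + stem. For loops ≥ 5 the largest-stem
  selection rule makes such extension impossible (the longer stem would
  have been selected instead). Detected $L \ge i + m$ always holds;
  equality holds for the large majority of artifact reads but dips by a
  point or two depending on how many small-loop stems a particular genome
  yields.
* The duplicate-fraction surrogate counts only exact sequence identity, so
  it understates clonality relative to coordinate-based duplicate marking
  when sequencing errors are on.
* Chance palindromes among PCR duplicates are replicated with their
  molecule, so the blunt-scheme content clusters slightly above the i.i.d.
  binomial background even though its expectation is unchanged.
* The collapse acceptance threshold applies the 0.33 mismatch rate to the
  chosen overlap only; it does not model quality-weighted alignment scores.
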