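#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

// Watson-Crick complement; anything else (incl. N) has no complement.
static inline char wc_complement(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'T': return 'A';
    case 'C': return 'G';
    case 'G': return 'C';
    default:  return 0;
  }
}

static inline bool is_pair(char a, char b) {
  char c = wc_complement(a);
  return c != 0 && c == b;
}

// Length of the terminal interrupted palindrome: the count of consecutive
// end pairs (seq[t], seq[n-1-t]) that are Watson-Crick complementary,
// stopping at the first non-complementary pair or at floor(n/2).
// [[Rcpp::export]]
IntegerVector cpp_palindrome_length(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  IntegerVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    if (seqs[r] == NA_STRING) { out[r] = NA_INTEGER; continue; }
    const char *s = CHAR(STRING_ELT(seqs, r));
    int len = (int) LENGTH(STRING_ELT(seqs, r));
    int cap = len / 2, t = 0;
    while (t < cap && is_pair(s[t], s[len - 1 - t])) ++t;
    out[r] = t;
  }
  return out;
}

// Adapter trimming + optional N trimming.  If trim_ns, leading/trailing
// runs of N are stripped first (uncalled tails would otherwise hide the
// adapter from the in-register suffix match).  Then the longest remaining
// 3' suffix of length s <= min(read, adapter) whose per-base mismatch
// rate against the adapter prefix of the same length is
// <= max_mismatch_rate is removed, and any newly exposed N run stripped.
// Returns an n x 2 matrix of 0-based keep bounds [lo, hi).
// [[Rcpp::export]]
IntegerMatrix cpp_trim_bounds(CharacterVector seqs, std::string adapter,
                              double max_mismatch_rate, bool trim_ns) {
  R_xlen_t n = seqs.size();
  int alen = (int) adapter.size();
  IntegerMatrix out(n, 2);
  for (R_xlen_t r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int len = (int) LENGTH(STRING_ELT(seqs, r));
    int lo = 0, hi = len;
    if (trim_ns) {
      while (lo < hi && s[lo] == 'N') ++lo;
      while (hi > lo && s[hi - 1] == 'N') --hi;
    }
    int smax = std::min(hi - lo, alen);
    int trim = 0;
    for (int sl = smax; sl >= 1; --sl) {
      int mm = 0;
      int allowed = (int) std::floor(max_mismatch_rate * sl + 1e-9);
      bool ok = true;
      for (int t = 0; t < sl; ++t) {
        if (s[hi - sl + t] != adapter[t] && ++mm > allowed) { ok = false; break; }
      }
      if (ok) { trim = sl; break; }
    }
    hi -= trim;
    if (trim_ns) {
      while (hi > lo && s[hi - 1] == 'N') --hi;
    }
    out(r, 0) = lo;
    out(r, 1) = hi;
  }
  return out;
}

// Overlap-collapse paired reads.  Slides the reverse complement of the
// reverse read against the forward read over every offset, keeps the
// placement with the fewest mismatches (ties: longest overlap, then
// smallest offset), and merges when the overlap passes the thresholds.
// Disagreements take the higher-quality base (ties: forward; an N always
// loses to a called base); merged qualities are the best available score.
// Qualities are Phred+33 strings.
// [[Rcpp::export]]
List cpp_collapse_pairs(CharacterVector fwd, CharacterVector fwd_q,
                        CharacterVector rev, CharacterVector rev_q,
                        int min_overlap, double max_mismatch_rate,
                        int min_length) {
  R_xlen_t n = fwd.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector ok(n);
  IntegerVector best_overlap(n), best_mm(n);
  std::string rc, rq, seq, qual;
  for (R_xlen_t r = 0; r < n; ++r) {
    const char *f = CHAR(STRING_ELT(fwd, r));
    const char *fq = CHAR(STRING_ELT(fwd_q, r));
    const char *rv = CHAR(STRING_ELT(rev, r));
    const char *vq = CHAR(STRING_ELT(rev_q, r));
    int a = (int) LENGTH(STRING_ELT(fwd, r));
    int b = (int) LENGTH(STRING_ELT(rev, r));
    rc.assign(b, 'N'); rq.assign(b, '!');
    for (int t = 0; t < b; ++t) {
      char c = wc_complement(rv[b - 1 - t]);
      rc[t] = c ? c : 'N';
      rq[t] = vq[b - 1 - t];
    }
    // Best placement by identity score (matches - mismatches); ties go to
    // the longer overlap, then the smaller offset.  A pure fewest-mismatch
    // rule would let chance 1-base overlaps with zero mismatches defeat a
    // long true overlap carrying a sequencing error.
    int bmm = -1, bov = 0, bd = 0, bscore = INT_MIN;
    for (int d = -(b - 1); d <= a - 1; ++d) {
      int lo = std::max(0, d), hi = std::min(a, d + b);
      int ov = hi - lo;
      if (ov < 1) continue;
      int mm = 0;
      bool pruned = false;
      for (int p = lo; p < hi; ++p) {
        if (f[p] != rc[p - d] && (ov - 2 * ++mm) < bscore) {
          pruned = true; break;  // score can only fall as mismatches accrue
        }
      }
      if (pruned) continue;
      int score = ov - 2 * mm;
      if (score > bscore || (score == bscore && ov > bov)) {
        bscore = score; bmm = mm; bov = ov; bd = d;
      }
    }
    best_overlap[r] = bov; best_mm[r] = (bmm < 0) ? NA_INTEGER : bmm;
    bool accept = bmm >= 0 && bov >= min_overlap &&
                  (double) bmm <= max_mismatch_rate * bov + 1e-9;
    if (accept) {
      int lo = std::min(0, bd), hi = std::max(a, bd + b);
      int mlen = hi - lo;
      if (mlen < min_length) accept = false;
      if (accept) {
        seq.assign(mlen, 'N'); qual.assign(mlen, '!');
        for (int p = lo; p < hi; ++p) {
          bool inF = (p >= 0 && p < a);
          bool inR = (p >= bd && p < bd + b);
          char cf = inF ? f[p] : 0, qf = inF ? fq[p] : 0;
          char cr = inR ? rc[p - bd] : 0, qr = inR ? rq[p - bd] : 0;
          char cb, qb;
          if (inF && inR) {
            qb = std::max(qf, qr);
            if (cf == cr) cb = cf;
            else if (cf == 'N') cb = cr;
            else if (cr == 'N') cb = cf;
            else cb = (qr > qf) ? cr : cf;  // equal quality: forward wins
          } else if (inF) { cb = cf; qb = qf; }
          else { cb = cr; qb = qr; }
          seq[p - lo] = cb; qual[p - lo] = qb;
        }
        mseq[r] = seq; mqual[r] = qual;
      }
    }
    ok[r] = accept;
    if (!accept) { mseq[r] = NA_STRING; mqual[r] = NA_STRING; }
  }
  return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                      _["collapsed"] = ok, _["overlap"] = best_overlap,
                      _["mismatches"] = best_mm);
}

// Hairpin stem search on a single strand.  Finds 0-based (i, j, m) with
// i <= max_fill, m >= min_stem, loop >= min_loop (j >= i + m + min_loop),
// j + m <= n, and strand[j..j+m-1] == revcomp(strand[i..i+m-1]).
// Selection: smallest i, then largest m, then largest j.
// Returns c(i, j, m) or c(-1, -1, -1) if no stem exists.
// [[Rcpp::export]]
IntegerVector cpp_find_hairpin(std::string s, int min_stem, int max_fill,
                               int min_loop) {
  int n = (int) s.size();
  int imax = std::min(max_fill, n);
  for (int i = 0; i <= imax; ++i) {
    int mmax = (n - i - min_loop) / 2;
    for (int m = mmax; m >= min_stem; --m) {
      for (int j = n - m; j >= i + m + min_loop; --j) {
        bool hit = true;
        for (int t = 0; t < m; ++t) {
          if (!is_pair(s[i + m - 1 - t], s[j + t])) { hit = false; break; }
        }
        if (hit) return IntegerVector::create(i, j, m);
      }
    }
  }
  return IntegerVector::create(-1, -1, -1);
}

// Exhaustive ungapped placement of each read over both strands of a small
// genome.  Best placement = fewest mismatches; ties: leftmost position,
// then + strand.  Mapped iff mismatch count <= floor(max_mismatch_frac *
// read length) and the best placement is unique at that count.
// Strand: 1 = +, -1 = -; pos is 0-based on the + strand.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, std::string genome,
                   double max_mismatch_frac) {
  int G = (int) genome.size();
  R_xlen_t n = reads.size();
  LogicalVector mapped(n);
  IntegerVector pos(n), strand(n), mism(n);
  std::string rc;
  for (R_xlen_t r = 0; r < n; ++r) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    int len = (int) LENGTH(STRING_ELT(reads, r));
    mapped[r] = false; pos[r] = NA_INTEGER; strand[r] = NA_INTEGER;
    mism[r] = NA_INTEGER;
    if (len == 0 || len > G) continue;
    int allowed = (int) std::floor(max_mismatch_frac * len + 1e-9);
    rc.assign(len, 'N');
    for (int t = 0; t < len; ++t) {
      char c = wc_complement(rd[len - 1 - t]);
      rc[t] = c ? c : 'N';
    }
    int bmm = allowed + 1, bpos = -1, bstr = 0, nbest = 0;
    for (int st = 0; st < 2; ++st) {
      const char *q = (st == 0) ? rd : rc.c_str();
      for (int p = 0; p + len <= G; ++p) {
        int mm = 0;
        bool bad = false;
        for (int t = 0; t < len; ++t) {
          if (q[t] != genome[p + t] && ++mm > bmm) { bad = true; break; }
        }
        if (bad) continue;
        if (mm < bmm) { bmm = mm; bpos = p; bstr = st; nbest = 1; }
        else if (mm == bmm) ++nbest;  // first-seen (+, leftmost) retained
      }
    }
    if (bmm <= allowed && nbest == 1) {
      mapped[r] = true; pos[r] = bpos; strand[r] = bstr == 0 ? 1 : -1;
      mism[r] = bmm;
    }
  }
  return List::create(_["mapped"] = mapped, _["pos"] = pos,
                      _["strand"] = strand, _["mismatches"] = mism);
}
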