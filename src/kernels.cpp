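#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline char dna_comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'G': return 'C'; case 'C': return 'G';
    default:  return 'N';
  }
}

// Mismatch counts between the length-L prefix and length-L suffix of `seq`,
// for every L in [min_len, max_len].  End-anchored, substitutions only: the
// two copies of a direct terminal repeat arise by replication of identical
// ends, so no indels are modelled.  With inverted = true the suffix is
// reverse-complemented before comparison (inverted-repeat diagnosis mode).
// [[Rcpp::export]]
IntegerVector terminal_mismatch_scan(std::string seq, int min_len, int max_len,
                                     bool inverted = false) {
  int n = (int) seq.size();
  if (min_len < 1 || max_len < min_len)
    stop("invalid repeat length range");
  if (max_len > n / 2)
    stop("max_len must not exceed half the genome length");
  const char *s = seq.data();
  IntegerVector out(max_len - min_len + 1);
  if (inverted) {
    // prefix[i] vs comp(seq[n-1-i]) is independent of L: cumulative count
    int mm = 0;
    for (int i = 0; i < max_len; ++i) {
      if (s[i] != dna_comp(s[n - 1 - i])) ++mm;
      if (i + 1 >= min_len) out[i + 1 - min_len] = mm;
    }
  } else {
    for (int L = min_len; L <= max_len; ++L) {
      int mm = 0;
      const char *tail = s + (n - L);
      for (int i = 0; i < L; ++i)
        if (s[i] != tail[i]) ++mm;
      out[L - min_len] = mm;
    }
  }
  return out;
}

// Semi-global alignment: the whole of `read` is aligned against any
// substring of `ref` (free leading/trailing reference, penalised read gaps).
// Linear gap penalty; traceback yields the edit decomposition needed for
// percent identity (matches / mismatches / insertions / deletions, where an
// insertion consumes read only and a deletion consumes reference only).
// Coordinates returned are 0-based offsets into `ref`, half-open.
// [[Rcpp::export]]
List semiglobal_align(std::string read, std::string ref,
                      int match = 1, int mismatch = -2, int gap = -3) {
  int m = (int) read.size(), n = (int) ref.size();
  if (m == 0 || n == 0) stop("empty sequence in semiglobal_align");
  const char *rd = read.data(), *rf = ref.data();
  // DP over (m+1) x (n+1); traceback codes: 0 stop, 1 diag, 2 up(ins), 3 left(del)
  std::vector<int> prev(n + 1), cur(n + 1);
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);
  for (int j = 0; j <= n; ++j) prev[j] = 0;              // free leading ref
  for (int i = 1; i <= m; ++i) {
    cur[0] = i * gap;
    tb[(size_t) i * (n + 1)] = 2;
    for (int j = 1; j <= n; ++j) {
      int sdiag = prev[j - 1] + (rd[i - 1] == rf[j - 1] ? match : mismatch);
      int sup   = prev[j] + gap;
      int sleft = cur[j - 1] + gap;
      int best = sdiag; unsigned char dir = 1;
      if (sup > best)   { best = sup;   dir = 2; }
      if (sleft > best) { best = sleft; dir = 3; }
      cur[j] = best;
      tb[(size_t) i * (n + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  // best cell in last row (free trailing ref); leftmost on ties
  int jbest = 0, sbest = prev[0];
  for (int j = 1; j <= n; ++j)
    if (prev[j] > sbest) { sbest = prev[j]; jbest = j; }
  int i = m, j = jbest;
  int matches = 0, mismatches = 0, ins = 0, del = 0;
  while (i > 0) {
    unsigned char dir = tb[(size_t) i * (n + 1) + j];
    if (dir == 1)      { if (rd[i - 1] == rf[j - 1]) ++matches; else ++mismatches; --i; --j; }
    else if (dir == 2) { ++ins; --i; }
    else               { ++del; --j; }
  }
  return List::create(_["score"] = sbest,
                      _["ref_start"] = j, _["ref_end"] = jbest,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["insertions"] = ins, _["deletions"] = del);
}

static inline int pair_class(char a, char b) {
  // 2 = G:C, 1 = A:T or G:T wobble, 0 = no pair
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 2;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 1;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// Enumerate hairpin candidates on the given (plus) strand of `seq`.
// Anchored on the loop: for each loop placement the stem is grown outward,
// accumulating G:C pairs, A:T/G:T pairs and mismatches.  A candidate is kept
// when the stability magnitude
//   |dG| = dg_gc*gc + dg_at*at - dg_loop_init - dg_loop_base*(loop-4)
//          - dg_mismatch*mm
// reaches min_abs_dg and a run of >= min_u_tract T's starts within u_window
// bases downstream of the 3' stem arm.  Per (loop position, loop length) only
// the most stable stem is emitted; overlap reduction across candidates is
// done by the caller.  Positions are 0-based; `position` is the 5' start of
// the left stem arm.
// [[Rcpp::export]]
DataFrame scan_hairpins(std::string seq,
                        int min_stem = 4, int max_stem = 20,
                        int min_loop = 4, int max_loop = 12,
                        int max_mismatch = 1,
                        double min_abs_dg = 10.5,
                        int min_u_tract = 3, int u_window = 8,
                        double dg_gc = 3.3, double dg_at = 2.0,
                        double dg_loop_init = 4.0, double dg_loop_base = 1.0,
                        double dg_mismatch = 3.0) {
  int n = (int) seq.size();
  const char *s = seq.data();
  std::vector<int> pos, stemv, loopv, mmv, utr;
  std::vector<double> dg;
  for (int loop = min_loop; loop <= max_loop; ++loop) {
    for (int l0 = 1; l0 + loop < n; ++l0) {   // loop occupies [l0, l0+loop)
      int gc = 0, at = 0, mm = 0;
      double best_dg = 0; int best_stem = 0, best_mm = 0, best_tract = 0;
      int kmax = std::min(l0, n - (l0 + loop));
      if (kmax > max_stem) kmax = max_stem;
      for (int k = 0; k < kmax; ++k) {
        int pc = pair_class(s[l0 - 1 - k], s[l0 + loop + k]);
        if (pc == 2) ++gc; else if (pc == 1) ++at; else ++mm;
        if (mm > max_mismatch) break;
        int stem = k + 1;
        if (stem < min_stem) continue;
        double val = dg_gc * gc + dg_at * at
                   - dg_loop_init - dg_loop_base * (loop - min_loop)
                   - dg_mismatch * mm;
        if (val < min_abs_dg || val <= best_dg) continue;
        // the poly-T tract must follow this stem's own 3' arm: check it
        // per candidate stem length, since a longer (more stable) stem can
        // bury the tract inside itself
        int arm_end = l0 + loop + stem;
        int tract = 0;
        int lim = std::min(n, arm_end + u_window);
        for (int t = arm_end; t < lim; ++t) {
          if (s[t] != 'T') continue;
          int run = 0;
          while (t + run < n && s[t + run] == 'T') ++run;
          if (run > tract) tract = run;
        }
        if (tract < min_u_tract) continue;
        best_dg = val; best_stem = stem; best_mm = mm; best_tract = tract;
      }
      if (best_stem == 0) continue;
      int tract = best_tract;
      pos.push_back(l0 - best_stem);
      stemv.push_back(best_stem);
      loopv.push_back(loop);
      mmv.push_back(best_mm);
      dg.push_back(best_dg);
      utr.push_back(tract);
    }
  }
  return DataFrame::create(_["position"] = pos, _["stem_len"] = stemv,
                           _["loop_len"] = loopv, _["mismatches_in_stem"] = mmv,
                           _["abs_delta_g"] = dg, _["u_tract_len"] = utr,
                           _["stringsAsFactors"] = false);
}
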