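#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Reverse complement of nucleotide strings (IUPAC-aware, case-preserving).
// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  static char comp[256];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 256; ++i) comp[i] = (char)i;
    const char *from = "ACGTUMRWSYKVHDBNacgtumrwsykvhdbn";
    const char *to   = "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn";
    for (int i = 0; from[i]; ++i) comp[(unsigned char)from[i]] = to[i];
    init = true;
  }
  CharacterVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) {
    if (x[k] == NA_STRING) { out[k] = NA_STRING; continue; }
    std::string s = as<std::string>(x[k]);
    std::string r(s.size(), ' ');
    for (size_t i = 0; i < s.size(); ++i)
      r[i] = comp[(unsigned char)s[s.size() - 1 - i]];
    out[k] = r;
  }
  return out;
}

// Semi-global (infix) Levenshtein alignment: the whole pattern is aligned
// against any substring of the text. Returns the minimal edit distance, and
// the 1-based [start, end] interval of the best-scoring substring. Ties are
// broken deterministically: smaller end position, and within a cell the
// diagonal move is preferred over vertical over horizontal, so repeated
// calls give identical loci.
// [[Rcpp::export(name = ".edit_locate_cpp")]]
List edit_locate_cpp(std::string pattern, std::string text) {
  const int m = pattern.size(), n = text.size();
  if (m == 0) stop("pattern must be non-empty");
  std::vector<int> prev(n + 1), cur(n + 1), pst(n + 1), cst(n + 1);
  for (int j = 0; j <= n; ++j) { prev[j] = 0; pst[j] = j; }
  for (int i = 1; i <= m; ++i) {
    cur[0] = i; cst[0] = 0;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int best = prev[j - 1] + (pc == text[j - 1] ? 0 : 1); // diagonal
      int st = pst[j - 1];
      if (prev[j] + 1 < best) { best = prev[j] + 1; st = pst[j]; }   // gap in text
      if (cur[j - 1] + 1 < best) { best = cur[j - 1] + 1; st = cst[j - 1]; } // gap in pattern
      cur[j] = best; cst[j] = st;
    }
    std::swap(prev, cur); std::swap(pst, cst);
  }
  int bj = 0, bd = prev[0];
  for (int j = 1; j <= n; ++j) if (prev[j] < bd) { bd = prev[j]; bj = j; }
  return List::create(_["distance"] = bd,
                      _["start"] = pst[bj] + 1,
                      _["end"] = bj);
}

// Longest window of the sequence whose fraction of 'T' bases is at least
// `frac` and whose length is at least `min_run`, with ties broken towards
// the leftmost window; the winning window is then trimmed to start and end
// on a T. Returns start/end (1-based, inclusive) or length 0 when no
// qualifying window exists. Linear-time via integer prefix sums: a window
// [i, j) qualifies iff sum over it of (100*isT - round(100*frac)) >= 0.
// [[Rcpp::export(name = ".polyt_window_cpp")]]
List polyt_window_cpp(std::string seq, int min_run, double frac) {
  const int n = seq.size();
  const long w_t = 100 - (long)(frac * 100 + 0.5);
  const long w_o = -(long)(frac * 100 + 0.5);
  std::vector<long> pre(n + 1, 0);
  for (int j = 0; j < n; ++j)
    pre[j + 1] = pre[j] + (seq[j] == 'T' || seq[j] == 't' ? w_t : w_o);
  // running minimum of the prefix; first index attaining each new minimum
  std::vector<long> pmin(n + 1);
  pmin[0] = pre[0];
  for (int j = 1; j <= n; ++j) pmin[j] = std::min(pmin[j - 1], pre[j]);
  int best_len = 0, best_start = -1;
  for (int j = 1; j <= n; ++j) {
    // earliest i with pre[i] <= pre[j]; pmin is non-increasing so binary search
    int lo = 0, hi = j;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (pmin[mid] <= pre[j]) hi = mid; else lo = mid + 1;
    }
    if (pmin[lo] <= pre[j] && j - lo > best_len) { best_len = j - lo; best_start = lo; }
  }
  if (best_start < 0 || best_len < min_run)
    return List::create(_["start"] = 0, _["end"] = -1, _["length"] = 0);
  int s = best_start, e = best_start + best_len; // 0-based half-open
  while (s < e && !(seq[s] == 'T' || seq[s] == 't')) ++s;
  while (e > s && !(seq[e - 1] == 'T' || seq[e - 1] == 't')) --e;
  if (e - s < min_run)
    return List::create(_["start"] = 0, _["end"] = -1, _["length"] = 0);
  return List::create(_["start"] = s + 1, _["end"] = e, _["length"] = e - s);
}
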