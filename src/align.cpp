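#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Shared DP buffers, reused across calls to avoid per-call allocation.
// Scores are integral (BLAST-style match/mismatch/gap costs).
namespace {
const int NEG = INT_MIN / 4;
thread_local std::vector<int> bufH, bufE, bufF;
thread_local std::vector<unsigned char> bufTH, bufTE, bufTF;

inline void ensure(size_t cells) {
  if (bufH.size() < cells) {
    bufH.resize(cells); bufE.resize(cells); bufF.resize(cells);
    bufTH.resize(cells); bufTE.resize(cells); bufTF.resize(cells);
  }
}

struct Traceback {
  std::string ap, as;
  int n_match, aln_len, i, j;
};

// Walk traceback matrices from (bi, bj); stops at H==0 cells when
// `local` else at (0,0). tbH codes: 0 stop, 1 diag, 2 from E, 3 from F.
Traceback walk(const std::string &pattern, const std::string &subject,
               int W, int bi, int bj, bool local) {
  std::string ap, as;
  int i = bi, j = bj, state = 0, n_match = 0;
  while (local ? true : (i > 0 || j > 0)) {
    const size_t k = (size_t)i * W + j;
    if (state == 0) {
      unsigned char tb = bufTH[k];
      if (local && tb == 0) break;
      if (tb == 1) {
        ap.push_back(pattern[i - 1]); as.push_back(subject[j - 1]);
        if (pattern[i - 1] == subject[j - 1]) ++n_match;
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ap.push_back('-'); as.push_back(subject[j - 1]);
      if (bufTE[k] == 0) state = 0;
      --j;
    } else {
      ap.push_back(pattern[i - 1]); as.push_back('-');
      if (bufTF[k] == 0) state = 0;
      --i;
    }
  }
  std::reverse(ap.begin(), ap.end());
  std::reverse(as.begin(), as.end());
  Traceback t;
  t.n_match = n_match; t.aln_len = (int)ap.size(); t.i = i; t.j = j;
  t.ap = std::move(ap); t.as = std::move(as);
  return t;
}
}  // namespace

// Affine-gap (Gotoh) local Smith-Waterman with full traceback.
// BLAST-style gap costs: a gap of length L costs open + L * extend.
// Coordinates in the result are 0-based, half-open.
//
// [[Rcpp::export]]
List cpp_sw_align(std::string pattern, std::string subject,
                  int match = 2, int mismatch = -3,
                  int gap_open = 5, int gap_ext = 2) {
  const int n = (int)pattern.size(), m = (int)subject.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0);
  const int W = m + 1;
  ensure((size_t)(n + 1) * W);
  int *H = bufH.data(), *E = bufE.data(), *F = bufF.data();
  unsigned char *TH = bufTH.data(), *TE = bufTE.data(), *TF = bufTF.data();
  for (int j = 0; j <= m; ++j) {
    H[j] = 0; E[j] = NEG; F[j] = NEG; TH[j] = 0;
  }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const size_t r = (size_t)i * W;
    H[r] = 0; E[r] = NEG; F[r] = NEG; TH[r] = 0;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t k = r + j;
      int e_open = H[k - 1] - gap_open - gap_ext;
      int e_ext = E[k - 1] - gap_ext;
      if (e_open >= e_ext) { E[k] = e_open; TE[k] = 0; }
      else { E[k] = e_ext; TE[k] = 1; }
      int f_open = H[k - W] - gap_open - gap_ext;
      int f_ext = F[k - W] - gap_ext;
      if (f_open >= f_ext) { F[k] = f_open; TF[k] = 0; }
      else { F[k] = f_ext; TF[k] = 1; }
      int diag = H[k - W - 1] + (pc == subject[j - 1] ? match : mismatch);
      int h = 0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[k] > h) { h = E[k]; tb = 2; }
      if (F[k] > h) { h = F[k]; tb = 3; }
      H[k] = h; TH[k] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0);
  Traceback t = walk(pattern, subject, W, bi, bj, true);
  return List::create(
      _["score"] = best,
      _["pstart"] = t.i, _["pend"] = bi,
      _["sstart"] = t.j, _["send"] = bj,
      _["n_match"] = t.n_match, _["aln_len"] = t.aln_len,
      _["identity"] = t.aln_len > 0 ? (double)t.n_match / t.aln_len : 0.0,
      _["pattern_aln"] = t.ap, _["subject_aln"] = t.as);
}

// Fitting alignment for unit tiling: the whole pattern (an 84-nt finger) is
// aligned against a prefix of the subject window. Both sequences are
// anchored at position 0; the subject end is free. Returns the number of
// subject characters consumed plus alignment strings for projecting the
// read onto finger coordinates.
//
// [[Rcpp::export]]
List cpp_fit_align(std::string pattern, std::string subject,
                   int match = 2, int mismatch = -3,
                   int gap_open = 5, int gap_ext = 2) {
  const int n = (int)pattern.size(), m = (int)subject.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = NEG);
  const int W = m + 1;
  ensure((size_t)(n + 1) * W);
  int *H = bufH.data(), *E = bufE.data(), *F = bufF.data();
  unsigned char *TH = bufTH.data(), *TE = bufTE.data(), *TF = bufTF.data();
  H[0] = 0; E[0] = NEG; F[0] = NEG; TH[0] = 0;
  for (int j = 1; j <= m; ++j) {  // leading subject consumed as pattern-gap
    E[j] = -gap_open - gap_ext * j;
    H[j] = E[j]; F[j] = NEG;
    TH[j] = 2; TE[j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    const size_t r = (size_t)i * W;
    F[r] = -gap_open - gap_ext * i;
    H[r] = F[r]; E[r] = NEG;
    TH[r] = 3; TF[r] = (i == 1) ? 0 : 1;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t k = r + j;
      int e_open = H[k - 1] - gap_open - gap_ext;
      int e_ext = E[k - 1] - gap_ext;
      if (e_open >= e_ext) { E[k] = e_open; TE[k] = 0; }
      else { E[k] = e_ext; TE[k] = 1; }
      int f_open = H[k - W] - gap_open - gap_ext;
      int f_ext = F[k - W] - gap_ext;
      if (f_open >= f_ext) { F[k] = f_open; TF[k] = 0; }
      else { F[k] = f_ext; TF[k] = 1; }
      int diag = H[k - W - 1] + (pc == subject[j - 1] ? match : mismatch);
      int h = diag; unsigned char tb = 1;
      if (E[k] > h) { h = E[k]; tb = 2; }
      if (F[k] > h) { h = F[k]; tb = 3; }
      H[k] = h; TH[k] = tb;
    }
  }
  int best = NEG, bj = 0;  // best full-pattern end over subject prefixes
  for (int j = 0; j <= m; ++j) {
    const int v = H[(size_t)n * W + j];
    if (v > best) { best = v; bj = j; }
  }
  Traceback t = walk(pattern, subject, W, n, bj, false);
  return List::create(
      _["score"] = best, _["consumed"] = bj,
      _["n_match"] = t.n_match, _["aln_len"] = t.aln_len,
      _["identity"] = t.aln_len > 0 ? (double)t.n_match / t.aln_len : 0.0,
      _["pattern_aln"] = t.ap, _["subject_aln"] = t.as);
}

// For every 0-based start position c of `child`, the length of the longest
// substring of `parent` equal to a prefix of child[c..], and the leftmost
// parent position where that longest match starts. O(n*m) time, O(m) space.
//
// [[Rcpp::export]]
List cpp_maxext(std::string child, std::string parent) {
  const int n = (int)child.size(), m = (int)parent.size();
  IntegerVector len(n), pos(n);
  std::vector<int> ext(m + 1, 0), nxt(m + 1, 0);
  for (int c = n - 1; c >= 0; --c) {
    int bestl = 0, bestq = -1;
    const char cc = child[c];
    for (int q = m - 1; q >= 0; --q) {
      nxt[q] = (cc == parent[q]) ? ext[q + 1] + 1 : 0;
      if (nxt[q] >= bestl) { bestl = nxt[q]; bestq = q; }  // >=: leftmost wins
    }
    nxt[m] = 0;
    std::swap(ext, nxt);
    len[c] = bestl;
    pos[c] = bestq;
  }
  return List::create(_["len"] = len, _["pos"] = pos);
}

// Length of the longest common prefix of two strings.
//
// [[Rcpp::export]]
int cpp_lcp(std::string a, std::string b) {
  const size_t n = std::min(a.size(), b.size());
  size_t i = 0;
  while (i < n && a[i] == b[i]) ++i;
  return (int)i;
}

// Length of the longest common suffix of two strings.
//
// [[Rcpp::export]]
int cpp_lcs_suffix(std::string a, std::string b) {
  const size_t n = std::min(a.size(), b.size());
  size_t i = 0;
  while (i < n && a[a.size() - 1 - i] == b[b.size() - 1 - i]) ++i;
  return (int)i;
}

// Pairwise Hamming distances among equal-length strings, excluding positions
// where either sequence has the `missing` character. Returns a dist-style
// lower-triangle vector (column-major, as stats::dist).
//
// [[Rcpp::export]]
NumericVector cpp_hamming_matrix(CharacterVector seqs, char missing = 'N') {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericVector out((size_t)n * (n - 1) / 2);
  size_t k = 0;
  for (int j = 0; j < n; ++j) {
    for (int i = j + 1; i < n; ++i) {
      int d = 0;
      const std::string &a = s[j], &b = s[i];
      const size_t L = a.size();
      for (size_t p = 0; p < L; ++p) {
        if (a[p] == missing || b[p] == missing) continue;
        if (a[p] != b[p]) ++d;
      }
      out[k++] = d;
    }
  }
  return out;
}
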