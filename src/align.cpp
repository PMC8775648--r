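#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// DP. A gap of length k costs open + k * ext. Sequences are 1-based index
// vectors into the rows/cols of `sub` (21 letters: the 20 canonical
// residues plus X).

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

struct AlnResult {
  double score;
  int length;        // alignment columns
  int positives;     // aligned pairs with positive substitution score
  std::vector<int> ai, bi;  // per column: residue index or 0 for gap
};

static AlnResult nw_gotoh(const IntegerVector& a, const IntegerVector& b,
                          const NumericMatrix& sub, double go, double ge,
                          bool traceback) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  // state 0 = match/mismatch, 1 = gap in b (consume a), 2 = gap in a
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = -(go + i * ge);
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = -(go + j * ge);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = max3(M[at(i - 1, j - 1)], X[at(i - 1, j - 1)],
                         Y[at(i - 1, j - 1)]);
      M[at(i, j)] = diag + sub(a[i - 1] - 1, b[j - 1] - 1);
      X[at(i, j)] = std::max(
          max3(M[at(i - 1, j)], Y[at(i - 1, j)], NEG) - go - ge,
          X[at(i - 1, j)] - ge);
      Y[at(i, j)] = std::max(
          max3(M[at(i, j - 1)], X[at(i, j - 1)], NEG) - go - ge,
          Y[at(i, j - 1)] - ge);
    }
  }
  AlnResult res;
  double best = max3(M[at(n, m)], X[at(n, m)], Y[at(n, m)]);
  res.score = best;
  res.length = 0; res.positives = 0;
  if (!traceback) return res;
  // deterministic traceback, preferring match, then gap-in-b, then gap-in-a
  int i = n, j = m;
  int state = (M[at(n, m)] >= X[at(n, m)] && M[at(n, m)] >= Y[at(n, m)]) ? 0
              : (X[at(n, m)] >= Y[at(n, m)] ? 1 : 2);
  std::vector<int> ra, rb;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      double sc = sub(a[i - 1] - 1, b[j - 1] - 1);
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (sc > 0) ++res.positives;
      double prev = M[at(i, j)] - sc;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[at(i, j)] - prev) < 1e-9) state = 0;
      else if (std::abs(X[at(i, j)] - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back(0);
      double cur = X[at(i, j)];
      --i;
      if (std::abs(X[at(i, j)] - ge - cur) < 1e-9 && i > 0) state = 1;
      else if (std::abs(M[at(i, j)] - go - ge - cur) < 1e-9) state = 0;
      else if (std::abs(Y[at(i, j)] - go - ge - cur) < 1e-9) state = 2;
      else state = 1;
    } else {
      ra.push_back(0); rb.push_back(b[j - 1]);
      double cur = Y[at(i, j)];
      --j;
      if (std::abs(Y[at(i, j)] - ge - cur) < 1e-9 && j > 0) state = 2;
      else if (std::abs(M[at(i, j)] - go - ge - cur) < 1e-9) state = 0;
      else if (std::abs(X[at(i, j)] - go - ge - cur) < 1e-9) state = 1;
      else state = 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  res.ai = ra; res.bi = rb;
  res.length = (int)ra.size();
  return res;
}

// Full alignment of one pair: returns score, positives, and the two
// gapped index rows (0 = gap).
// [[Rcpp::export(name = ".nw_align_pair")]]
List nw_align_pair(IntegerVector a, IntegerVector b, NumericMatrix sub,
                   double gap_open, double gap_ext) {
  AlnResult r = nw_gotoh(a, b, sub, gap_open, gap_ext, true);
  return List::create(_["score"] = r.score,
                      _["positives"] = r.positives,
                      _["length"] = r.length,
                      _["a"] = wrap(r.ai), _["b"] = wrap(r.bi));
}

// Score and percent-positives matrices for all pairs of two encoded
// sequence lists.
// [[Rcpp::export(name = ".nw_stats_matrix")]]
List nw_stats_matrix(List qs, List rs, NumericMatrix sub,
                     double gap_open, double gap_ext) {
  const int nq = qs.size(), nr = rs.size();
  NumericMatrix score(nq, nr), pos(nq, nr);
  for (int i = 0; i < nq; ++i) {
    IntegerVector a = qs[i];
    for (int j = 0; j < nr; ++j) {
      IntegerVector b = rs[j];
      AlnResult r = nw_gotoh(a, b, sub, gap_open, gap_ext, true);
      score(i, j) = r.score;
      pos(i, j) = 100.0 * r.positives / r.length;
    }
  }
  return List::create(_["score"] = score, _["positives"] = pos);
}
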