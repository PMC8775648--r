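#include <Rcpp.h>
using namespace Rcpp;

// Best ungapped window of a log-odds profile over an encoded protein.
//
// seq: 1-based residue indices into the 20-letter alphabet, NA for X.
// lo:  L x 20 log-odds matrix (bits). NA residues contribute 0 at any
//      column, matching their exclusion from frequency computations.
// Proteins shorter than L are slid inside the profile; columns without a
// residue contribute 0 ("single best partial window").
//
// Returns [best score, best start (0-based; for short proteins the offset
// of the protein inside the profile, reported as a negative start)].
// [[Rcpp::export(name = ".scan_windows")]]
NumericVector scan_windows(IntegerVector seq, NumericMatrix lo) {
  const int n = seq.size();
  const int L = lo.nrow();
  double best = R_NegInf;
  int best_start = 0;
  if (n >= L) {
    for (int w = 0; w + L <= n; ++w) {
      double s = 0.0;
      for (int c = 0; c < L; ++c) {
        int a = seq[w + c];
        if (a != NA_INTEGER) s += lo(c, a - 1);
      }
      if (s > best) { best = s; best_start = w; }
    }
  } else {
    // protein fits inside the profile: offset o aligns protein pos i to
    // profile column o + i
    for (int o = 0; o + n <= L; ++o) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) {
        int a = seq[i];
        if (a != NA_INTEGER) s += lo(o + i, a - 1);
      }
      if (s > best) { best = s; best_start = -o; }
    }
  }
  return NumericVector::create(best, (double)best_start);
}

// Max-window scores for a batch of encoded proteins (list of integer
// vectors) against one profile; used by the shuffle-null calibration.
// [[Rcpp::export(name = ".scan_windows_batch")]]
NumericVector scan_windows_batch(List seqs, NumericMatrix lo) {
  const int m = seqs.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    IntegerVector s = seqs[k];
    out[k] = scan_windows(s, lo)[0];
  }
  return out;
}
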