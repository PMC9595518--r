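#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Multiple-tau autocorrelation on a semilogarithmic lag ladder.
//
// Level 0 evaluates lags 1..m (in bins); each further level halves the
// time resolution (pairwise binning) and evaluates lags m/2+1 .. m in
// the coarsened bins.  Per lag j on a series I of length n the estimator
// is the symmetrically normalized correlator
//   G(j) = [ (1/(n-j)) sum_t I_t I_{t+j} ] / (mean_head * mean_tail) - 1,
// with mean_head over I_1..I_{n-j} and mean_tail over I_{j+1}..I_n.
// Symmetric normalization removes the leading finite-length bias and
// matches the direct all-pairs estimator exactly at uncoarsened lags.
// [[Rcpp::export]]
DataFrame multitau_cpp(NumericVector counts, int m) {
  std::vector<double> lag_bins, G, n_pairs;
  std::vector<double> I(counts.begin(), counts.end());
  double binsize = 1.0;
  int level = 0;
  while (true) {
    const int n = (int)I.size();
    const int jmin = (level == 0) ? 1 : (m / 2 + 1);
    if (n <= jmin) break;
    for (int j = jmin; j <= m; ++j) {
      const int np = n - j;
      if (np < 1) break;
      double s = 0.0, sh = 0.0, st = 0.0;
      for (int t = 0; t < np; ++t) {
        s += I[t] * I[t + j];
        sh += I[t];
        st += I[t + j];
      }
      const double mh = sh / np, mt = st / np;
      if (mh <= 0.0 || mt <= 0.0) continue;  // normalization undefined here
      lag_bins.push_back((double)j * binsize);
      G.push_back(s / np / (mh * mt) - 1.0);
      n_pairs.push_back((double)np);
    }
    if (n < 2 * (m + 1)) break;
    const int half = n / 2;
    std::vector<double> J(half);
    for (int t = 0; t < half; ++t) J[t] = I[2 * t] + I[2 * t + 1];
    I.swap(J);
    binsize *= 2.0;
    ++level;
  }
  return DataFrame::create(_["lag_bins"] = lag_bins, _["G"] = G,
                           _["n_pairs"] = n_pairs);
}

// 8-connected labelling of a binary matrix (flood fill).  Returns an
// integer matrix of component labels, 0 for background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.push_back(r0 + c0 * nr);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int r = idx % nr, c = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Direct 2D convolution with a small kernel, zero-padded borders.
// [[Rcpp::export]]
NumericMatrix conv2_cpp(NumericMatrix img, NumericMatrix kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kernel.nrow(), kc = kernel.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int j = 0; j < kc; ++j) {
        const int cc = c + j - hc;
        if (cc < 0 || cc >= nc) continue;
        for (int i = 0; i < kr; ++i) {
          const int rr = r + i - hr;
          if (rr < 0 || rr >= nr) continue;
          s += img(rr, cc) * kernel(i, j);
        }
      }
      out(r, c) = s;
    }
  }
  return out;
}
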