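#include <Rcpp.h>
using namespace Rcpp;

// Maximal circular two-sample statistic for circular binary segmentation.
//
// For a segment of n bins with values x, every circular split corresponds
// to an arc x[(i+1)..j] (0 <= i < j <= n, proper non-empty arc and
// complement). The statistic is |mean(arc) - mean(complement)| scaled by
// sqrt(1/n1 + 1/n2); the overall sd is constant across splits (and across
// permutations of the same segment), so it is left out of the scan and
// applied by the caller when a t-scale value is needed.
//
// Returns max statistic and the (i, j) achieving it (1-based arc bounds:
// arc = bins (i+1)..j).
// [[Rcpp::export(name = ".cbsScan")]]
List cbsScan(NumericVector x, int minArc) {
  int n = x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int k = 0; k < n; ++k) S[k + 1] = S[k] + x[k];
  double best = -1.0;
  int bi = 0, bj = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      int n1 = j - i, n2 = n - n1;
      if (n1 < minArc || n2 < minArc) continue;
      double m1 = (S[j] - S[i]) / n1;
      double m2 = (S[n] - S[j] + S[i]) / n2;
      double stat = std::fabs(m1 - m2) / std::sqrt(1.0 / n1 + 1.0 / n2);
      if (stat > best) {
        best = stat;
        bi = i;
        bj = j;
      }
    }
  }
  return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
}
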