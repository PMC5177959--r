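#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Nearest-neighbour simplex prediction over a precomputed distance
// matrix. D: full pairwise distances between manifold vectors; values:
// quantity to predict at each vector; lib/targets: 1-based vector
// indices (lib may contain repeats from bootstrap resampling); k:
// number of neighbours (E + 1). Library entries equal to the target
// index are excluded (leave-one-out). Returns the Pearson correlation
// between predictions and observations, or NA when undefined.
// [[Rcpp::export(name = ".cross_map_rho_cpp")]]
double cross_map_rho_cpp(const NumericMatrix& D,
                         const NumericVector& values,
                         const IntegerVector& lib,
                         const IntegerVector& targets,
                         const int k) {
  const int nlib = lib.size();
  const int ntar = targets.size();
  std::vector<std::pair<double, int> > cand(nlib);
  std::vector<double> pred(ntar), obs(ntar);
  int m = 0;
  for (int i = 0; i < ntar; ++i) {
    const int t0 = targets[i] - 1;
    int nc = 0;
    for (int j = 0; j < nlib; ++j) {
      const int lj = lib[j] - 1;
      if (lj == t0) continue;
      const double d = D(t0, lj);
      if (!R_finite(d)) continue;
      cand[nc++] = std::make_pair(d, lj);
    }
    if (nc == 0) continue;
    const int kk = std::min(k, nc);
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.begin() + nc);
    const double dmin = cand[0].first;
    double wsum = 0.0, p = 0.0;
    if (dmin == 0.0) {
      // all weight on exact matches
      for (int j = 0; j < kk && cand[j].first == 0.0; ++j) {
        p += values[cand[j].second];
        wsum += 1.0;
      }
    } else {
      for (int j = 0; j < kk; ++j) {
        const double w = std::exp(-cand[j].first / dmin);
        p += w * values[cand[j].second];
        wsum += w;
      }
    }
    const double o = values[t0];
    if (!R_finite(o) || wsum <= 0.0) continue;
    pred[m] = p / wsum;
    obs[m] = o;
    ++m;
  }
  if (m < 3) return NA_REAL;
  double mp = 0.0, mo = 0.0;
  for (int i = 0; i < m; ++i) { mp += pred[i]; mo += obs[i]; }
  mp /= m; mo /= m;
  double spo = 0.0, sp2 = 0.0, so2 = 0.0;
  for (int i = 0; i < m; ++i) {
    const double a = pred[i] - mp, b = obs[i] - mo;
    spo += a * b; sp2 += a * a; so2 += b * b;
  }
  if (sp2 <= 0.0 || so2 <= 0.0) return NA_REAL;
  return spo / std::sqrt(sp2 * so2);
}
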