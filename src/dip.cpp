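#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Hartigan & Hartigan's dip statistic: the maximum distance between the
// empirical cdf and the closest unimodal cdf.  Implementation of the
// published iterative algorithm: repeatedly fit the greatest convex minorant
// (gcm) and least concave majorant (lcm) of the ecdf on a shrinking candidate
// modal interval [low, high]; the dip is the largest of the one-sided fit
// errors outside the final modal interval and half the gcm/lcm separation
// inside it.  All distances are kept in units of counts (1/n) and divided by
// 2n at the end.
static double dip_sorted(const std::vector<double>& x) {
  const int n = (int)x.size();
  if (n < 2) return 0.0;
  if (x[0] == x[n - 1]) return 0.0;  // degenerate: point mass is unimodal

  // pred[j]: previous touch point of the gcm through (x_j, j); succ[j]: next
  // touch point of the lcm.  1-based indexing to match the recursions.
  std::vector<int> pred(n + 2), succ(n + 2);
  const double* xx = x.data() - 1;  // xx[1..n]

  pred[1] = 1;
  for (int j = 2; j <= n; ++j) {
    pred[j] = j - 1;
    for (;;) {
      int pj = pred[j];
      if (pj == 1) break;
      int ppj = pred[pj];
      // keep pj while slope(ppj,pj) < slope(pj,j), i.e. convexity holds
      if ((xx[j] - xx[pj]) * (pj - ppj) < (xx[pj] - xx[ppj]) * (j - pj)) break;
      pred[j] = ppj;
    }
  }
  succ[n] = n;
  for (int k = n - 1; k >= 1; --k) {
    succ[k] = k + 1;
    for (;;) {
      int sk = succ[k];
      if (sk == n) break;
      int ssk = succ[sk];
      if ((xx[k] - xx[sk]) * (sk - ssk) < (xx[sk] - xx[ssk]) * (k - sk)) break;
      succ[k] = ssk;
    }
  }

  int low = 1, high = n;
  double dip = 1.0;  // lower bound: one jump always escapes a continuous fit

  std::vector<int> gcm(n + 2), lcm(n + 2);
  for (;;) {
    // gcm touch points from high down to low; lcm touch points low..high
    gcm[1] = high;
    int l_gcm = 1;
    while (gcm[l_gcm] > low) { gcm[l_gcm + 1] = pred[gcm[l_gcm]]; ++l_gcm; }
    lcm[1] = low;
    int l_lcm = 1;
    while (lcm[l_lcm] < high) { lcm[l_lcm + 1] = succ[lcm[l_lcm]]; ++l_lcm; }

    // largest separation between the two curves over [low, high]
    int ig = l_gcm, ih = l_lcm;
    double d = 0.0;
    if (l_gcm != 2 || l_lcm != 2) {
      int ix = l_gcm - 1, iv = 2;
      do {
        int gx = gcm[ix], lv = lcm[iv];
        if (gx > lv) {
          // next knot along is an lcm touch point: gcm curve vs that knot
          int g1 = gcm[ix + 1];
          double dx = (lv - g1 + 1) -
                      (xx[lv] - xx[g1]) * (gx - g1) / (xx[gx] - xx[g1]);
          ++iv;
          if (dx >= d) { d = dx; ig = ix + 1; ih = iv - 1; }
        } else {
          // next knot along is a gcm touch point: lcm curve vs that knot
          int l1 = lcm[iv - 1];
          double dx = (xx[gx] - xx[l1]) * (lv - l1) / (xx[lv] - xx[l1]) -
                      (gx - l1 - 1);
          --ix;
          if (dx >= d) { d = dx; ig = ix + 1; ih = iv; }
        }
        if (ix < 1) ix = 1;
        if (iv > l_lcm) iv = l_lcm;
      } while (gcm[ix] != lcm[iv]);
    } else {
      d = 1.0;
    }
    if (d < dip) break;

    // one-sided fit errors outside the tentative modal interval:
    // ecdf above the gcm on [low, gcm[ig]] ...
    double dip_l = 0.0;
    for (int j = ig; j < l_gcm; ++j) {
      double max_t = 1.0;
      int jb = gcm[j + 1], je = gcm[j];
      if (je - jb > 1 && xx[je] != xx[jb]) {
        double c = (je - jb) / (xx[je] - xx[jb]);
        for (int jj = jb; jj <= je; ++jj) {
          double t = (jj - jb + 1) - (xx[jj] - xx[jb]) * c;
          if (max_t < t) max_t = t;
        }
      }
      if (dip_l < max_t) dip_l = max_t;
    }
    // ... and ecdf below the lcm on [lcm[ih], high]
    double dip_u = 0.0;
    for (int j = ih; j < l_lcm; ++j) {
      double max_t = 1.0;
      int jb = lcm[j], je = lcm[j + 1];
      if (je - jb > 1 && xx[je] != xx[jb]) {
        double c = (je - jb) / (xx[je] - xx[jb]);
        for (int jj = jb; jj <= je; ++jj) {
          double t = (xx[jj] - xx[jb]) * c - (jj - jb - 1);
          if (max_t < t) max_t = t;
        }
      }
      if (dip_u < max_t) dip_u = max_t;
    }

    double dip_new = (dip_l < dip_u) ? dip_u : dip_l;
    if (dip < dip_new) dip = dip_new;
    int new_low = gcm[ig], new_high = lcm[ih];
    if (new_low == low && new_high == high) break;  // no progress possible
    low = new_low;
    high = new_high;
  }
  return dip / (2.0 * n);
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  return dip_sorted(xs);
}

// Dip statistics of `nrep` uniform(0,1) samples of size n.  The uniform is
// the conventional calibration null for the dip test (asymptotically the
// least favourable unimodal distribution).  Uses R's RNG: seed from R.
// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int nrep) {
  NumericVector out(nrep);
  std::vector<double> xs(n);
  for (int r = 0; r < nrep; ++r) {
    for (int i = 0; i < n; ++i) xs[i] = unif_rand();
    std::sort(xs.begin(), xs.end());
    out[r] = dip_sorted(xs);
  }
  return out;
}
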