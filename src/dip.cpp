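#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <limits>
using namespace Rcpp;

// Dip statistic for unimodality: the minimal sup-norm distance between
// the empirical CDF and any unimodal distribution function (convex df
// left of the mode, concave right of it, with an atom allowed at the
// mode).  Computed by bisection over the distance d; for a candidate d
// the feasibility question -- does a unimodal G exist with
// sup |F_n - G| <= d? -- decomposes over the mode knot j:
//
//   * convex side: a convex nondecreasing function through the bands
//     [lo_k, up_k] at the distinct sample values y_0..y_{j-1}, where
//     lo_k = c_k/n - d (c_k = cumulative count) and
//     up_k = c_{k-1}/n + d (the left-limit corner of the ECDF step);
//     its left limit at y_j must not exceed up_j.
//   * concave side: a concave nondecreasing function through the bands
//     at y_j..y_{m-1}; the upper band at the mode knot itself is
//     relaxed to c_j/n + d because the atom absorbs the left limit.
//   * junction: the convex side's minimal achievable end value must not
//     exceed the concave side's maximal achievable start value (the
//     jump at the mode is upward).
//
// Convex-side feasibility is the classical hull criterion: a convex
// function within [lo, up] exists iff the greatest convex minorant of
// the up-corners stays above lo.  End-value extremes come from chord
// extrapolation bounds: for each support point k, the steepest chord
// from an earlier up-corner to k's lo-corner bounds the continuation
// slope from below.  The concave side is the mirror image
// (h(x) = -g(-x)).

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();
const double EPS = 1e-12;

// Incremental prefix feasibility for a convex nondecreasing function
// within [lo, up].  After adding each point k, the lower convex hull of
// the up-corners is evaluated against lo.
//  T_strict: largest prefix length t with hull >= lo at all points < t.
//  T_relax : largest t with hull >= lo at all points < t-1 (the final
//            point's lower band waived -- used for the mode knot on the
//            mirrored, i.e. concave, side).
void prefix_feasible(const std::vector<double>& y,
                     const std::vector<double>& lo,
                     const std::vector<double>& up,
                     int& T_strict, int& T_relax) {
  int m = (int)y.size();
  std::vector<int> hull;
  T_strict = 0;
  T_relax = 0;
  for (int k = 0; k < m; ++k) {
    while (hull.size() >= 2) {
      int a = hull[hull.size() - 2], c = hull[hull.size() - 1];
      double cross = (y[c] - y[a]) * (up[k] - up[a]) -
                     (up[c] - up[a]) * (y[k] - y[a]);
      if (cross <= 0) hull.pop_back(); else break;
    }
    hull.push_back(k);
    bool ok_interior = true;
    int seg = 0;
    for (int i = 0; i < k && ok_interior; ++i) {
      while (seg + 1 < (int)hull.size() && y[hull[seg + 1]] < y[i])
        ++seg;
      double gv;
      if (seg + 1 >= (int)hull.size()) gv = up[hull[seg]];
      else {
        int a = hull[seg], c = hull[seg + 1];
        gv = up[a] + (up[c] - up[a]) * (y[i] - y[a]) / (y[c] - y[a]);
      }
      if (gv < lo[i] - EPS) ok_interior = false;
    }
    if (!ok_interior) break;
    T_relax = k + 1;
    bool ok_own = up[k] >= lo[k] - EPS;  // hull passes through up[k]
    if (T_strict == k && ok_own) T_strict = k + 1;
  }
}

bool dip_feasible(const std::vector<double>& y,
                  const std::vector<double>& cum,
                  double n, double d) {
  int m = (int)y.size();
  if (m == 1) return true;

  std::vector<double> lo(m), up(m);
  for (int k = 0; k < m; ++k) {
    lo[k] = cum[k] / n - d;
    up[k] = (k == 0 ? 0.0 : cum[k - 1] / n) + d;
  }

  int Tconv, Tconv_relax_unused;
  prefix_feasible(y, lo, up, Tconv, Tconv_relax_unused);

  // Mirror transform for the concave side.
  std::vector<double> ry(m), rlo(m), rup(m);
  for (int k = 0; k < m; ++k) {
    ry[k] = -y[m - 1 - k];
    rlo[k] = -up[m - 1 - k];
    rup[k] = -lo[m - 1 - k];
  }
  int Tconc_strict_unused, Tconc;
  prefix_feasible(ry, rlo, rup, Tconc_strict_unused, Tconc);

  // Chord slope bounds for the junction extremes.
  std::vector<double> sigma(m, NEG_INF);  // convex side, at point k:
  for (int k = 0; k < m; ++k)             // steepest (up_i -> lo_k) chord
    for (int i = 0; i < k; ++i) {
      double dy = y[k] - y[i];
      if (dy <= 0) continue;
      double s = (lo[k] - up[i]) / dy;
      if (s > sigma[k]) sigma[k] = s;
    }
  std::vector<double> tau(m, NEG_INF);    // concave side, at point k1:
  for (int k1 = 0; k1 < m; ++k1)          // steepest (up_k1 -> lo_k2) chord
    for (int k2 = k1 + 1; k2 < m; ++k2) {
      double dy = y[k2] - y[k1];
      if (dy <= 0) continue;
      double s = (lo[k2] - up[k1]) / dy;
      if (s > tau[k1]) tau[k1] = s;
    }

  for (int j = 0; j < m; ++j) {
    if (j > Tconv) continue;       // convex side (j points) infeasible
    if (m - j > Tconc) continue;   // concave side infeasible
    // Minimal achievable end value of the convex side at y[j].
    double m_conv = NEG_INF;
    for (int k = 0; k < j; ++k) {
      double cand = lo[k];  // monotonicity bound
      if (sigma[k] > 0) {
        double c2 = lo[k] + sigma[k] * (y[j] - y[k]);
        if (c2 > cand) cand = c2;
      }
      if (cand > m_conv) m_conv = cand;
    }
    // Maximal achievable start value of the concave side at y[j]
    // (own upper band relaxed to cum[j]/n + d by the atom).
    double M_conc = cum[j] / n + d;
    for (int k = j + 1; k < m; ++k) {
      double cand = up[k];  // monotonicity bound
      if (tau[k] > 0) {
        double c2 = up[k] - tau[k] * (y[k] - y[j]);
        if (c2 < cand) cand = c2;
      }
      if (cand < M_conc) M_conc = cand;
    }
    bool ok = true;
    if (j > 0) {
      if (m_conv > up[j] + EPS) ok = false;    // left-limit cap
      if (m_conv > M_conc + EPS) ok = false;   // junction
    }
    if (ok && M_conc < lo[j] - EPS) ok = false;
    if (ok) return true;
  }
  return false;
}

double dip_of_sorted(const std::vector<double>& xs) {
  int n = (int)xs.size();
  if (n < 2) return 0.0;
  std::vector<double> y, cum;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    y.push_back(xs[i]);
    cum.push_back((double)j);
    i = j;
  }
  if (y.size() == 1) return 0.0;
  double lo = 0.0, hi = 0.5;
  for (int it = 0; it < 40; ++it) {
    double mid = 0.5 * (lo + hi);
    if (dip_feasible(y, cum, (double)n, mid)) hi = mid; else lo = mid;
  }
  return hi;
}

}  // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  return dip_of_sorted(xs);
}

// Bootstrap null distribution of the dip under the uniform(0,1) null,
// using R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".dip_boot_cpp")]]
NumericVector dip_boot_cpp(int n, int n_boot) {
  NumericVector out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    NumericVector u = runif(n);
    std::vector<double> xs(u.begin(), u.end());
    std::sort(xs.begin(), xs.end());
    out[b] = dip_of_sorted(xs);
  }
  return out;
}
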