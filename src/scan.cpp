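#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Spectral index form codes (shared with R/indices.R):
// 1 SI  = Ri + Rj
// 2 DI  = Ri - Rj
// 3 PI  = Ri * Rj
// 4 RI  = Ri / Rj
// 5 NDI = (Ri - Rj) / (Ri + Rj)
// 6 TBI1 = Ri / (Rj + Rk)
// 7 TBI2 = (Ri + Rj) / Rk
// 8 TBI3 = (Ri - Rj) / (Rj - Rk)
// 9 TBI4 = (Ri - Rj) / (Ri + Rj - 2 Rk)
// 10 TBI5 = Ri + Rj - 2 Rk

// Per-cell Pearson r between the per-sample index vector and y.
// Two-pass centering keeps cancellation error negligible relative to the
// naive R oracle. A cell is invalid when any sample's index is non-finite,
// any denominator magnitude is below eps, or the index variance (biased,
// mean of squared deviations) is below eps.
static inline bool cell_pearson(const double* v, const double* yc,
                                double sy2, int n, double eps, double& r) {
  double mv = 0.0;
  for (int s = 0; s < n; ++s) {
    if (!std::isfinite(v[s])) return false;
    mv += v[s];
  }
  mv /= n;
  double svv = 0.0, svy = 0.0;
  for (int s = 0; s < n; ++s) {
    double d = v[s] - mv;
    svv += d * d;
    svy += d * yc[s];
  }
  if (svv / n < eps) return false;
  r = svy / std::sqrt(svv * sy2);
  return true;
}

// [[Rcpp::export]]
List scan_pairs_cpp(NumericMatrix R, NumericVector y, int form, double eps) {
  const int n = R.nrow();
  const int B = R.ncol();
  NumericMatrix r(B, B);
  LogicalMatrix valid(B, B);
  std::fill(r.begin(), r.end(), NA_REAL);

  std::vector<double> yc(n);
  double my = 0.0;
  for (int s = 0; s < n; ++s) my += y[s];
  my /= n;
  double sy2 = 0.0;
  for (int s = 0; s < n; ++s) { yc[s] = y[s] - my; sy2 += yc[s] * yc[s]; }
  if (sy2 <= 0) stop("SOM variance is zero");

  std::vector<double> v(n);
  for (int i = 0; i < B; ++i) {
    const double* Ri = &R(0, i);
    for (int j = 0; j < B; ++j) {
      if (j == i) continue;
      const double* Rj = &R(0, j);
      bool ok = true;
      for (int s = 0; s < n; ++s) {
        double a = Ri[s], b = Rj[s];
        switch (form) {
          case 1: v[s] = a + b; break;
          case 2: v[s] = a - b; break;
          case 3: v[s] = a * b; break;
          case 4:
            if (std::fabs(b) < eps) { ok = false; } else v[s] = a / b;
            break;
          case 5: {
            double den = a + b;
            if (std::fabs(den) < eps) { ok = false; } else v[s] = (a - b) / den;
            break;
          }
          default: stop("form code must be 1..5 for pair scans");
        }
        if (!ok) break;
      }
      if (!ok) continue;
      double rv;
      if (cell_pearson(v.data(), yc.data(), sy2, n, eps, rv)) {
        r(i, j) = rv;
        valid(i, j) = true;
      }
    }
  }
  return List::create(_["r"] = r, _["valid"] = valid);
}

// Triple scan over i in [i_lo, i_hi) (0-based, half-open) so the R wrapper
// can chunk the first axis; the returned slab has dim (i_hi-i_lo, B, B).
// [[Rcpp::export]]
List scan_triples_cpp(NumericMatrix R, NumericVector y, int form, double eps,
                      int i_lo, int i_hi) {
  const int n = R.nrow();
  const int B = R.ncol();
  const int ni = i_hi - i_lo;
  if (ni <= 0 || i_lo < 0 || i_hi > B) stop("bad i range");
  NumericVector r((R_xlen_t)ni * B * B, NA_REAL);
  LogicalVector valid((R_xlen_t)ni * B * B);

  std::vector<double> yc(n);
  double my = 0.0;
  for (int s = 0; s < n; ++s) my += y[s];
  my /= n;
  double sy2 = 0.0;
  for (int s = 0; s < n; ++s) { yc[s] = y[s] - my; sy2 += yc[s] * yc[s]; }
  if (sy2 <= 0) stop("SOM variance is zero");

  if (form < 6 || form > 10) stop("form code must be 6..10 for triple scans");

  // Loop order (j, k) outer, i inner: the denominators of TBI1/TBI2/TBI3
  // and the b - 2c term of TBI5 depend only on (j, k), so their reciprocals
  // are hoisted out of the i loop; only TBI4's denominator involves Ri and
  // is evaluated per cell. Arithmetic per cell is unchanged by chunking.
  std::vector<double> v(n), inv(n), w(n);
  for (int j = 0; j < B; ++j) {
    const double* Rj = &R(0, j);
    for (int k = 0; k < B; ++k) {
      if (k == j) continue;
      const double* Rk = &R(0, k);
      bool jk_ok = true;
      if (form == 6) {          // Ri * inv, inv = 1/(Rj+Rk)
        for (int s = 0; s < n; ++s) {
          double den = Rj[s] + Rk[s];
          if (std::fabs(den) < eps) { jk_ok = false; break; }
          inv[s] = 1.0 / den;
        }
      } else if (form == 7) {   // (Ri+Rj)/Rk = Ri*inv + w
        for (int s = 0; s < n; ++s) {
          if (std::fabs(Rk[s]) < eps) { jk_ok = false; break; }
          inv[s] = 1.0 / Rk[s];
          w[s] = Rj[s] * inv[s];
        }
      } else if (form == 8) {   // (Ri-Rj)/(Rj-Rk) = Ri*inv - w
        for (int s = 0; s < n; ++s) {
          double den = Rj[s] - Rk[s];
          if (std::fabs(den) < eps) { jk_ok = false; break; }
          inv[s] = 1.0 / den;
          w[s] = Rj[s] * inv[s];
        }
      } else if (form == 10) {  // Ri + w, w = Rj - 2 Rk
        for (int s = 0; s < n; ++s) w[s] = Rj[s] - 2.0 * Rk[s];
      }
      if (!jk_ok) continue;
      for (int i = i_lo; i < i_hi; ++i) {
        if (i == j || i == k) continue;
        const double* Ri = &R(0, i);
        bool ok = true;
        switch (form) {
          case 6:
            for (int s = 0; s < n; ++s) v[s] = Ri[s] * inv[s];
            break;
          case 7:
            for (int s = 0; s < n; ++s) v[s] = Ri[s] * inv[s] + w[s];
            break;
          case 8:
            for (int s = 0; s < n; ++s) v[s] = Ri[s] * inv[s] - w[s];
            break;
          case 9:
            for (int s = 0; s < n; ++s) {
              double den = Ri[s] + Rj[s] - 2.0 * Rk[s];
              if (std::fabs(den) < eps) { ok = false; break; }
              v[s] = (Ri[s] - Rj[s]) / den;
            }
            break;
          case 10:
            for (int s = 0; s < n; ++s) v[s] = Ri[s] + w[s];
            break;
        }
        if (!ok) continue;
        double rv;
        if (cell_pearson(v.data(), yc.data(), sy2, n, eps, rv)) {
          R_xlen_t idx = (R_xlen_t)(i - i_lo) +
                         (R_xlen_t)ni * (j + (R_xlen_t)B * k);
          r[idx] = rv;
          valid[idx] = true;
        }
      }
    }
  }
  return List::create(_["r"] = r, _["valid"] = valid);
}
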