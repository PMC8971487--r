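#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Moving extremum over a centred window of k samples (k odd), edges
// truncated (equivalently: padded with -Inf for max / +Inf for min).
// van Herk / Gil-Werman: O(n) per trace independent of k.
static void run_extreme(const double* x, int n, int k, bool take_max,
                        double* out) {
  const double pad = take_max ? -std::numeric_limits<double>::infinity()
                              :  std::numeric_limits<double>::infinity();
  const int h = (k - 1) / 2;
  const int m = n + k - 1;                 // padded length
  const int nb = (m + k - 1) / k;          // number of k-blocks
  const int mp = nb * k;
  std::vector<double> xp(mp, pad), pre(mp), suf(mp);
  for (int i = 0; i < n; ++i) xp[i + h] = x[i];
  for (int b = 0; b < nb; ++b) {
    const int s = b * k, e = s + k - 1;
    pre[s] = xp[s];
    for (int i = s + 1; i <= e; ++i)
      pre[i] = take_max ? std::max(pre[i - 1], xp[i])
                        : std::min(pre[i - 1], xp[i]);
    suf[e] = xp[e];
    for (int i = e - 1; i >= s; --i)
      suf[i] = take_max ? std::max(suf[i + 1], xp[i])
                        : std::min(suf[i + 1], xp[i]);
  }
  for (int i = 0; i < n; ++i) {
    // window in padded coords: [i, i + k - 1]
    const double a = suf[i], b = pre[i + k - 1];
    out[i] = take_max ? std::max(a, b) : std::min(a, b);
  }
}

// Grey-scale morphological opening (erosion then dilation, flat structuring
// element of k samples) applied down each column of X (time x pixels).
// [[Rcpp::export]]
NumericMatrix cpp_opening_cols(NumericMatrix X, int k) {
  const int n = X.nrow(), p = X.ncol();
  if (k < 1 || k % 2 == 0) stop("structuring element length must be odd");
  NumericMatrix out(n, p);
  std::vector<double> ero(n);
  for (int j = 0; j < p; ++j) {
    run_extreme(&X(0, j), n, k, false, ero.data());
    run_extreme(ero.data(), n, k, true, &out(0, j));
  }
  return out;
}

// Per-column APD at `level` percent repolarisation, in ms.
// start = earliest maximum first difference before the peak (frame grid);
// end   = first downward crossing, after the peak, of
//         baseline + (1 - level/100) * (peak - baseline), interpolated;
// baseline = median of the pre-upstroke segment (noise-robust; equals the
// pre-upstroke level exactly on clean traces).  NA when undefined.
// [[Rcpp::export]]
NumericVector cpp_apd_cols(NumericMatrix X, double frame_rate, double level) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector out(p, NA_REAL);
  const double dt_ms = 1000.0 / frame_rate;
  std::vector<double> pre;
  for (int j = 0; j < p; ++j) {
    const double* x = &X(0, j);
    int ipk = 0;
    for (int i = 1; i < n; ++i) if (x[i] > x[ipk]) ipk = i;
    if (ipk == 0 || ipk == n - 1) continue;
    int istart = 0; double dmax = x[1] - x[0];
    for (int i = 1; i < ipk; ++i) {
      const double d = x[i + 1] - x[i];
      if (d > dmax) { dmax = d; istart = i; }
    }
    // baseline: median of samples up to the upstroke start
    pre.assign(x, x + istart + 1);
    const int h = pre.size() / 2;
    std::nth_element(pre.begin(), pre.begin() + h, pre.end());
    double base = pre[h];
    if (pre.size() % 2 == 0) {
      std::nth_element(pre.begin(), pre.begin() + h - 1, pre.end());
      base = (base + pre[h - 1]) / 2.0;
    }
    const double amp = x[ipk] - base;
    if (!(amp > 0)) continue;
    const double L = base + (1.0 - level / 100.0) * amp;
    double tend = NA_REAL;
    for (int i = ipk; i < n - 1; ++i) {
      if (x[i] >= L && x[i + 1] < L) {
        tend = i + (x[i] - L) / (x[i] - x[i + 1]);
        break;
      }
    }
    if (ISNA(tend)) continue;
    out[j] = (tend - istart) * dt_ms;
  }
  return out;
}

// Per-column activation time in ms from window start.
// midpoint: first upward crossing, before the peak, of
//           baseline + 0.5 * (peak - baseline), linearly interpolated;
// max_dvdt: earliest maximum first difference before the peak (frame grid).
// [[Rcpp::export]]
NumericVector cpp_act_cols(NumericMatrix X, double frame_rate, bool midpoint) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector out(p, NA_REAL);
  const double dt_ms = 1000.0 / frame_rate;
  for (int j = 0; j < p; ++j) {
    const double* x = &X(0, j);
    int ipk = 0;
    for (int i = 1; i < n; ++i) if (x[i] > x[ipk]) ipk = i;
    if (ipk == 0) continue;
    double base = x[0];
    for (int i = 1; i < ipk; ++i) if (x[i] < base) base = x[i];
    const double amp = x[ipk] - base;
    if (!(amp > 0)) continue;
    if (midpoint) {
      const double L = base + 0.5 * amp;
      for (int i = 0; i < ipk; ++i) {
        if (x[i] < L && x[i + 1] >= L) {
          out[j] = (i + (L - x[i]) / (x[i + 1] - x[i])) * dt_ms;
          break;
        }
      }
    } else {
      int istart = 0; double dmax = x[1] - x[0];
      for (int i = 1; i < ipk; ++i) {
        const double d = x[i + 1] - x[i];
        if (d > dmax) { dmax = d; istart = i; }
      }
      out[j] = istart * dt_ms;
    }
  }
  return out;
}

// Solve the small normal-equation system G b = r in place (partial
// pivoting); returns false when numerically rank deficient.
static bool solve_small(std::vector<double>& G, std::vector<double>& r,
                        int q) {
  for (int c = 0; c < q; ++c) {
    int piv = c; double best = std::fabs(G[c * q + c]);
    for (int i = c + 1; i < q; ++i) {
      const double v = std::fabs(G[c * q + i]);
      if (v > best) { best = v; piv = i; }
    }
    if (best < 1e-10) return false;
    if (piv != c) {
      for (int cc = 0; cc < q; ++cc) std::swap(G[cc * q + c], G[cc * q + piv]);
      std::swap(r[c], r[piv]);
    }
    const double d = G[c * q + c];
    for (int i = c + 1; i < q; ++i) {
      const double f = G[c * q + i] / d;
      if (f == 0.0) continue;
      for (int cc = c; cc < q; ++cc) G[cc * q + i] -= f * G[cc * q + c];
      r[i] -= f * r[c];
    }
  }
  for (int c = q - 1; c >= 0; --c) {
    double s = r[c];
    for (int cc = c + 1; cc < q; ++cc) s -= G[cc * q + c] * r[cc];
    r[c] = s / G[c * q + c];
  }
  return true;
}

// Local least-squares polynomial surface fit of an activation map over a
// centred (window x window) neighbourhood; returns the gradient (d/dx, d/dy)
// at each pixel, x = column, y = row, in map units per pixel.
// order 1: T = a + b x + c y ; order 2: full second-order polynomial.
// Pixels with fewer than min_points finite neighbours (or a rank-deficient
// fit) are NA.
// [[Rcpp::export]]
List cpp_local_polyfit(NumericMatrix A, int window, int order,
                       int min_points) {
  const int nr = A.nrow(), nc = A.ncol();
  const int h = (window - 1) / 2;
  const int q = (order == 1) ? 3 : 6;
  NumericMatrix gx(nr, nc), gy(nr, nc);
  std::fill(gx.begin(), gx.end(), NA_REAL);
  std::fill(gy.begin(), gy.end(), NA_REAL);
  std::vector<double> G(q * q), rhs(q), phi(q);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!R_finite(A(r, c))) continue;
      std::fill(G.begin(), G.end(), 0.0);
      std::fill(rhs.begin(), rhs.end(), 0.0);
      int npts = 0;
      for (int dr = -h; dr <= h; ++dr) {
        const int rr = r + dr;
        if (rr < 0 || rr >= nr) continue;
        for (int dc = -h; dc <= h; ++dc) {
          const int cc = c + dc;
          if (cc < 0 || cc >= nc) continue;
          const double t = A(rr, cc);
          if (!R_finite(t)) continue;
          const double x = dc, y = dr;
          phi[0] = 1.0; phi[1] = x; phi[2] = y;
          if (q == 6) { phi[3] = x * x; phi[4] = x * y; phi[5] = y * y; }
          for (int a = 0; a < q; ++a) {
            rhs[a] += phi[a] * t;
            for (int b = 0; b <= a; ++b) G[b * q + a] += phi[a] * phi[b];
          }
          ++npts;
        }
      }
      if (npts < min_points || npts < q) continue;
      for (int a = 0; a < q; ++a)
        for (int b = a + 1; b < q; ++b) G[b * q + a] = G[a * q + b];
      std::vector<double> Gc(G), rc(rhs);
      if (!solve_small(Gc, rc, q)) continue;
      gx(r, c) = rc[1];   // derivative wrt x at the centre
      gy(r, c) = rc[2];   // derivative wrt y at the centre
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}
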