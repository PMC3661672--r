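#include <Rcpp.h>
using namespace Rcpp;

// Rediscretize a timestamped planar polyline to constant step length.
// Each output point is exactly `step` away (chord distance) from the previous
// output point and lies on the input polyline; its timestamp is linearly
// interpolated within the original segment carrying it.  The final vertex is
// appended as a (possibly shorter) last step so the trip end is never lost.
// [[Rcpp::export(".redisc_cpp")]]
DataFrame redisc_cpp(NumericVector t, NumericVector x, NumericVector y,
                     double step) {
  const int n = x.size();
  std::vector<double> to, xo, yo;
  double px = x[0], py = y[0];
  to.push_back(t[0]); xo.push_back(px); yo.push_back(py);
  int seg = 0;      // segment holding the current point
  double u0 = 0.0;  // its parameter within that segment
  while (seg < n - 1) {
    bool placed = false;
    for (int j = seg; j < n - 1 && !placed; ++j) {
      const double w0 = (j == seg) ? u0 : 0.0;
      const double dx = x[j + 1] - x[j], dy = y[j + 1] - y[j];
      const double dd = dx * dx + dy * dy;
      if (dd == 0.0) continue;  // duplicated fix position
      // |A + w d - P|^2 = step^2, first root at or beyond w0
      const double ex = x[j] - px, ey = y[j] - py;
      const double b = ex * dx + ey * dy;
      const double c = ex * ex + ey * ey - step * step;
      const double disc = b * b - dd * c;
      if (disc < 0.0) continue;
      const double w = (-b + std::sqrt(disc)) / dd;
      if (w >= w0 - 1e-12 && w <= 1.0 + 1e-12) {
        const double wc = std::min(std::max(w, 0.0), 1.0);
        px = x[j] + wc * dx; py = y[j] + wc * dy;
        to.push_back(t[j] + wc * (t[j + 1] - t[j]));
        xo.push_back(px); yo.push_back(py);
        seg = j; u0 = wc; placed = true;
      }
    }
    if (!placed) break;  // remainder of the polyline lies within one step
  }
  const double fx = x[n - 1] - px, fy = y[n - 1] - py;
  if (std::sqrt(fx * fx + fy * fy) > 1e-9) {
    to.push_back(t[n - 1]); xo.push_back(x[n - 1]); yo.push_back(y[n - 1]);
  }
  return DataFrame::create(_["t"] = to, _["x"] = xo, _["y"] = yo);
}

// First-passage time at every path point for an increasing radius grid.
// For point i and radius r the backward/forward crossing instants are found
// at the first segment on which the distance from point i exceeds r, locating
// the instant by linear interpolation of the distance within that segment.
// NA where the track ends before a crossing.  Because the radii are sorted,
// one forward and one backward scan per point serves the whole grid: the
// first exceedance index is non-decreasing in r.
// [[Rcpp::export(".fpt_matrix_cpp")]]
NumericMatrix fpt_matrix_cpp(NumericVector t, NumericVector x, NumericVector y,
                             NumericVector radii) {
  const int n = x.size(), m = radii.size();
  NumericMatrix out(n, m);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> tf(m), tb(m);
  for (int i = 0; i < n; ++i) {
    int pf = 0;
    double dprev = 0.0;
    for (int j = i + 1; j < n && pf < m; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double d = std::sqrt(dx * dx + dy * dy);
      while (pf < m && d > radii[pf]) {
        const double f = (radii[pf] - dprev) / (d - dprev);
        tf[pf] = t[j - 1] + f * (t[j] - t[j - 1]);
        ++pf;
      }
      dprev = d;
    }
    int pb = 0;
    dprev = 0.0;
    for (int j = i - 1; j >= 0 && pb < m; --j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double d = std::sqrt(dx * dx + dy * dy);
      while (pb < m && d > radii[pb]) {
        const double f = (radii[pb] - dprev) / (d - dprev);
        tb[pb] = t[j + 1] - f * (t[j + 1] - t[j]);
        ++pb;
      }
      dprev = d;
    }
    const int p = pf < pb ? pf : pb;
    for (int q = 0; q < p; ++q) out(i, q) = tf[q] - tb[q];
  }
  return out;
}

// Exact dynamic-programming minimization of the mean-shift Gaussian contrast
// (sum over segments of within-segment squared deviation from the segment
// mean) for every K = 1..Kmax under a minimum segment length Lmin.
// Returns J(K) and, per K, the 1-based indices of the last element of each
// segment but the final one.  Ties resolve to the earliest breakpoint.
// [[Rcpp::export(".lavielle_dp_cpp")]]
List lavielle_dp_cpp(NumericVector z, int Kmax, int Lmin) {
  const int n = z.size();
  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + z[i];
    s2[i + 1] = s2[i] + z[i] * z[i];
  }
  auto cost = [&](int i, int j) {  // inclusive, 0-based
    const int len = j - i + 1;
    const double a = s1[j + 1] - s1[i];
    return (s2[j + 1] - s2[i]) - a * a / len;
  };
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<std::vector<double> > D(Kmax, std::vector<double>(n, INF));
  std::vector<std::vector<int> > back(Kmax, std::vector<int>(n, -1));
  for (int j = Lmin - 1; j < n; ++j) D[0][j] = cost(0, j);
  for (int k = 2; k <= Kmax; ++k) {
    for (int j = k * Lmin - 1; j < n; ++j) {
      double best = INF; int arg = -1;
      for (int i = (k - 1) * Lmin; i <= j - Lmin + 1; ++i) {
        const double v = D[k - 2][i - 1] + cost(i, j);
        if (v < best) { best = v; arg = i; }
      }
      D[k - 1][j] = best; back[k - 1][j] = arg;
    }
  }
  NumericVector J(Kmax, NA_REAL);
  List brks(Kmax);
  for (int k = 1; k <= Kmax; ++k) {
    if ((double)n < (double)k * Lmin) { brks[k - 1] = IntegerVector(0); continue; }
    J[k - 1] = D[k - 1][n - 1];
    IntegerVector b(k - 1);
    int j = n - 1;
    for (int kk = k; kk >= 2; --kk) {
      const int i = back[kk - 1][j];  // 0-based start of segment kk
      b[kk - 2] = i;                  // = 1-based end of segment kk-1
      j = i - 1;
    }
    brks[k - 1] = b;
  }
  return List::create(_["J"] = J, _["breaks"] = brks);
}
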