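#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Natural cubic spline through (xk, yk) (xk strictly increasing), evaluated
// at integer sample positions 0..n-1.  Two knots fall back to a straight
// line.  Evaluation outside the knot range extrapolates the end segments,
// which is safe here because knots are mirror-extended past both ends.
static void natural_spline_eval(const std::vector<double>& xk,
                                const std::vector<double>& yk,
                                int n, std::vector<double>& out) {
  const int m = (int)xk.size();
  if (m < 2) { std::fill(out.begin(), out.end(), m == 1 ? yk[0] : 0.0); return; }
  if (m == 2) {
    const double slope = (yk[1] - yk[0]) / (xk[1] - xk[0]);
    for (int i = 0; i < n; ++i) out[i] = yk[0] + slope * (i - xk[0]);
    return;
  }
  // second derivatives M (natural: M[0] = M[m-1] = 0), Thomas algorithm
  std::vector<double> h(m - 1), mu(m, 0.0), z(m, 0.0), M(m, 0.0);
  for (int i = 0; i < m - 1; ++i) h[i] = xk[i + 1] - xk[i];
  for (int i = 1; i < m - 1; ++i) {
    const double alpha = 3.0 * ((yk[i + 1] - yk[i]) / h[i] -
                                (yk[i] - yk[i - 1]) / h[i - 1]);
    const double l = 2.0 * (xk[i + 1] - xk[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l;
    z[i] = (alpha - h[i - 1] * z[i - 1]) / l;
  }
  for (int i = m - 2; i >= 1; --i) M[i] = z[i] - mu[i] * M[i + 1];
  // evaluate; sample grid is ascending so walk segments once
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    const double x = (double)i;
    while (seg < m - 2 && x > xk[seg + 1]) ++seg;
    const double hj = h[seg];
    const double A = (xk[seg + 1] - x) / hj, B = (x - xk[seg]) / hj;
    out[i] = A * yk[seg] + B * yk[seg + 1] +
             ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) *
                 (hj * hj) / 6.0;
  }
}

// strict local extrema (interior samples only)
static void find_extrema(const std::vector<double>& x, int n,
                         std::vector<int>& imax, std::vector<int>& imin) {
  imax.clear(); imin.clear();
  for (int i = 1; i < n - 1; ++i) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) imax.push_back(i);
    else if (x[i] < x[i - 1] && x[i] < x[i + 1]) imin.push_back(i);
  }
}

// mirror up to two extrema past each end (about the first / last sample)
static void mirrored_knots(const std::vector<int>& idx,
                           const std::vector<double>& x, int n,
                           std::vector<double>& xk, std::vector<double>& yk) {
  const int k = (int)idx.size();
  xk.clear(); yk.clear();
  const int nl = k >= 2 ? 2 : 1, nr = k >= 2 ? 2 : 1;
  for (int j = nl - 1; j >= 0; --j) {
    const double xm = -(double)idx[j];
    if (xm < (double)idx[0]) { xk.push_back(xm); yk.push_back(x[idx[j]]); }
  }
  for (int j = 0; j < k; ++j) { xk.push_back((double)idx[j]); yk.push_back(x[idx[j]]); }
  for (int j = 0; j < nr; ++j) {
    const double xm = 2.0 * (n - 1) - (double)idx[k - 1 - j];
    if (xm > (double)idx[k - 1]) { xk.push_back(xm); yk.push_back(x[idx[k - 1 - j]]); }
  }
}

// One EMD of x: sifting with cubic-spline envelopes, Cauchy-type stop
// criterion sum((h_prev-h)^2)/sum(h_prev^2) < tol, at most max_sift
// sweeps per IMF, mirror-extended boundaries.  Stops when the residual
// has fewer than 3 interior extrema or max_imfs is reached.
// [[Rcpp::export]]
List emd_cpp(NumericVector signal, int max_imfs, int max_sift, double tol) {
  const int n = signal.size();
  std::vector<double> resid(signal.begin(), signal.end());
  std::vector<double> h(n), upper(n), lower(n);
  std::vector<int> imax, imin;
  std::vector<double> xk, yk;
  std::vector<std::vector<double> > imfs;

  for (int k = 0; k < max_imfs; ++k) {
    find_extrema(resid, n, imax, imin);
    if ((int)imax.size() + (int)imin.size() < 3) break;
    h = resid;
    for (int s = 0; s < max_sift; ++s) {
      find_extrema(h, n, imax, imin);
      if (imax.size() < 1 || imin.size() < 1 ||
          imax.size() + imin.size() < 3) break;
      mirrored_knots(imax, h, n, xk, yk);
      natural_spline_eval(xk, yk, n, upper);
      mirrored_knots(imin, h, n, xk, yk);
      natural_spline_eval(xk, yk, n, lower);
      // pointwise Cauchy criterion: SD = sum((h_prev - h)^2 / h_prev^2);
      // on long signals this keeps sifting up to max_sift, as in the
      // canonical fixed-sifting ensemble EMD
      double sd_crit = 0.0;
      for (int i = 0; i < n; ++i) {
        const double m = 0.5 * (upper[i] + lower[i]);
        const double hp = h[i];
        sd_crit += m * m / (hp * hp + 1e-300);
        h[i] -= m;
      }
      if (sd_crit < tol) break;
    }
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) resid[i] -= h[i];
  }

  NumericMatrix M(n, std::max((int)imfs.size(), 1));
  if (imfs.empty()) {
    for (int i = 0; i < n; ++i) M(i, 0) = 0.0;
  } else {
    for (int k = 0; k < (int)imfs.size(); ++k)
      for (int i = 0; i < n; ++i) M(i, k) = imfs[k][i];
  }
  NumericVector r(n);
  for (int i = 0; i < n; ++i) r[i] = resid[i];
  return List::create(_["imfs"] = M, _["residual"] = r,
                      _["n_imfs"] = (int)imfs.size());
}

// Direct-form II transposed IIR filter, a[0] assumed 1 (caller normalizes).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  const int n = x.size(), nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
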