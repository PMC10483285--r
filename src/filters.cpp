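// Fast IIR filtering kernels: direct-form-II-transposed single pass and a
// zero-phase forward-backward pass with steady-state initial conditions and
// odd-reflection edge padding (the usual filtfilt construction).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// One IIR pass with initial state z (length max(nb,na)-1), DF2T.
static void lfilter(const std::vector<double> &b, const std::vector<double> &a,
                    const double *x, double *y, int n, std::vector<double> z) {
  int nf = b.size();               // b and a padded to equal length
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 1; j < nf - 1; ++j) {
      z[j - 1] = b[j] * xi + z[j] - a[j] * yi;
    }
    z[nf - 2] = b[nf - 1] * xi - a[nf - 1] * yi;
    y[i] = yi;
  }
}

// [[Rcpp::export]]
NumericVector cpp_filtfilt(NumericVector bv, NumericVector av,
                           NumericVector xv, NumericVector ziv) {
  int nb = bv.size(), na = av.size();
  int nf = std::max(nb, na);
  std::vector<double> b(nf, 0.0), a(nf, 0.0);
  for (int i = 0; i < nb; ++i) b[i] = bv[i];
  for (int i = 0; i < na; ++i) a[i] = av[i];
  int n = xv.size();
  int pad = 3 * (nf - 1);
  if (pad > n - 1) pad = n - 1;
  int ntot = n + 2 * pad;

  std::vector<double> ext(ntot), tmp(ntot);
  // odd reflection about the end points
  for (int i = 0; i < pad; ++i) ext[i] = 2.0 * xv[0] - xv[pad - i];
  for (int i = 0; i < n; ++i) ext[pad + i] = xv[i];
  for (int i = 0; i < pad; ++i) ext[pad + n + i] = 2.0 * xv[n - 1] - xv[n - 2 - i];

  std::vector<double> z0(ziv.begin(), ziv.end());
  std::vector<double> z(z0.size());

  for (size_t j = 0; j < z.size(); ++j) z[j] = z0[j] * ext[0];
  lfilter(b, a, ext.data(), tmp.data(), ntot, z);
  std::reverse(tmp.begin(), tmp.end());
  for (size_t j = 0; j < z.size(); ++j) z[j] = z0[j] * tmp[0];
  lfilter(b, a, tmp.data(), ext.data(), ntot, z);
  std::reverse(ext.begin(), ext.end());

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ext[pad + i];
  return out;
}

// Normalize a complex matrix to unit modulus in place (phasors for PLV).
// [[Rcpp::export]]
ComplexMatrix cpp_unit_phasor(ComplexMatrix z) {
  int n = z.nrow() * z.ncol();
  Rcomplex *p = z.begin();
  for (int i = 0; i < n; ++i) {
    double m = std::sqrt(p[i].r * p[i].r + p[i].i * p[i].i);
    if (m > 0) { p[i].r /= m; p[i].i /= m; }
    else { p[i].r = 1.0; p[i].i = 0.0; }
  }
  return z;
}

// Sum of band oscillations: for each channel c the contribution
// amp[c] * cos(2*pi*f*t + theta0[c] + j_c(t)) is added to sig (nch x n),
// where j_c is linearly interpolated from OU knots (nk x nch) spaced
// knot_dt apart.
// [[Rcpp::export]]
void cpp_add_band(NumericMatrix sig, double freq, double fs,
                  NumericMatrix knots, double knot_dt,
                  NumericVector amp, NumericVector theta0) {
  int nch = sig.nrow(), n = sig.ncol(), nk = knots.nrow();
  double w = 2.0 * M_PI * freq / fs;
  double step = 1.0 / (fs * knot_dt);   // knot index advance per sample
  double *s0 = sig.begin();
  for (int c = 0; c < nch; ++c) {
    const double *kn = &knots(0, c);
    double a = amp[c], th = theta0[c];
    double *p = s0 + c;
    double tk = 0.0;
    for (int i = 0; i < n; ++i, tk += step) {
      int k0 = (int)tk;
      if (k0 >= nk - 1) k0 = nk - 2;
      double frac = tk - k0;
      double j = kn[k0] + (kn[k0 + 1] - kn[k0]) * frac;
      p[(R_xlen_t)i * nch] += a * std::cos(w * i + th + j);
    }
  }
}

// Add linearly upsampled noise columns (low: m x nch, sampled every
// `decimate` samples) into the channels x n signal matrix.
// [[Rcpp::export]]
void cpp_add_upsampled(NumericMatrix sig, NumericMatrix low, double decimate) {
  int nch = sig.nrow(), n = sig.ncol(), m = low.nrow();
  double *s0 = sig.begin();
  for (int c = 0; c < nch; ++c) {
    const double *lo = &low(0, c);
    double *p = s0 + c;
    double idx = 0.0, step = 1.0 / decimate;
    for (int i = 0; i < n; ++i, idx += step) {
      int k0 = (int)idx;
      if (k0 >= m - 1) k0 = m - 2;
      double frac = idx - k0;
      p[(R_xlen_t)i * nch] += lo[k0] + (lo[k0 + 1] - lo[k0]) * frac;
    }
  }
}

// Apply a cascade of zero-phase IIR filters to every row of x (in place on
// a copy). blist/alist/zlist hold the coefficient sets.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_rows(NumericMatrix x, List blist, List alist,
                                List zlist) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  int nfilt = blist.size();
  std::vector<double> row(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) row[j] = x(i, j);
    NumericVector rv(row.begin(), row.end());
    for (int f = 0; f < nfilt; ++f) {
      rv = cpp_filtfilt(blist[f], alist[f], rv, zlist[f]);
    }
    for (int j = 0; j < nc; ++j) out(i, j) = rv[j];
  }
  return out;
}
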