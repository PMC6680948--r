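// Compiled kernels for the synthetic-signal path: Gaussian / pink noise
// generation, zero-phase IIR filtering, and per-epoch analyzers.  These are
// the only hot loops in the package; month-long records at desk scale make
// pure-R equivalents impractically slow.
#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_gaussian_noise(double n, int seed) {
  R_xlen_t len = (R_xlen_t)n;
  NumericVector out(len);
  std::mt19937_64 rng((uint64_t)(unsigned int)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::normal_distribution<double> norm(0.0, 1.0);
  for (R_xlen_t i = 0; i < len; ++i) out[i] = norm(rng);
  return out;
}

// Economy pink-noise shaping (three-pole IIR approximation to a 1/f
// amplitude spectrum) applied to unit white noise; output rescaled to
// approximately unit variance by a fixed empirical constant.
// [[Rcpp::export]]
NumericVector cpp_pink_noise(double n, int seed) {
  R_xlen_t len = (R_xlen_t)n;
  NumericVector out(len);
  std::mt19937_64 rng((uint64_t)(unsigned int)seed * 0x9E3779B97F4A7C15ULL + 2ULL);
  std::normal_distribution<double> norm(0.0, 1.0);
  double b0 = 0.0, b1 = 0.0, b2 = 0.0;
  for (R_xlen_t i = 0; i < len; ++i) {
    double w = norm(rng);
    b0 = 0.99765 * b0 + w * 0.0990460;
    b1 = 0.96300 * b1 + w * 0.2965164;
    b2 = 0.57000 * b2 + w * 1.0526913;
    out[i] = (b0 + b1 + b2 + w * 0.1848) / 2.9;
  }
  return out;
}

static void iir_forward(const std::vector<double>& b, const std::vector<double>& a,
                        std::vector<double>& x) {
  // direct form II transposed, a[0] assumed 1
  size_t nb = b.size(), na = a.size();
  size_t nz = (nb > na ? nb : na) - 1;
  if (nb == 5 && na == 5) {           // order-4 fast path (our band filters)
    double z0 = 0.0, z1 = 0.0, z2 = 0.0, z3 = 0.0;
    const double b0 = b[0], b1 = b[1], b2 = b[2], b3 = b[3], b4 = b[4];
    const double a1 = a[1], a2 = a[2], a3 = a[3], a4 = a[4];
    for (size_t i = 0; i < x.size(); ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi + z2 - a2 * yi;
      z2 = b3 * xi + z3 - a3 * yi;
      z3 = b4 * xi - a4 * yi;
      x[i] = yi;
    }
    return;
  }
  std::vector<double> z(nz, 0.0);
  for (size_t i = 0; i < x.size(); ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (size_t k = 1; k < nz; ++k) {
      double bk = (k < nb) ? b[k] : 0.0;
      double ak = (k < na) ? a[k] : 0.0;
      z[k - 1] = bk * xi + z[k] - ak * yi;
    }
    if (nz > 0) {
      double bk = (nz < nb) ? b[nz] : 0.0;
      double ak = (nz < na) ? a[nz] : 0.0;
      z[nz - 1] = bk * xi - ak * yi;
    }
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering with odd-reflection edge
// padding to suppress start-up transients.
// [[Rcpp::export]]
NumericVector cpp_filtfilt(NumericVector b, NumericVector a, NumericVector x) {
  R_xlen_t n = x.size();
  if (n == 0) return x;
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  if (aa.empty() || aa[0] == 0.0) stop("invalid filter: a[0] must be nonzero");
  if (aa[0] != 1.0) {
    for (size_t k = 0; k < bb.size(); ++k) bb[k] /= aa[0];
    for (size_t k = 0; k < aa.size(); ++k) aa[k] /= aa[0];
  }
  R_xlen_t order = (R_xlen_t)std::max(bb.size(), aa.size()) - 1;
  R_xlen_t pad = std::min<R_xlen_t>(n - 1, std::max<R_xlen_t>(3 * order, 48));
  std::vector<double> ext(n + 2 * pad);
  for (R_xlen_t i = 0; i < pad; ++i)
    ext[i] = 2.0 * x[0] - x[pad - i];
  for (R_xlen_t i = 0; i < n; ++i) ext[pad + i] = x[i];
  for (R_xlen_t i = 0; i < pad; ++i)
    ext[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  iir_forward(bb, aa, ext);
  std::reverse(ext.begin(), ext.end());
  iir_forward(bb, aa, ext);
  std::reverse(ext.begin(), ext.end());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = ext[pad + i];
  return out;
}

// Per-epoch analyzers on a single filtered channel.  Returns a matrix with
// one row per whole epoch and columns: mean absolute amplitude, average
// power, line length (sum of absolute first differences within the epoch).
// A trailing partial epoch is dropped.
// [[Rcpp::export]]
NumericMatrix cpp_epoch_stats(NumericVector x, int samples_per_epoch) {
  if (samples_per_epoch <= 0) stop("samples_per_epoch must be positive");
  R_xlen_t n = x.size();
  R_xlen_t ne = n / samples_per_epoch;
  NumericMatrix out(ne, 3);
  for (R_xlen_t e = 0; e < ne; ++e) {
    R_xlen_t s = e * (R_xlen_t)samples_per_epoch;
    double maa = 0.0, pw = 0.0, ll = 0.0;
    for (R_xlen_t i = 0; i < samples_per_epoch; ++i) {
      double v = x[s + i];
      maa += std::fabs(v);
      pw += v * v;
      if (i > 0) ll += std::fabs(v - x[s + i - 1]);
    }
    out(e, 0) = maa / samples_per_epoch;
    out(e, 1) = pw / samples_per_epoch;
    out(e, 2) = ll;
  }
  return out;
}
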