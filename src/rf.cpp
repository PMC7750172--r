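// Forward acoustic model kernels: per-pixel superposition of a band-limited
// system response onto element-time RF data, sparse system-matrix assembly,
// and anti-aliased stamping for the phantom rasterizer.
//
// Units: positions mm, times us, frequencies MHz, speed of sound m/s.
// The pulse is sampled at the acquisition rate; pulse_center (1-based) is the
// sample that arrives exactly at t = r/c.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// directivity: 0 = none, 1 = cos(theta) w.r.t. element normal, 2 = hard
// cutoff at cutoff_deg
static inline double directivity_gain(int mode, double ct, double cutoff_cos) {
  if (mode == 0) return 1.0;
  if (ct <= 0.0) return 0.0;
  if (mode == 2) return (ct >= cutoff_cos) ? 1.0 : 0.0;
  return ct;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_rf(NumericVector px, NumericVector pz,
                              NumericVector amp, NumericVector ex,
                              NumericVector ez, NumericVector nx,
                              NumericVector nz, NumericVector pulse,
                              int pulse_center, double fs_MHz, double t0_us,
                              double c_mps, int n_samples, int dir_mode,
                              double cutoff_deg) {
  const int npix = px.size(), nel = ex.size(), plen = pulse.size();
  const double c_mmus = c_mps * 1e-3;  // mm per us
  const double cutoff_cos = std::cos(cutoff_deg * M_PI / 180.0);
  // accumulate into a sample-major buffer so the inner loop is contiguous
  std::vector<double> buf((size_t)n_samples * nel, 0.0);
  for (int p = 0; p < npix; ++p) {
    const double a0 = amp[p];
    if (a0 == 0.0) continue;
    for (int e = 0; e < nel; ++e) {
      const double dx = px[p] - ex[e], dz = pz[p] - ez[e];
      double r = std::sqrt(dx * dx + dz * dz);
      if (r < 0.05) r = 0.05;  // guard against on-element singularity
      const double ct = (dx * nx[e] + dz * nz[e]) / r;
      const double g = directivity_gain(dir_mode, ct, cutoff_cos);
      if (g == 0.0) continue;
      const double a = a0 * g / std::sqrt(r);
      const double s_arr = (r / c_mmus - t0_us) * fs_MHz;  // fractional sample
      int s0 = (int)std::ceil(s_arr - (pulse_center - 1));
      int s1 = (int)std::floor(s_arr + (plen - pulse_center));
      if (s0 < 0) s0 = 0;
      if (s1 > n_samples - 1) s1 = n_samples - 1;
      double* be = buf.data() + (size_t)e * n_samples;
      for (int s = s0; s <= s1; ++s) {
        const double u = (double)s - s_arr + (pulse_center - 1);
        const int i0 = (int)std::floor(u);
        if (i0 < 0 || i0 >= plen) continue;
        const double w = u - i0;
        const double v = (i0 + 1 < plen)
                             ? pulse[i0] * (1.0 - w) + pulse[i0 + 1] * w
                             : pulse[i0] * (1.0 - w);
        be[s] += a * v;
      }
    }
  }
  NumericMatrix rf(nel, n_samples);
  for (int e = 0; e < nel; ++e) {
    const double* be = buf.data() + (size_t)e * n_samples;
    for (int s = 0; s < n_samples; ++s) rf(e, s) = be[s];
  }
  return rf;
}

// Sparse propagation-matrix triplets: row = e + nel*s (column-major RF
// vectorization), one column per pixel.
// [[Rcpp::export]]
List cpp_system_triplets(NumericVector px, NumericVector pz, NumericVector ex,
                         NumericVector ez, NumericVector nx, NumericVector nz,
                         NumericVector pulse, int pulse_center, double fs_MHz,
                         double t0_us, double c_mps, int n_samples,
                         int dir_mode, double cutoff_deg) {
  const int npix = px.size(), nel = ex.size(), plen = pulse.size();
  const double c_mmus = c_mps * 1e-3;
  const double cutoff_cos = std::cos(cutoff_deg * M_PI / 180.0);
  std::vector<int> ri, ci;
  std::vector<double> xv;
  ri.reserve((size_t)npix * nel * plen / 2);
  ci.reserve(ri.capacity());
  xv.reserve(ri.capacity());
  for (int p = 0; p < npix; ++p) {
    for (int e = 0; e < nel; ++e) {
      const double dx = px[p] - ex[e], dz = pz[p] - ez[e];
      double r = std::sqrt(dx * dx + dz * dz);
      if (r < 0.05) r = 0.05;
      const double ct = (dx * nx[e] + dz * nz[e]) / r;
      const double g = directivity_gain(dir_mode, ct, cutoff_cos);
      if (g == 0.0) continue;
      const double a = g / std::sqrt(r);
      const double s_arr = (r / c_mmus - t0_us) * fs_MHz;
      int s0 = (int)std::ceil(s_arr - (pulse_center - 1));
      int s1 = (int)std::floor(s_arr + (plen - pulse_center));
      if (s0 < 0) s0 = 0;
      if (s1 > n_samples - 1) s1 = n_samples - 1;
      for (int s = s0; s <= s1; ++s) {
        const double u = (double)s - s_arr + (pulse_center - 1);
        const int i0 = (int)std::floor(u);
        if (i0 < 0 || i0 >= plen) continue;
        const double w = u - i0;
        const double v = (i0 + 1 < plen)
                             ? pulse[i0] * (1.0 - w) + pulse[i0 + 1] * w
                             : pulse[i0] * (1.0 - w);
        if (v == 0.0) continue;
        ri.push_back(e + nel * s + 1);  // 1-based for Matrix::sparseMatrix
        ci.push_back(p + 1);
        xv.push_back(a * v);
      }
    }
  }
  return List::create(Named("i") = IntegerVector(ri.begin(), ri.end()),
                      Named("j") = IntegerVector(ci.begin(), ci.end()),
                      Named("x") = NumericVector(xv.begin(), xv.end()));
}

// Max-combine anti-aliased stamping of disk cross-sections along sampled
// centrelines; coverage = clamp(radius + 0.5 - dist, 0, 1).
// xs, ys are 0-based pixel coordinates (ys indexes rows).
// [[Rcpp::export]]
NumericMatrix cpp_stamp_points(int nrow, int ncol, NumericVector ys,
                               NumericVector xs, NumericVector radius) {
  NumericMatrix img(nrow, ncol);
  const int n = xs.size();
  for (int k = 0; k < n; ++k) {
    const double x = xs[k], y = ys[k], rad = radius[k];
    const int j0 = std::max(0, (int)std::floor(x - rad - 1.0));
    const int j1 = std::min(ncol - 1, (int)std::ceil(x + rad + 1.0));
    const int i0 = std::max(0, (int)std::floor(y - rad - 1.0));
    const int i1 = std::min(nrow - 1, (int)std::ceil(y + rad + 1.0));
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        const double dxx = j - x, dyy = i - y;
        double cov = rad + 0.5 - std::sqrt(dxx * dxx + dyy * dyy);
        if (cov <= 0.0) continue;
        if (cov > 1.0) cov = 1.0;
        if (cov > img(i, j)) img(i, j) = cov;
      }
    }
  }
  return img;
}
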