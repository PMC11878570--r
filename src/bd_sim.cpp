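#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Expected photon counts per bin for one diffusing species.
//
// Particles start uniform in a periodic box (half-widths half_x/y/z),
// take one Gaussian step per bin with per-bin 1d step SD step_sd
// (length 1 for Brownian motion, length n_bins for time-rescaled
// anomalous increments), and emit with a 3D Gaussian detection
// profile: counts_per_bin * exp(-2(x^2+y^2)/omega1^2 - 2 z^2/omega_z^2).
// Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
NumericVector bd_expected_counts(int n_bins, int n_particles,
                                 NumericVector step_sd,
                                 double omega1, double omega_z,
                                 double half_x, double half_y,
                                 double half_z,
                                 double counts_per_bin) {
  NumericVector lambda(n_bins);
  std::vector<double> x(n_particles), y(n_particles), z(n_particles);
  for (int p = 0; p < n_particles; ++p) {
    x[p] = (2.0 * unif_rand() - 1.0) * half_x;
    y[p] = (2.0 * unif_rand() - 1.0) * half_y;
    z[p] = (2.0 * unif_rand() - 1.0) * half_z;
  }
  const double ax = 2.0 / (omega1 * omega1);
  const double az = 2.0 / (omega_z * omega_z);
  const bool per_bin_sd = step_sd.size() > 1;
  const double wx = 2.0 * half_x, wy = 2.0 * half_y, wz = 2.0 * half_z;
  for (int b = 0; b < n_bins; ++b) {
    const double s = per_bin_sd ? step_sd[b] : step_sd[0];
    double tot = 0.0;
    for (int p = 0; p < n_particles; ++p) {
      double xp = x[p] + s * norm_rand();
      double yp = y[p] + s * norm_rand();
      double zp = z[p] + s * norm_rand();
      // periodic wrap into [-half, half)
      xp -= wx * std::floor((xp + half_x) / wx);
      yp -= wy * std::floor((yp + half_y) / wy);
      zp -= wz * std::floor((zp + half_z) / wz);
      x[p] = xp; y[p] = yp; z[p] = zp;
      const double r2 = ax * (xp * xp + yp * yp) + az * zp * zp;
      if (r2 < 30.0) tot += std::exp(-r2);
    }
    lambda[b] = counts_per_bin * tot;
    if ((b & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return lambda;
}
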