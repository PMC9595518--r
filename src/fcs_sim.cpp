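#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Photon-count trace from Brownian emitters in a periodic box observed
// through a 3D Gaussian detection profile.  Uses R's RNG so set.seed()
// in the calling R code makes the trace reproducible.
//
// Geometry: box is centred on the detection volume, side Lx laterally
// (x and y) and Lz axially; profile exp(-2(x^2+y^2)/w0^2 - 2 z^2/(k w0)^2).
// One Brownian substep per bin (per-axis sd step_sd), periodic wrapping.
// Two-state blinking: stationary dark fraction theta_t, relaxation time
// tau_t (telegraph process).  Optional exponential brightness bleaching.
// [[Rcpp::export]]
NumericVector sim_fcs_counts_cpp(int n_particles, int n_bins, double dt,
                                 double step_sd, double Lx, double Lz,
                                 double w0, double kz,
                                 double brightness, double background_rate,
                                 double theta_t, double tau_t,
                                 double bleach_rate) {
  std::vector<double> x(n_particles), y(n_particles), z(n_particles);
  std::vector<signed char> lit(n_particles, 1);
  const double hx = Lx / 2.0, hz = Lz / 2.0;
  for (int i = 0; i < n_particles; ++i) {
    x[i] = R::runif(-hx, hx);
    y[i] = R::runif(-hx, hx);
    z[i] = R::runif(-hz, hz);
    if (theta_t > 0.0 && R::unif_rand() < theta_t) lit[i] = 0;
  }
  const bool blink = theta_t > 0.0;
  const double p_relax = blink ? (1.0 - std::exp(-dt / tau_t)) : 0.0;
  const double p_bd = theta_t * p_relax;          // bright -> dark
  const double p_db = (1.0 - theta_t) * p_relax;  // dark -> bright
  const double a_lat = 2.0 / (w0 * w0);
  const double wz = kz * w0;
  const double a_ax = 2.0 / (wz * wz);

  NumericVector counts(n_bins);
  for (int t = 0; t < n_bins; ++t) {
    if ((t & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    double b = brightness;
    if (bleach_rate > 0.0) b *= std::exp(-bleach_rate * t * dt);
    double lambda = background_rate * dt;
    for (int i = 0; i < n_particles; ++i) {
      x[i] += R::norm_rand() * step_sd;
      y[i] += R::norm_rand() * step_sd;
      z[i] += R::norm_rand() * step_sd;
      if (x[i] > hx) x[i] -= Lx; else if (x[i] < -hx) x[i] += Lx;
      if (y[i] > hx) y[i] -= Lx; else if (y[i] < -hx) y[i] += Lx;
      if (z[i] > hz) z[i] -= Lz; else if (z[i] < -hz) z[i] += Lz;
      if (blink) {
        if (lit[i]) { if (R::unif_rand() < p_bd) lit[i] = 0; }
        else        { if (R::unif_rand() < p_db) lit[i] = 1; }
      }
      if (lit[i]) {
        lambda += b * dt *
          std::exp(-(x[i] * x[i] + y[i] * y[i]) * a_lat - z[i] * z[i] * a_ax);
      }
    }
    counts[t] = R::rpois(lambda);
  }
  return counts;
}
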