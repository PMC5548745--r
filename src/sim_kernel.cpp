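#include <Rcpp.h>
using namespace Rcpp;

// Brownian-dynamics photon-rate kernel for one molecular species diffusing
// on a periodic 2D membrane patch through two laterally displaced Gaussian
// detection areas.
//
// Detection profile W(r) = exp(-2 r^2 / omega^2); the green focus sits at
// the origin, the red focus at (r0, 0).  Per bin the expected count rate of
// a particle is q_green * W_G for its green label, q_red * W_R for its red
// label, and the green emission additionally leaks into the red channel
// with weight q_cross * W_G (spectral crosstalk).  Positions advance by
// Gaussian steps of sd sqrt(2 D dt) per axis with periodic wrapping, using
// R's RNG so that set.seed() governs reproducibility.
//
// Returns the accumulated *expected* counts per bin for both channels
// (Poisson emission is drawn in R on the summed rates), plus optionally
// the full position history for brute-force cross-checks on tiny systems.
// [[Rcpp::export(name = ".sim_species_kernel")]]
List sim_species_kernel(int n_particles, int n_bins, double dt,
                        double D, double box,
                        double q_green, double q_red, double q_cross,
                        double omega_g, double omega_r, double r0,
                        bool keep_positions = false) {
  NumericVector lam_g(n_bins), lam_r(n_bins);
  if (n_particles == 0) {
    return List::create(_["lambda_green"] = lam_g, _["lambda_red"] = lam_r);
  }
  std::vector<double> px(n_particles), py(n_particles);
  RNGScope scope;
  for (int i = 0; i < n_particles; ++i) {
    px[i] = unif_rand() * box;
    py[i] = unif_rand() * box;
  }
  // centre the foci in the box so particles never straddle the wrap seam
  // while inside the detection area
  const double cx = box / 2.0, cy = box / 2.0;
  const double step = std::sqrt(2.0 * D * dt);
  const double ig2 = 2.0 / (omega_g * omega_g);
  const double ir2 = 2.0 / (omega_r * omega_r);
  // beyond ~4.5 omega the profile is < 1e-17; skip the exp
  const double cut_g = 20.25 * omega_g * omega_g;
  const double cut_r = 20.25 * omega_r * omega_r;
  const bool green_on = (q_green != 0.0) || (q_cross != 0.0);
  const bool red_on = (q_red != 0.0);

  NumericMatrix pos_x, pos_y;
  if (keep_positions) {
    pos_x = NumericMatrix(n_bins, n_particles);
    pos_y = NumericMatrix(n_bins, n_particles);
  }

  for (int t = 0; t < n_bins; ++t) {
    double lg = 0.0, lr = 0.0;
    for (int i = 0; i < n_particles; ++i) {
      double x = px[i] + step * norm_rand();
      double y = py[i] + step * norm_rand();
      x -= box * std::floor(x / box);
      y -= box * std::floor(y / box);
      px[i] = x; py[i] = y;
      if (keep_positions) { pos_x(t, i) = x; pos_y(t, i) = y; }
      const double dxg = x - cx, dyg = y - cy;
      if (green_on) {
        const double r2 = dxg * dxg + dyg * dyg;
        if (r2 < cut_g) {
          const double wg = std::exp(-ig2 * r2);
          lg += q_green * wg;
          lr += q_cross * wg;
        }
      }
      if (red_on) {
        const double dxr = x - (cx + r0);
        const double r2 = dxr * dxr + dyg * dyg;
        if (r2 < cut_r) lr += q_red * std::exp(-ir2 * r2);
      }
    }
    lam_g[t] = lg * dt;
    lam_r[t] = lr * dt;
  }

  if (keep_positions) {
    return List::create(_["lambda_green"] = lam_g, _["lambda_red"] = lam_r,
                        _["x"] = pos_x, _["y"] = pos_y,
                        _["focus_green"] = NumericVector::create(cx, cy),
                        _["focus_red"] = NumericVector::create(cx + r0, cy));
  }
  return List::create(_["lambda_green"] = lam_g, _["lambda_red"] = lam_r);
}

// Multiple-tau style lag sums used by the correlators: for a set of integer
// lags, returns sum(x[t] * y[t + k]), sum(x[t]) and sum(y[t + k]) over the
// overlap window, plus the number of terms.  Plain O(n) per lag; the R side
// handles coarsening.
// [[Rcpp::export(name = ".lag_sums_kernel")]]
List lag_sums_kernel(NumericVector x, NumericVector y, IntegerVector lags) {
  const int n = x.size();
  const int m = lags.size();
  NumericVector sxy(m), sx(m), sy(m);
  IntegerVector cnt(m);
  for (int j = 0; j < m; ++j) {
    const int k = lags[j];
    const int nk = n - k;
    double a = 0.0, b = 0.0, c = 0.0;
    for (int t = 0; t < nk; ++t) {
      a += x[t] * y[t + k];
      b += x[t];
      c += y[t + k];
    }
    sxy[j] = a; sx[j] = b; sy[j] = c; cnt[j] = nk > 0 ? nk : 0;
  }
  return List::create(_["sxy"] = sxy, _["sx"] = sx, _["sy"] = sy,
                      _["n"] = cnt);
}
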