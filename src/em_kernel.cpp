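#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of dx = F(x) dt + sigma dW for an ensemble of
// independent trajectories. Families: 0 = intro_linear (F = -x/2),
// 1 = linear_tilt (F = -(4x^3 - 2x - k)), 2 = cubic_tilt
// (F = -(72x^3 - 3kx^2 - 15x)). Uses R's RNG so set.seed() governs
// reproducibility. Returns the final state of each trajectory.
// [[Rcpp::export]]
NumericVector em_ensemble_cpp(NumericVector x0, int family, double k,
                              double sigma, double dt, int n_steps) {
  int n = x0.size();
  NumericVector x = clone(x0);
  double s = sigma * std::sqrt(dt);
  RNGScope scope;
  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double xi = x[i];
      double f;
      switch (family) {
      case 0: f = -0.5 * xi; break;
      case 1: f = -(4.0 * xi * xi * xi - 2.0 * xi - k); break;
      default: f = -((72.0 * xi - 3.0 * k) * xi * xi - 15.0 * xi); break;
      }
      xi += f * dt + s * norm_rand();
      if (!std::isfinite(xi) || std::fabs(xi) > 1e6)
        stop("simulation overflow in run %d at step %d (dt too large?)",
             i + 1, step + 1);
      x[i] = xi;
    }
  }
  return x;
}
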