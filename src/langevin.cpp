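#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped (Brownian) Euler-Maruyama integrator on a bead-spring
// network:  x <- x - (dt/gamma) * grad U + sqrt(2 kT dt / gamma) * xi
// with U = sum over constraints of 0.5 * k * (d - d0)^2.
// Noise is drawn through R's RNG, so set.seed() on the R side makes the
// trajectory fully deterministic.
//
// Returns an (n_beads x 3 x n_reported) coordinate array; frames are
// recorded every report_every steps (the starting frame is handled on
// the R side). Any coordinate leaving [-sanity_bound, sanity_bound]
// aborts: with a stable timestep the network cannot travel that far.
// [[Rcpp::export]]
NumericVector langevin_core(NumericMatrix x0,
                            IntegerVector ci, IntegerVector cj,
                            NumericVector d0, NumericVector kk,
                            int n_steps, double dt, double kT,
                            double gamma, int report_every,
                            double sanity_bound) {
  const int n = x0.nrow();
  const int m = ci.size();
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = x0(i, d);

  const int n_rep = n_steps / report_every;
  NumericVector frames(Dimension(n, 3, n_rep));
  const double pref = dt / gamma;
  const double noise = (kT > 0.0) ? std::sqrt(2.0 * kT * dt / gamma) : 0.0;
  int fidx = 0;

  for (int s = 1; s <= n_steps; ++s) {
    std::fill(f.begin(), f.end(), 0.0);
    for (int c = 0; c < m; ++c) {
      const int i = ci[c] - 1, j = cj[c] - 1;
      const double dx = x[3 * i] - x[3 * j];
      const double dy = x[3 * i + 1] - x[3 * j + 1];
      const double dz = x[3 * i + 2] - x[3 * j + 2];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < 1e-12) continue;
      const double fm = -kk[c] * (d - d0[c]) / d;
      f[3 * i] += fm * dx; f[3 * i + 1] += fm * dy; f[3 * i + 2] += fm * dz;
      f[3 * j] -= fm * dx; f[3 * j + 1] -= fm * dy; f[3 * j + 2] -= fm * dz;
    }
    for (int i = 0; i < 3 * n; ++i) {
      x[i] += pref * f[i];
      if (noise > 0.0) x[i] += noise * R::norm_rand();
      if (std::fabs(x[i]) > sanity_bound)
        stop("unstable timestep: coordinate exceeded sanity bound at step %d",
             s);
    }
    if (s % report_every == 0) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[fidx * 3 * n + d * n + i] = x[3 * i + d];
      ++fidx;
    }
  }
  return frames;
}
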