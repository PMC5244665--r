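#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step random walk inside an impermeable sphere with radial elastic
// reflection; phase accrual under two rectangular PGSE gradient lobes along z.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector mc_walk_sphere_cpp(int n_walkers, int n_steps, double R,
                                 double step, double dt, double gammaG,
                                 double delta, double Delta) {
  RNGScope scope;
  // integer lobe boundaries so both lobes hold exactly the same step count
  // (floating-point accumulation of t would unbalance them and leave a
  // spurious static phase)
  int n_lobe = (int)std::lround(delta / dt);
  int i_start2 = (int)std::lround(Delta / dt);
  double sum_cos = 0.0, sum_sin = 0.0, sum_cos2 = 0.0;
  const double R2 = R * R;
  for (int w = 0; w < n_walkers; ++w) {
    // uniform start inside the sphere (rejection sampling)
    double x, y, z;
    do {
      x = (2.0 * unif_rand() - 1.0) * R;
      y = (2.0 * unif_rand() - 1.0) * R;
      z = (2.0 * unif_rand() - 1.0) * R;
    } while (x * x + y * y + z * z > R2);
    double phase = 0.0;
    for (int s = 0; s < n_steps; ++s) {
      // uniform direction on the sphere: z ~ U(-1,1), azimuth ~ U(0,2pi)
      double cz = 2.0 * unif_rand() - 1.0;
      double az = 6.283185307179586 * unif_rand();
      double rr = std::sqrt(1.0 - cz * cz);
      x += step * rr * std::cos(az);
      y += step * rr * std::sin(az);
      z += step * cz;
      double r2 = x * x + y * y + z * z;
      while (r2 > R2) {  // radial elastic reflection at the wall
        double r = std::sqrt(r2);
        double fac = (2.0 * R - r) / r;
        x *= fac; y *= fac; z *= fac;
        r2 = x * x + y * y + z * z;
      }
      double z_mid = z - 0.5 * step * cz;  // midpoint rule for phase accrual
      double g = 0.0;
      if (s < n_lobe) g = 1.0;
      else if (s >= i_start2 && s < i_start2 + n_lobe) g = -1.0;
      phase += g * gammaG * z_mid * dt;
    }
    sum_cos += std::cos(phase);
    sum_sin += std::sin(phase);
    sum_cos2 += std::cos(phase) * std::cos(phase);
  }
  double mc = sum_cos / n_walkers;
  double ms = sum_sin / n_walkers;
  double E = std::sqrt(mc * mc + ms * ms);
  double var_cos = sum_cos2 / n_walkers - mc * mc;
  double se = std::sqrt(std::max(var_cos, 0.0) / n_walkers);
  return NumericVector::create(E, se);
}
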