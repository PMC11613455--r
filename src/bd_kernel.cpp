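#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Brownian dynamics of spheres with a smoothed square-well pair
// potential in a cubic periodic box. Forces are in kBT/A; the update is
// x += D * f * dt + sqrt(2 D dt) * xi with minimum-image conventions.
// Uses R's RNG so results are reproducible under set.seed().
//
// Potential (gap g = r - sigma_ij, energies in kBT):
//   g < 0        : 0.5 * k_core * g^2 - eps   (harmonic core)
//   0 <= g <= w-s: -eps                        (flat well)
//   w-s < g < w  : -eps/2 * (1 + cos(pi (g - (w-s)) / s))
//   g >= w       : 0

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// [[Rcpp::export(name = ".bd_run_cpp")]]
NumericVector bd_run_cpp(NumericMatrix x0, NumericVector radii, double L,
                         double D, double dt, double eps, double w, double s,
                         double k_core, int n_steps, int n_equil, int thin) {
  const int N = x0.nrow();
  std::vector<double> x(N * 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = x0(i, d);

  const int n_total = n_equil + n_steps;
  const int n_out = n_steps / thin;
  NumericVector out(Dimension(n_out, N, 3));
  const double sd_step = std::sqrt(2.0 * D * dt);
  const double rcut = 2.0 * (*std::max_element(radii.begin(), radii.end())) + w;
  const double rcut2 = rcut * rcut;
  std::vector<double> f(N * 3);
  int out_i = 0;

  for (int step = 1; step <= n_total; ++step) {
    std::fill(f.begin(), f.end(), 0.0);
    if (eps != 0.0 || k_core != 0.0) {
      for (int i = 0; i < N - 1; ++i) {
        for (int j = i + 1; j < N; ++j) {
          double dv[3], r2 = 0.0;
          for (int d = 0; d < 3; ++d) {
            dv[d] = min_image(x[3 * j + d] - x[3 * i + d], L);
            r2 += dv[d] * dv[d];
          }
          if (r2 >= rcut2) continue;
          const double r = std::sqrt(r2);
          const double g = r - (radii[i] + radii[j]);
          double dudg = 0.0;
          if (g < 0.0) {
            dudg = k_core * g;
          } else if (g > w - s && g < w) {
            dudg = eps * 0.5 * M_PI / s * std::sin(M_PI * (g - (w - s)) / s);
          }
          if (dudg == 0.0 || r <= 0.0) continue;
          for (int d = 0; d < 3; ++d) {
            const double fij = -dudg * dv[d] / r; // force on j
            f[3 * j + d] += fij;
            f[3 * i + d] -= fij;
          }
        }
      }
    }
    for (int i = 0; i < N; ++i) {
      for (int d = 0; d < 3; ++d) {
        double xi = ::norm_rand();
        double xn = x[3 * i + d] + D * f[3 * i + d] * dt + sd_step * xi;
        xn -= L * std::floor(xn / L);
        x[3 * i + d] = xn;
      }
    }
    if (step > n_equil && (step - n_equil) % thin == 0) {
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d)
          out[out_i + n_out * (i + N * d)] = x[3 * i + d];
      ++out_i;
    }
  }
  return out;
}

// Pair forces for a single configuration (test oracle hook).
// [[Rcpp::export(name = ".bd_forces_cpp")]]
NumericMatrix bd_forces_cpp(NumericMatrix x0, NumericVector radii, double L,
                            double eps, double w, double s, double k_core) {
  const int N = x0.nrow();
  NumericMatrix f(N, 3);
  const double rcut = 2.0 * (*std::max_element(radii.begin(), radii.end())) + w;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dv[3], r2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        dv[d] = min_image(x0(j, d) - x0(i, d), L);
        r2 += dv[d] * dv[d];
      }
      if (r2 >= rcut * rcut) continue;
      const double r = std::sqrt(r2);
      const double g = r - (radii[i] + radii[j]);
      double dudg = 0.0;
      if (g < 0.0) {
        dudg = k_core * g;
      } else if (g > w - s && g < w) {
        dudg = eps * 0.5 * M_PI / s * std::sin(M_PI * (g - (w - s)) / s);
      }
      if (dudg == 0.0 || r <= 0.0) continue;
      for (int d = 0; d < 3; ++d) {
        const double fij = -dudg * dv[d] / r;
        f(j, d) += fij;
        f(i, d) -= fij;
      }
    }
  }
  return f;
}
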