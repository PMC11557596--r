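// Brownian dynamics of a confined two-type bead-spring polymer.
//
// Interactions: soft Gaussian exclusion (all pairs), FENE bond (chain
// neighbours), heterochromatin attraction (B-B pairs), repulsive WCA wall
// at the spherical cavity. Forces are the exact analytic gradients of the
// pair energies; the integrator is Euler-Maruyama for the overdamped
// Langevin equation with per-bead Stokes drag 3 pi eta sigma_i.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct PairParams {
  double eps_vex, fene_k, fene_r0_factor, eps_HC, alpha_HC, d_B,
         eps_wall, r_cut_factor;
};

static PairParams read_params(const List& p) {
  PairParams P;
  P.eps_vex = as<double>(p["eps_vex"]);
  P.fene_k = as<double>(p["fene_k"]);
  P.fene_r0_factor = as<double>(p["fene_r0_factor"]);
  P.eps_HC = as<double>(p["eps_HC"]);
  P.alpha_HC = as<double>(p["alpha_HC"]);
  P.d_B = as<double>(p["d_B"]);
  P.eps_wall = as<double>(p["eps_wall"]);
  P.r_cut_factor = as<double>(p["r_cut_factor"]);
  return P;
}

// Accumulate forces and return total potential energy. type: 0 = A, 1 = B.
// bad is set to the 0-based index of a bead with a non-finite interaction
// (FENE overextension), or -1.
static double forces_energy(const double* x, int n, const int* type,
                            const double* sigma, double Rcav,
                            const PairParams& P, double* F, int* bad) {
  *bad = -1;
  double E = 0.0;
  const double hc_cst = P.d_B - 1.0 / (P.alpha_HC * P.d_B);
  std::fill(F, F + 3 * n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = x[i + n], zi = x[i + 2 * n];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - x[j], dy = yi - x[j + n], dz = zi - x[j + 2 * n];
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double sig = 0.5 * (sigma[i] + sigma[j]);
      const double rcut = P.r_cut_factor * sig;
      const bool bonded = (j == i + 1);
      double fpref = 0.0;  // F_i = fpref * (xi - xj), accumulated
      if (r2 <= rcut * rcut) {
        const double a = 4.0 / (sig * sig);
        const double ev = P.eps_vex * std::exp(-a * r2);
        E += ev;
        fpref += 2.0 * a * ev;
        if (P.eps_HC > 0 && type[i] == 1 && type[j] == 1) {
          const double g = std::exp(-P.alpha_HC * (hc_cst + r2));
          E += -P.eps_HC * r2 * g;
          fpref += 2.0 * P.eps_HC * g * (1.0 - P.alpha_HC * r2);
        }
      }
      if (bonded) {
        const double r0 = P.fene_r0_factor * sig;
        const double u = r2 / (r0 * r0);
        if (u >= 1.0) {
          *bad = i;
          return R_PosInf;
        }
        E += -12.0 * P.fene_k * r0 * r0 * std::log(1.0 - u);
        fpref += -24.0 * P.fene_k / (1.0 - u);
      }
      if (fpref != 0.0) {
        F[i] += fpref * dx;          F[j] -= fpref * dx;
        F[i + n] += fpref * dy;      F[j + n] -= fpref * dy;
        F[i + 2 * n] += fpref * dz;  F[j + 2 * n] -= fpref * dz;
      }
    }
    // wall
    const double ri = std::sqrt(xi * xi + yi * yi + zi * zi);
    double riw = Rcav - ri;
    const double si = sigma[i];
    if (riw < 1e-6) riw = 1e-6;  // escaped bead: strong restoring push
    if (riw <= std::pow(2.0, 1.0 / 6.0) * si && ri > 0) {
      const double sr6 = std::pow(si / riw, 6);
      E += 4.0 * P.eps_wall * (sr6 * sr6 - sr6) + P.eps_wall;
      const double dEdr = 4.0 * P.eps_wall * (-12.0 * sr6 * sr6 + 6.0 * sr6) / riw;
      const double c = dEdr / ri;  // F_i = dE/driw * x_i / |x_i|
      F[i] += c * xi;
      F[i + n] += c * yi;
      F[i + 2 * n] += c * zi;
    }
  }
  return E;
}

// [[Rcpp::export]]
List compute_forces_cpp(NumericMatrix pos, IntegerVector type,
                        NumericVector sigma, double cavity_radius,
                        List params) {
  const int n = pos.nrow();
  PairParams P = read_params(params);
  NumericMatrix F(n, 3);
  int bad;
  double E = forces_energy(REAL(pos), n, INTEGER(type), REAL(sigma),
                           cavity_radius, P, REAL(F), &bad);
  return List::create(_["forces"] = F, _["energy"] = E,
                      _["bad_bead"] = bad + 1);
}

// [[Rcpp::export]]
List bd_run_cpp(NumericMatrix pos0, IntegerVector type, NumericVector sigma,
                double cavity_radius, List params, double dt, int n_steps,
                int stride, double kBT, double eta_star) {
  const int n = pos0.nrow();
  PairParams P = read_params(params);
  const int n_snap = n_steps / stride + 1 + ((n_steps % stride) ? 1 : 0);
  NumericVector snaps(Dimension(n, 3, n_snap));
  NumericVector times(n_snap), e_per_bead(n_snap);
  std::vector<double> x(REAL(pos0), REAL(pos0) + 3 * n);
  std::vector<double> F(3 * n), mob(n), nstd(n);
  for (int i = 0; i < n; ++i) {
    const double drag = 3.0 * M_PI * eta_star * sigma[i];
    mob[i] = dt / drag;
    nstd[i] = std::sqrt(2.0 * kBT * dt / drag);
  }
  int bad = -1, k = 0, fail_step = -1;
  for (int s = 0; s <= n_steps; ++s) {
    const bool record = (s % stride == 0) || (s == n_steps);
    double E = 0.0;
    if (record || s < n_steps) {
      E = forces_energy(x.data(), n, INTEGER(type), REAL(sigma),
                        cavity_radius, P, F.data(), &bad);
      if (bad >= 0 || !std::isfinite(E)) { fail_step = s; break; }
    }
    if (record) {
      times[k] = s * dt;
      e_per_bead[k] = E / n;
      std::copy(x.begin(), x.end(), REAL(snaps) + (R_xlen_t)k * 3 * n);
      ++k;
    }
    if (s == n_steps) break;
    bool finite_ok = true;
    for (int i = 0; i < n; ++i) {
      const double m = mob[i], sd = nstd[i];
      for (int d = 0; d < 3; ++d) {
        double& xi = x[i + d * n];
        xi += m * F[i + d * n] + (sd > 0 ? sd * norm_rand() : 0.0);
        if (!std::isfinite(xi)) finite_ok = false;
      }
    }
    if (!finite_ok) { fail_step = s; break; }
  }
  return List::create(_["snapshots"] = snaps, _["times"] = times,
                      _["energy_per_bead"] = e_per_bead,
                      _["n_recorded"] = k, _["fail_step"] = fail_step,
                      _["bad_bead"] = bad + 1);
}
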