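// Parallel-beam tilt-series forward projector and exact adjoint
// (backprojector) for the toy tomography model. Rotation about the y
// axis; bilinear interpolation in the (x, z) plane; ray step of one voxel.
// The same sampling weights are used in both directions, so
// <A x, y> == <x, A^T y> to machine precision.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// vol: nx * ny * nz (column-major), projections: nu(=nx) * nv(=ny) per angle
// [[Rcpp::export]]
NumericVector project_cpp(NumericVector vol, IntegerVector dims,
                          NumericVector angles_rad, double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  NumericVector out((R_xlen_t)nx * ny * na);
  const double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double T = std::sqrt((double)nx * nx + (double)nz * nz) / 2.0 + 1.0;
  for (int a = 0; a < na; ++a) {
    const double st = std::sin(angles_rad[a]), ct = std::cos(angles_rad[a]);
    for (int v = 0; v < ny; ++v) {
      for (int u = 0; u < nx; ++u) {
        const double u0 = u - cx;
        double acc = 0.0;
        for (double t = -T; t <= T; t += step) {
          const double x = cx + u0 * ct + t * st;
          const double z = cz - u0 * st + t * ct;
          const int i0 = (int)std::floor(x), k0 = (int)std::floor(z);
          const double fx = x - i0, fz = z - k0;
          for (int di = 0; di <= 1; ++di)
            for (int dk = 0; dk <= 1; ++dk) {
              const int ii = i0 + di, kk = k0 + dk;
              if (ii < 0 || kk < 0 || ii >= nx || kk >= nz) continue;
              const double w = (di ? fx : 1 - fx) * (dk ? fz : 1 - fz);
              acc += w * vol[(R_xlen_t)kk * nx * ny + (R_xlen_t)v * nx + ii];
            }
        }
        out[(R_xlen_t)a * nx * ny + (R_xlen_t)v * nx + u] = acc * step;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, na);
  return out;
}

// exact adjoint of project_cpp
// [[Rcpp::export]]
NumericVector backproject_cpp(NumericVector proj, IntegerVector dims,
                              NumericVector angles_rad, double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  NumericVector vol((R_xlen_t)nx * ny * nz);
  const double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double T = std::sqrt((double)nx * nx + (double)nz * nz) / 2.0 + 1.0;
  for (int a = 0; a < na; ++a) {
    const double st = std::sin(angles_rad[a]), ct = std::cos(angles_rad[a]);
    for (int v = 0; v < ny; ++v) {
      for (int u = 0; u < nx; ++u) {
        const double u0 = u - cx;
        const double val =
          proj[(R_xlen_t)a * nx * ny + (R_xlen_t)v * nx + u] * step;
        if (val == 0.0) continue;
        for (double t = -T; t <= T; t += step) {
          const double x = cx + u0 * ct + t * st;
          const double z = cz - u0 * st + t * ct;
          const int i0 = (int)std::floor(x), k0 = (int)std::floor(z);
          const double fx = x - i0, fz = z - k0;
          for (int di = 0; di <= 1; ++di)
            for (int dk = 0; dk <= 1; ++dk) {
              const int ii = i0 + di, kk = k0 + dk;
              if (ii < 0 || kk < 0 || ii >= nx || kk >= nz) continue;
              const double w = (di ? fx : 1 - fx) * (dk ? fz : 1 - fz);
              vol[(R_xlen_t)kk * nx * ny + (R_xlen_t)v * nx + ii] += w * val;
            }
        }
      }
    }
  }
  vol.attr("dim") = IntegerVector::create(nx, ny, nz);
  return vol;
}
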