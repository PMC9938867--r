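// Saturating (entropy-type) Hessian-magnitude penalty for the
// missing-cone deconvolution: value and gradient in one or two passes over
// the volume, with periodic boundaries. The hot loop of er_decon().
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int wrap(int i, int n) {
  return i < 0 ? i + n : (i >= n ? i - n : i);
}

// [[Rcpp::export(name = ".er_penalty_cpp")]]
List er_penalty_cpp(NumericVector g, double mu, bool want_grad) {
  IntegerVector dm = g.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const double *G = REAL(g);
  std::vector<double> hxx, hyy, hzz, hxy, hxz, hyz;
  if (want_grad) {
    hxx.resize(N); hyy.resize(N); hzz.resize(N);
    hxy.resize(N); hxz.resize(N); hyz.resize(N);
  }
  double P = 0.0;
  auto idx = [&](int x, int y, int z) {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  };
  for (int z = 0; z < nz; ++z) {
    const int zp = wrap(z + 1, nz), zm = wrap(z - 1, nz);
    for (int y = 0; y < ny; ++y) {
      const int yp = wrap(y + 1, ny), ym = wrap(y - 1, ny);
      for (int x = 0; x < nx; ++x) {
        const int xp = wrap(x + 1, nx), xm = wrap(x - 1, nx);
        const R_xlen_t i = idx(x, y, z);
        const double c = G[i];
        const double axx = G[idx(xp, y, z)] - 2 * c + G[idx(xm, y, z)];
        const double ayy = G[idx(x, yp, z)] - 2 * c + G[idx(x, ym, z)];
        const double azz = G[idx(x, y, zp)] - 2 * c + G[idx(x, y, zm)];
        const double axy = 0.25 * (G[idx(xp, yp, z)] - G[idx(xp, ym, z)] -
                                   G[idx(xm, yp, z)] + G[idx(xm, ym, z)]);
        const double axz = 0.25 * (G[idx(xp, y, zp)] - G[idx(xp, y, zm)] -
                                   G[idx(xm, y, zp)] + G[idx(xm, y, zm)]);
        const double ayz = 0.25 * (G[idx(x, yp, zp)] - G[idx(x, yp, zm)] -
                                   G[idx(x, ym, zp)] + G[idx(x, ym, zm)]);
        const double q = axx * axx + ayy * ayy + azz * azz +
                         2 * (axy * axy + axz * axz + ayz * ayz);
        P += log1p(q / mu);
        if (want_grad) {
          const double w = 1.0 / (mu + q);
          hxx[i] = w * axx; hyy[i] = w * ayy; hzz[i] = w * azz;
          hxy[i] = w * axy; hxz[i] = w * axz; hyz[i] = w * ayz;
        }
      }
    }
  }
  List out = List::create(_["P"] = P);
  if (want_grad) {
    NumericVector grad(N);
    grad.attr("dim") = dm;
    double *GR = REAL(grad);
    for (int z = 0; z < nz; ++z) {
      const int zp = wrap(z + 1, nz), zm = wrap(z - 1, nz);
      for (int y = 0; y < ny; ++y) {
        const int yp = wrap(y + 1, ny), ym = wrap(y - 1, ny);
        for (int x = 0; x < nx; ++x) {
          const int xp = wrap(x + 1, nx), xm = wrap(x - 1, nx);
          const R_xlen_t i = idx(x, y, z);
          const double v =
            hxx[idx(xp, y, z)] - 2 * hxx[i] + hxx[idx(xm, y, z)] +
            hyy[idx(x, yp, z)] - 2 * hyy[i] + hyy[idx(x, ym, z)] +
            hzz[idx(x, y, zp)] - 2 * hzz[i] + hzz[idx(x, y, zm)] +
            0.5 * (hxy[idx(xp, yp, z)] - hxy[idx(xp, ym, z)] -
                   hxy[idx(xm, yp, z)] + hxy[idx(xm, ym, z)]) +
            0.5 * (hxz[idx(xp, y, zp)] - hxz[idx(xp, y, zm)] -
                   hxz[idx(xm, y, zp)] + hxz[idx(xm, y, zm)]) +
            0.5 * (hyz[idx(x, yp, zp)] - hyz[idx(x, yp, zm)] -
                   hyz[idx(x, ym, zp)] + hyz[idx(x, ym, zm)]);
          GR[i] = 2.0 * v;
        }
      }
    }
    out["grad"] = grad;
  }
  return out;
}
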