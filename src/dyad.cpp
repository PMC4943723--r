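#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Steady-state finite-volume reaction-diffusion solver on a voxel grid with
// impermeable obstacle voxels.  Solves, on cytosol voxels,
//   D * Laplacian(c) - vmax * c / (km + c) + src = 0
// with no-flux conditions at obstacle faces and the domain boundary.  The
// Michaelis-Menten sink is handled by Picard iteration (the denominator is
// lagged); each linearised system is symmetric positive definite and solved
// by Jacobi-preconditioned conjugate gradients with matrix-free 7-point
// stencils.  Obstacle voxels never enter the operator, so obstacle-adjacent
// faces carry identically zero flux by construction.

struct Grid {
  int nx, ny, nz;
  const int *mask;  // 0 cytosol, 1 obstacle
  inline int idx(int i, int j, int k) const { return i + nx * (j + ny * k); }
};

// y = A x with A = -(D/h^2) L + diag(kdiag); obstacle voxels carry 0.
static void matvec(const Grid &g, double dh2,
                   const std::vector<double> &kdiag,
                   const std::vector<double> &x, std::vector<double> &y) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int p = g.idx(i, j, k);
        if (g.mask[p]) { y[p] = 0.0; continue; }
        double acc = kdiag[p] * x[p];
        double xi = x[p];
        if (i > 0      && !g.mask[p - 1])        acc += dh2 * (xi - x[p - 1]);
        if (i < nx - 1 && !g.mask[p + 1])        acc += dh2 * (xi - x[p + 1]);
        if (j > 0      && !g.mask[p - nx])       acc += dh2 * (xi - x[p - nx]);
        if (j < ny - 1 && !g.mask[p + nx])       acc += dh2 * (xi - x[p + nx]);
        if (k > 0      && !g.mask[p - nx * ny])  acc += dh2 * (xi - x[p - nx * ny]);
        if (k < nz - 1 && !g.mask[p + nx * ny])  acc += dh2 * (xi - x[p + nx * ny]);
        y[p] = acc;
      }
}

// [[Rcpp::export(name = ".dyad_solve_cpp")]]
List dyad_solve_cpp(IntegerVector mask, int nx, int ny, int nz,
                    double h, double d,
                    NumericVector src,        // uM/s per voxel
                    NumericVector vmax,       // uM/s per voxel (MM numerator)
                    double km,
                    double cg_tol, int cg_maxit,
                    double picard_tol, int picard_maxit) {
  const int n = nx * ny * nz;
  Grid g{nx, ny, nz, INTEGER(mask)};
  const double dh2 = d / (h * h);

  std::vector<double> c(n, 0.0), kdiag(n, 0.0), diagA(n, 0.0);
  std::vector<double> r(n, 0.0), z(n, 0.0), p(n, 0.0), Ap(n, 0.0);

  double bnorm2 = 0.0;
  for (int i = 0; i < n; ++i)
    if (!g.mask[i]) bnorm2 += src[i] * src[i];
  if (bnorm2 == 0.0)
    return List::create(_["c"] = NumericVector(n), _["picard_iters"] = 0,
                        _["cg_iters"] = 0, _["rel_change"] = 0.0,
                        _["converged"] = true);

  int total_cg = 0, pic = 0;
  double rel_change = R_PosInf;
  bool converged = false;

  for (pic = 1; pic <= picard_maxit; ++pic) {
    // lagged Michaelis-Menten coefficient
    for (int i = 0; i < n; ++i) {
      if (g.mask[i]) { kdiag[i] = 0.0; continue; }
      kdiag[i] = vmax[i] / (km + c[i]);
    }
    // Jacobi diagonal of A
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int q = g.idx(i, j, k);
          if (g.mask[q]) { diagA[q] = 1.0; continue; }
          int nb = 0;
          if (i > 0      && !g.mask[q - 1]) ++nb;
          if (i < nx - 1 && !g.mask[q + 1]) ++nb;
          if (j > 0      && !g.mask[q - nx]) ++nb;
          if (j < ny - 1 && !g.mask[q + nx]) ++nb;
          if (k > 0      && !g.mask[q - nx * ny]) ++nb;
          if (k < nz - 1 && !g.mask[q + nx * ny]) ++nb;
          diagA[q] = dh2 * nb + kdiag[q];
          if (diagA[q] <= 0.0) diagA[q] = 1.0;  // isolated voxel guard
        }

    // CG on A c = src, warm-started from the previous Picard iterate
    matvec(g, dh2, kdiag, c, Ap);
    double rz = 0.0;
    for (int i = 0; i < n; ++i) {
      r[i] = g.mask[i] ? 0.0 : (src[i] - Ap[i]);
      z[i] = r[i] / diagA[i];
      p[i] = z[i];
      rz += r[i] * z[i];
    }
    for (int it = 0; it < cg_maxit; ++it) {
      double rn2 = 0.0;
      for (int i = 0; i < n; ++i) rn2 += r[i] * r[i];
      if (rn2 <= cg_tol * cg_tol * bnorm2) break;
      matvec(g, dh2, kdiag, p, Ap);
      double pAp = 0.0;
      for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
      if (pAp <= 0.0) break;
      double alpha = rz / pAp;
      for (int i = 0; i < n; ++i) { c[i] += alpha * p[i]; r[i] -= alpha * Ap[i]; }
      double rznew = 0.0;
      for (int i = 0; i < n; ++i) { z[i] = r[i] / diagA[i]; rznew += r[i] * z[i]; }
      double beta = rznew / rz;
      rz = rznew;
      for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
      ++total_cg;
    }

    // Picard convergence: relative change of the MM coefficient field
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      if (g.mask[i] || vmax[i] <= 0.0) continue;
      double knew = vmax[i] / (km + c[i]);
      num += std::fabs(knew - kdiag[i]);
      den += std::fabs(knew);
    }
    rel_change = (den > 0.0) ? num / den : 0.0;
    if (rel_change < picard_tol) { converged = true; break; }
  }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = c[i];
  return List::create(_["c"] = out, _["picard_iters"] = pic,
                      _["cg_iters"] = total_cg,
                      _["rel_change"] = rel_change,
                      _["converged"] = converged);
}
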