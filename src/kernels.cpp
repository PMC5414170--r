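#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel layouts follow R's column-major order: scalar fields are (nx,ny,nz)
// arrays, tensor fields are (nx,ny,nz,6) with lower-triangular components
// (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) per voxel.

static inline int tcomp(int a, int b) {
  // component index of the symmetric 3x3 tensor in lower-triangular storage
  static const int map[3][3] = {{0, 1, 3}, {1, 2, 4}, {3, 4, 5}};
  return map[a][b];
}

// Mask-aware central difference of c along axis `axis` at every voxel.
// One-sided at the mask/array boundary, zero where no in-mask neighbour
// exists or the voxel itself is outside the mask.
static void masked_gradient(const double *c, const int *mask,
                            const int nx, const int ny, const int nz,
                            const int axis, const double h, double *g) {
  const int stride[3] = {1, nx, nx * ny};
  const int dims[3] = {nx, ny, nz};
  const int s = stride[axis];
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int idx = i + nx * (j + ny * k);
        const int pos[3] = {i, j, k};
        if (!mask[idx]) { g[idx] = 0.0; continue; }
        const bool hasm = pos[axis] > 0 && mask[idx - s];
        const bool hasp = pos[axis] < dims[axis] - 1 && mask[idx + s];
        if (hasm && hasp)      g[idx] = (c[idx + s] - c[idx - s]) / (2.0 * h);
        else if (hasp)         g[idx] = (c[idx + s] - c[idx]) / h;
        else if (hasm)         g[idx] = (c[idx] - c[idx - s]) / h;
        else                   g[idx] = 0.0;
      }
    }
  }
}

// [[Rcpp::export(name = ".div_tensor_flux")]]
NumericVector div_tensor_flux(NumericVector c, NumericVector D,
                              LogicalVector mask, IntegerVector dims,
                              NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (c.size() != nvox || mask.size() != nvox || D.size() != 6 * nvox)
    stop("field/tensor/mask sizes do not match the grid");
  const double *cp = c.begin();
  const double *Dp = D.begin();
  const int *mp = mask.begin();
  const double h[3] = {spacing[0], spacing[1], spacing[2]};

  // precompute mask-aware central gradients along each axis
  std::vector<double> gx(nvox), gy(nvox), gz(nvox);
  masked_gradient(cp, mp, nx, ny, nz, 0, h[0], gx.data());
  masked_gradient(cp, mp, nx, ny, nz, 1, h[1], gy.data());
  masked_gradient(cp, mp, nx, ny, nz, 2, h[2], gz.data());
  const double *grads[3] = {gx.data(), gy.data(), gz.data()};

  NumericVector out(nvox);
  double *divp = out.begin();
  const int stride[3] = {1, nx, nx * ny};
  const int ext[3] = {nx, ny, nz};

  // conservative flux form: loop over in-mask faces, add +/- F/h to the
  // two adjacent voxels; faces touching out-of-mask voxels carry no flux
  for (int a = 0; a < 3; ++a) {
    const int s = stride[a];
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int pos[3] = {i, j, k};
          if (pos[a] >= ext[a] - 1) continue;
          const int p = i + nx * (j + ny * k);
          const int q = p + s;
          if (!mp[p] || !mp[q]) continue;
          double grad_face[3];
          for (int b = 0; b < 3; ++b) {
            if (b == a) grad_face[b] = (cp[q] - cp[p]) / h[a];
            else        grad_face[b] = 0.5 * (grads[b][p] + grads[b][q]);
          }
          double F = 0.0;
          for (int b = 0; b < 3; ++b) {
            const R_xlen_t comp = (R_xlen_t)tcomp(a, b) * nvox;
            const double Dbar = 0.5 * (Dp[comp + p] + Dp[comp + q]);
            F += Dbar * grad_face[b];
          }
          divp[p] += F / h[a];
          divp[q] -= F / h[a];
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Cyclic Jacobi eigendecomposition of a symmetric 3x3 matrix.
// A enters as lower-triangular 6-vector; on exit eval holds eigenvalues
// (descending) and evec the corresponding unit eigenvectors (columns).
static void jacobi_eig3(const double *A6, double *eval, double *evec) {
  double a[3][3] = {{A6[0], A6[1], A6[3]},
                    {A6[1], A6[2], A6[4]},
                    {A6[3], A6[4], A6[5]}};
  double v[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    double diag = std::fabs(a[0][0]) + std::fabs(a[1][1]) + std::fabs(a[2][2]);
    if (off <= 1e-15 * (diag + 1e-300)) break;
    for (int p = 0; p < 2; ++p) {
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-300) continue;
        const double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        const double t = (theta >= 0 ? 1.0 : -1.0) /
                         (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        const double cth = 1.0 / std::sqrt(t * t + 1.0);
        const double sth = t * cth;
        for (int r = 0; r < 3; ++r) {
          const double arp = a[r][p], arq = a[r][q];
          a[r][p] = cth * arp - sth * arq;
          a[r][q] = sth * arp + cth * arq;
        }
        for (int col = 0; col < 3; ++col) {
          const double apc = a[p][col], aqc = a[q][col];
          a[p][col] = cth * apc - sth * aqc;
          a[q][col] = sth * apc + cth * aqc;
        }
        for (int r = 0; r < 3; ++r) {
          const double vrp = v[r][p], vrq = v[r][q];
          v[r][p] = cth * vrp - sth * vrq;
          v[r][q] = sth * vrp + cth * vrq;
        }
      }
    }
  }
  int ord[3] = {0, 1, 2};
  for (int x = 0; x < 2; ++x)
    for (int y = x + 1; y < 3; ++y)
      if (a[ord[y]][ord[y]] > a[ord[x]][ord[x]]) std::swap(ord[x], ord[y]);
  for (int x = 0; x < 3; ++x) {
    eval[x] = a[ord[x]][ord[x]];
    for (int r = 0; r < 3; ++r) evec[r + 3 * x] = v[r][ord[x]];
  }
}

// [[Rcpp::export(name = ".tensor_eigenvalues")]]
NumericMatrix tensor_eigenvalues(NumericVector D, R_xlen_t nvox) {
  if (D.size() != 6 * nvox) stop("tensor array size does not match nvox");
  NumericMatrix out(nvox, 3);
  double A6[6], eval[3], evec[9];
  for (R_xlen_t p = 0; p < nvox; ++p) {
    for (int m = 0; m < 6; ++m) A6[m] = D[(R_xlen_t)m * nvox + p];
    jacobi_eig3(A6, eval, evec);
    out(p, 0) = eval[0]; out(p, 1) = eval[1]; out(p, 2) = eval[2];
  }
  return out;
}

// Raise each in-mask tensor's eigenvalues to `exponent` (eigenvectors kept),
// clamping tiny negative eigenvalues to zero first. Out-of-mask voxels pass
// through unchanged.
// [[Rcpp::export(name = ".power_tensor_eigenvalues")]]
NumericVector power_tensor_eigenvalues(NumericVector D, LogicalVector mask,
                                       double exponent) {
  const R_xlen_t nvox = mask.size();
  if (D.size() != 6 * nvox) stop("tensor array size does not match mask");
  NumericVector out = clone(D);
  double A6[6], eval[3], evec[9];
  for (R_xlen_t p = 0; p < nvox; ++p) {
    if (!mask[p]) continue;
    for (int m = 0; m < 6; ++m) A6[m] = D[(R_xlen_t)m * nvox + p];
    jacobi_eig3(A6, eval, evec);
    double lp[3];
    for (int x = 0; x < 3; ++x)
      lp[x] = std::pow(std::max(eval[x], 0.0), exponent);
    // reassemble V diag(lp) V^T, lower-triangular components
    const int ai[6] = {0, 0, 1, 0, 1, 2};
    const int bi[6] = {0, 1, 1, 2, 2, 2};
    for (int m = 0; m < 6; ++m) {
      double s = 0.0;
      for (int x = 0; x < 3; ++x)
        s += lp[x] * evec[ai[m] + 3 * x] * evec[bi[m] + 3 * x];
      out[(R_xlen_t)m * nvox + p] = s;
    }
  }
  out.attr("dim") = D.attr("dim");
  return out;
}
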