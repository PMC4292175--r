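#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear resampling of a cubic/rectangular volume under a rigid
// transform about the box center: out(x) = in(R^T (x - c - s) + c),
// with x, s in (0-based) voxel coordinates and c = (dim - 1) / 2.
// A feature at c + p maps to c + R p + s. Samples falling outside the
// input grid are set to 0.
// [[Rcpp::export(name = ".rotate_vol")]]
NumericVector rotate_vol(NumericVector vol, IntegerVector dims,
                         NumericMatrix R, NumericVector shift) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  NumericVector out(vol.size());
  const double *in = vol.begin();
  // rows of R^T are columns of R
  const double r11 = R(0,0), r21 = R(1,0), r31 = R(2,0);
  const double r12 = R(0,1), r22 = R(1,1), r32 = R(2,1);
  const double r13 = R(0,2), r23 = R(1,2), r33 = R(2,2);
  for (int k = 0; k < nz; ++k) {
    const double dz = k - cz - shift[2];
    for (int j = 0; j < ny; ++j) {
      const double dy = j - cy - shift[1];
      for (int i = 0; i < nx; ++i) {
        const double dx = i - cx - shift[0];
        // R^T * d
        const double sx = r11 * dx + r21 * dy + r31 * dz + cx;
        const double sy = r12 * dx + r22 * dy + r32 * dz + cy;
        const double sz = r13 * dx + r23 * dy + r33 * dz + cz;
        double val = 0.0;
        if (sx >= 0 && sx <= nx - 1 && sy >= 0 && sy <= ny - 1 &&
            sz >= 0 && sz <= nz - 1) {
          int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
              z0 = (int)std::floor(sz);
          if (x0 == nx - 1) x0--;
          if (y0 == ny - 1) y0--;
          if (z0 == nz - 1) z0--;
          const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          const int b = x0 + nx * (y0 + ny * z0);
          const int sxy = nx * ny;
          const double c00 = in[b] * (1 - fx) + in[b + 1] * fx;
          const double c10 = in[b + nx] * (1 - fx) + in[b + nx + 1] * fx;
          const double c01 = in[b + sxy] * (1 - fx) + in[b + sxy + 1] * fx;
          const double c11 = in[b + sxy + nx] * (1 - fx) + in[b + sxy + nx + 1] * fx;
          const double c0 = c00 * (1 - fy) + c10 * fy;
          const double c1 = c01 * (1 - fy) + c11 * fy;
          val = c0 * (1 - fz) + c1 * fz;
        }
        out[i + nx * (j + ny * k)] = val;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Nearest-correspondence RMSD of point set X against model points M for
// a stack of candidate rotations (3 x 3 x k, column-major):
// rmsd[r] = sqrt(mean_i min_j |R_r x_i - m_j|^2).
// [[Rcpp::export(name = ".grid_nn_rmsd")]]
NumericVector grid_nn_rmsd(NumericMatrix X, NumericMatrix M,
                           NumericVector rots) {
  const int n = X.nrow(), m = M.nrow();
  const int k = rots.size() / 9;
  NumericVector out(k);
  std::vector<double> xv(3 * n), mv(3 * m);
  for (int i = 0; i < n; ++i) {
    xv[3*i] = X(i,0); xv[3*i+1] = X(i,1); xv[3*i+2] = X(i,2);
  }
  for (int j = 0; j < m; ++j) {
    mv[3*j] = M(j,0); mv[3*j+1] = M(j,1); mv[3*j+2] = M(j,2);
  }
  const double *rp = rots.begin();
  for (int r = 0; r < k; ++r) {
    const double *R = rp + 9 * r;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double x = xv[3*i], y = xv[3*i+1], z = xv[3*i+2];
      const double px = R[0]*x + R[3]*y + R[6]*z;
      const double py = R[1]*x + R[4]*y + R[7]*z;
      const double pz = R[2]*x + R[5]*y + R[8]*z;
      double best = R_PosInf;
      const double *mj = mv.data();
      for (int j = 0; j < m; ++j, mj += 3) {
        const double dx = px - mj[0], dy = py - mj[1], dz = pz - mj[2];
        const double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best) best = d2;
      }
      ss += best;
    }
    out[r] = std::sqrt(ss / n);
  }
  return out;
}
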