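#include <Rcpp.h>
using namespace Rcpp;

// Voxel-major patch matrix for a 3D "same"-padded convolution.
// x is laid out column-major with dims (X, Y, Z, C); the returned matrix has
// one row per voxel (x fastest) and one column per (dx, dy, dz, c) kernel tap,
// dx fastest. Padding follows the usual "same" rule: pad_begin = (k - 1) / 2.
// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector x, IntegerVector dims,
                       int kx, int ky, int kz) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int px = (kx - 1) / 2, py = (ky - 1) / 2, pz = (kz - 1) / 2;
  const int nvox = X * Y * Z;
  const int ncol = kx * ky * kz * C;
  NumericMatrix out(nvox, ncol);
  for (int c = 0; c < C; ++c) {
    const double *xc = x.begin() + (R_xlen_t)c * nvox;
    for (int dz = 0; dz < kz; ++dz) {
      for (int dy = 0; dy < ky; ++dy) {
        for (int dx = 0; dx < kx; ++dx) {
          const int col = dx + kx * (dy + ky * (dz + kz * c));
          double *ocol = &out(0, col);
          for (int z = 0; z < Z; ++z) {
            const int zi = z + dz - pz;
            if (zi < 0 || zi >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int yi = y + dy - py;
              if (yi < 0 || yi >= Y) continue;
              const int xi0 = dx - px;
              int xlo = std::max(0, -xi0);
              int xhi = std::min(X, X - xi0);
              const double *src = xc + xi0 + X * (yi + Y * zi);
              double *dst = ocol + X * (y + Y * z);
              for (int xv = xlo; xv < xhi; ++xv) dst[xv] = src[xv];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3d: scatter patch-matrix gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix dcols, IntegerVector dims,
                       int kx, int ky, int kz) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int px = (kx - 1) / 2, py = (ky - 1) / 2, pz = (kz - 1) / 2;
  const int nvox = X * Y * Z;
  NumericVector dx_(nvox * (R_xlen_t)C);
  for (int c = 0; c < C; ++c) {
    double *gc = dx_.begin() + (R_xlen_t)c * nvox;
    for (int dz = 0; dz < kz; ++dz) {
      for (int dy = 0; dy < ky; ++dy) {
        for (int dxk = 0; dxk < kx; ++dxk) {
          const int col = dxk + kx * (dy + ky * (dz + kz * c));
          const double *dc = &dcols(0, col);
          for (int z = 0; z < Z; ++z) {
            const int zi = z + dz - pz;
            if (zi < 0 || zi >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int yi = y + dy - py;
              if (yi < 0 || yi >= Y) continue;
              const int xi0 = dxk - px;
              int xlo = std::max(0, -xi0);
              int xhi = std::min(X, X - xi0);
              double *dst = gc + xi0 + X * (yi + Y * zi);
              const double *src = dc + X * (y + Y * z);
              for (int xv = xlo; xv < xhi; ++xv) dst[xv] += src[xv];
            }
          }
        }
      }
    }
  }
  return dx_;
}

// 2x2x2 max pooling with stride 2 (floor mode: trailing odd planes dropped).
// Returns the pooled values and the 0-based linear argmax index into the input,
// which makes the backward pass a plain scatter.
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int OX = X / 2, OY = Y / 2, OZ = Z / 2;
  if (OX < 1 || OY < 1 || OZ < 1)
    stop("maxpool3d: spatial dims (%d, %d, %d) too small to pool", X, Y, Z);
  const R_xlen_t nout = (R_xlen_t)OX * OY * OZ * C;
  NumericVector out(nout);
  IntegerVector idx(nout);
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    const R_xlen_t coff = (R_xlen_t)c * X * Y * Z;
    for (int z = 0; z < OZ; ++z) {
      for (int y = 0; y < OY; ++y) {
        for (int xv = 0; xv < OX; ++xv) {
          double best = R_NegInf;
          R_xlen_t bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dxk = 0; dxk < 2; ++dxk) {
                const R_xlen_t ii = coff + (2 * xv + dxk) +
                  (R_xlen_t)X * ((2 * y + dy) + (R_xlen_t)Y * (2 * z + dz));
                const double v = x[ii];
                if (v > best) { best = v; bi = ii; }
              }
          out[o] = best;
          idx[o] = (int)bi;
          ++o;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector dout, IntegerVector idx,
                            IntegerVector in_dims) {
  R_xlen_t n = (R_xlen_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector dx_(n);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx_[idx[i]] += dout[i];
  return dx_;
}

// Separable isotropic Gaussian smoothing of a 3D grid, zero background
// outside the volume (appropriate for brain-on-empty-space data).
// [[Rcpp::export]]
NumericVector gauss_smooth3d(NumericVector x, IntegerVector dims, double sigma) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  NumericVector cur = clone(x);
  if (sigma <= 0) return cur;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  NumericVector tmp((R_xlen_t)X * Y * Z);
  const int strides[3] = {1, X, X * Y};
  const int extents[3] = {X, Y, Z};
  for (int axis = 0; axis < 3; ++axis) {
    const int st = strides[axis], n = extents[axis];
    for (int z = 0; z < (axis == 2 ? 1 : Z); ++z) {
      for (int y = 0; y < (axis == 1 ? 1 : Y); ++y) {
        for (int xv = 0; xv < (axis == 0 ? 1 : X); ++xv) {
          const R_xlen_t base = xv + (R_xlen_t)X * (y + (R_xlen_t)Y * z);
          for (int i = 0; i < n; ++i) {
            double acc = 0.0;
            for (int d = -r; d <= r; ++d) {
              const int j = i + d;
              if (j < 0 || j >= n) continue;
              acc += k[d + r] * cur[base + (R_xlen_t)j * st];
            }
            tmp[base + (R_xlen_t)i * st] = acc;
          }
        }
      }
    }
    std::copy(tmp.begin(), tmp.end(), cur.begin());
  }
  cur.attr("dim") = IntegerVector::create(X, Y, Z);
  return cur;
}
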