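// Low-level tensor kernels for the 3D residual U-Net and SSIM.
// Tensors are R arrays in column-major order, spatial dims first:
// x[i, j, k, c] at linear index i + nx*(j + ny*(k + nz*c)).
// Convolutions are 3x3x3, stride 1, zero-padded to "same" size.
// The im2col patch-matrix layout puts, for input channel c and kernel
// offset (kx, ky, kz) in {-1,0,1}^3, the column c*27 + (kx+1) + 3*(ky+1)
// + 9*(kz+1); weight matrices are (27*ci) x co in the same row order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Chunk the z-axis so the input slab stays in L2 while its 27 offset
// copies are gathered, capping the patch matrix at ~32 MB.
static int chunk_slices(int nx, int ny, int nz, int ci) {
  size_t slab = (size_t)nx * ny * ci * 8;            // bytes per input slice
  int zb = (int)std::max((size_t)1, (size_t)1500000 / std::max(slab, (size_t)1));
  size_t per_slice = (size_t)nx * ny * 27 * ci;
  int zb_cap = (int)std::max((size_t)1, (size_t)4000000 / std::max(per_slice, (size_t)1));
  zb = std::min(zb, zb_cap);
  return std::min(zb, nz);
}

static void im2col_chunk(const double* x, int nx, int ny, int nz, int ci,
                         int z0, int zn, arma::mat& P) {
  for (int c = 0; c < ci; ++c) {
    const double* xc = x + (size_t)nx * ny * nz * c;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          int col = c * 27 + (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1);
          double* pcol = P.colptr(col);
          for (int z = 0; z < zn; ++z) {
            int zz = z0 + z + kz;
            bool zok = (zz >= 0 && zz < nz);
            for (int y = 0; y < ny; ++y) {
              int yy = y + ky;
              double* prow = pcol + ((size_t)z * ny + y) * nx;
              if (!zok || yy < 0 || yy >= ny) {
                std::fill(prow, prow + nx, 0.0);
                continue;
              }
              const double* src = xc + ((size_t)zz * ny + yy) * nx;
              if (kx == 0) {
                std::copy(src, src + nx, prow);
              } else if (kx == -1) {
                prow[0] = 0.0;
                std::copy(src, src + nx - 1, prow + 1);
              } else {
                std::copy(src + 1, src + nx, prow);
                prow[nx - 1] = 0.0;
              }
            }
          }
        }
  }
}

// Scatter-add transpose of im2col: dX[v + k, c] += dP[v, (c, k)].
static void col2im_add_chunk(const arma::mat& dP, int nx, int ny, int nz,
                             int ci, int z0, int zn, double* dx) {
  for (int c = 0; c < ci; ++c) {
    double* xc = dx + (size_t)nx * ny * nz * c;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          int col = c * 27 + (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1);
          const double* pcol = dP.colptr(col);
          for (int z = 0; z < zn; ++z) {
            int zz = z0 + z + kz;
            if (zz < 0 || zz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              int yy = y + ky;
              if (yy < 0 || yy >= ny) continue;
              const double* prow = pcol + ((size_t)z * ny + y) * nx;
              double* dst = xc + ((size_t)zz * ny + yy) * nx;
              if (kx == 0) {
                for (int i = 0; i < nx; ++i) dst[i] += prow[i];
              } else if (kx == -1) {
                for (int i = 1; i < nx; ++i) dst[i - 1] += prow[i];
              } else {
                for (int i = 0; i < nx - 1; ++i) dst[i + 1] += prow[i];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, IntegerVector dims,
                        NumericMatrix W, NumericVector b) {
  int nx = dims[0], ny = dims[1], nz = dims[2], ci = dims[3];
  int co = W.ncol();
  if (W.nrow() != 27 * ci) stop("weight matrix rows must equal 27*ci");
  arma::mat Wm(W.begin(), W.nrow(), co, false);
  NumericVector out((size_t)nx * ny * nz * co);
  int zb = chunk_slices(nx, ny, nz, ci);
  arma::mat P((size_t)nx * ny * zb, 27 * ci);
  for (int z0 = 0; z0 < nz; z0 += zb) {
    int zn = std::min(zb, nz - z0);
    if (zn != zb) P.set_size((size_t)nx * ny * zn, 27 * ci);
    im2col_chunk(x.begin(), nx, ny, nz, ci, z0, zn, P);
    arma::mat Y = P * Wm;
    for (int c = 0; c < co; ++c) {
      double bias = b[c];
      const double* ycol = Y.colptr(c);
      double* dst = out.begin() + (size_t)nx * ny * nz * c + (size_t)nx * ny * z0;
      size_t n = (size_t)nx * ny * zn;
      for (size_t i = 0; i < n; ++i) dst[i] = ycol[i] + bias;
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, co);
  return out;
}

// Destructive ReLU: clamps negative entries of a freshly allocated conv
// output in place (the caller owns the only reference).
// [[Rcpp::export]]
NumericVector relu_fw_inplace(NumericVector z) {
  double* p = z.begin();
  for (R_xlen_t i = 0; i < z.size(); ++i)
    if (p[i] < 0) p[i] = 0;
  return z;
}

// Destructive ReLU backward: da *= (a > 0), where a is the stored
// post-activation.
// [[Rcpp::export]]
NumericVector relu_bw_inplace(NumericVector da, NumericVector a) {
  if (da.size() != a.size()) stop("relu_bw_inplace: size mismatch");
  double* d = da.begin();
  const double* ap = a.begin();
  for (R_xlen_t i = 0; i < da.size(); ++i)
    if (ap[i] <= 0) d[i] = 0;
  return da;
}

// Channel concatenation of two 4D tensors sharing spatial dims.
// [[Rcpp::export]]
NumericVector concat4(NumericVector a, IntegerVector da,
                      NumericVector b, IntegerVector db) {
  size_t sa = (size_t)da[0] * da[1] * da[2];
  if (sa != (size_t)db[0] * db[1] * db[2]) stop("concat4: spatial dims differ");
  NumericVector out(sa * (da[3] + db[3]));
  std::copy(a.begin(), a.end(), out.begin());
  std::copy(b.begin(), b.end(), out.begin() + sa * da[3]);
  out.attr("dim") = IntegerVector::create(da[0], da[1], da[2], da[3] + db[3]);
  return out;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, IntegerVector dims, NumericMatrix W,
               NumericVector dy, bool need_dx = true) {
  int nx = dims[0], ny = dims[1], nz = dims[2], ci = dims[3];
  int co = W.ncol();
  arma::mat Wm(W.begin(), W.nrow(), co, false);
  arma::mat dW(27 * ci, co, arma::fill::zeros);
  arma::vec db(co, arma::fill::zeros);
  NumericVector dx((size_t)nx * ny * nz * ci);
  int zb = chunk_slices(nx, ny, nz, ci);
  arma::mat P((size_t)nx * ny * zb, 27 * ci);
  arma::mat dY((size_t)nx * ny * zb, co);
  for (int z0 = 0; z0 < nz; z0 += zb) {
    int zn = std::min(zb, nz - z0);
    if (zn != zb) {
      P.set_size((size_t)nx * ny * zn, 27 * ci);
      dY.set_size((size_t)nx * ny * zn, co);
    }
    im2col_chunk(x.begin(), nx, ny, nz, ci, z0, zn, P);
    size_t n = (size_t)nx * ny * zn;
    for (int c = 0; c < co; ++c) {
      const double* src = dy.begin() + (size_t)nx * ny * nz * c + (size_t)nx * ny * z0;
      std::copy(src, src + n, dY.colptr(c));
    }
    dW += P.t() * dY;
    db += arma::sum(dY, 0).t();
    if (need_dx) {
      arma::mat dP = dY * Wm.t();
      col2im_add_chunk(dP, nx, ny, nz, ci, z0, zn, dx.begin());
    }
  }
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, ci);
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW), _["db"] = wrap(db));
}

// 2x max pooling over the three spatial dims; spatial dims must be even.
// Returns pooled values plus the winning linear index (1-based, into x)
// per output voxel, for the backward pass.
// [[Rcpp::export]]
List maxpool3d_fw(NumericVector x, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool3d_fw: spatial dims must be even");
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  NumericVector y((size_t)ox * oy * oz * nc);
  IntegerVector idx((size_t)ox * oy * oz * nc);
  const double* xp = x.begin();
  size_t o = 0;
  for (int c = 0; c < nc; ++c) {
    size_t cbase = (size_t)nx * ny * nz * c;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dyy = 0; dyy < 2; ++dyy)
              for (int dxx = 0; dxx < 2; ++dxx) {
                size_t li = cbase + (size_t)(2 * i + dxx) +
                            (size_t)nx * ((2 * j + dyy) + (size_t)ny * (2 * k + dz));
                if (xp[li] > best) { best = xp[li]; bidx = li; }
              }
          y[o] = best;
          idx[o] = (int)(bidx + 1);
        }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw(IntegerVector idx, NumericVector dy,
                           IntegerVector in_dims) {
  NumericVector dx((size_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3]);
  for (R_xlen_t o = 0; o < dy.size(); ++o) dx[idx[o] - 1] += dy[o];
  dx.attr("dim") = in_dims;
  return dx;
}

// Nearest-neighbour 2x upsampling of the spatial dims.
// [[Rcpp::export]]
NumericVector upsample3d_nn_fw(NumericVector x, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericVector y((size_t)ox * oy * oz * nc);
  for (int c = 0; c < nc; ++c) {
    size_t ib = (size_t)nx * ny * nz * c, ob = (size_t)ox * oy * oz * c;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j) {
        const double* src = x.begin() + ib + (size_t)nx * ((j / 2) + (size_t)ny * (k / 2));
        double* dst = y.begin() + ob + (size_t)ox * (j + (size_t)oy * k);
        for (int i = 0; i < ox; ++i) dst[i] = src[i / 2];
      }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample3d_nn_bw(NumericVector dy, IntegerVector out_dims) {
  // out_dims are the dims of the *input* of the forward op.
  int nx = out_dims[0], ny = out_dims[1], nz = out_dims[2], nc = out_dims[3];
  int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericVector dx((size_t)nx * ny * nz * nc);
  for (int c = 0; c < nc; ++c) {
    size_t ib = (size_t)nx * ny * nz * c, ob = (size_t)ox * oy * oz * c;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j) {
        const double* src = dy.begin() + ob + (size_t)ox * (j + (size_t)oy * k);
        double* dst = dx.begin() + ib + (size_t)nx * ((j / 2) + (size_t)ny * (k / 2));
        for (int i = 0; i < ox; ++i) dst[i / 2] += src[i];
      }
  }
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return dx;
}

// Separable 3D convolution of a single-channel volume with a 1D kernel
// applied along each axis in turn, zero-padded. Used by the SSIM filter.
// [[Rcpp::export]]
NumericVector sepconv3d(NumericVector x, IntegerVector dims, NumericVector k) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int kl = k.size(), h = kl / 2;
  if (kl % 2 == 0) stop("sepconv3d: kernel length must be odd");
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(x.begin(), x.begin() + n), tmp(n, 0.0);
  // axis strides
  int dimlen[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    int len = dimlen[ax];
    size_t st = stride[ax];
    size_t nlines = n / len;
    std::fill(tmp.begin(), tmp.end(), 0.0);
    // enumerate lines: iterate all voxels with coordinate 0 along ax
    for (size_t v = 0; v < n; ++v) {
      // coordinate along axis
      size_t coord = (v / st) % len;
      if (coord != 0) continue;
      // convolve this line
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int t = -h; t <= h; ++t) {
          int s = i + t;
          if (s < 0 || s >= len) continue;
          acc += a[v + (size_t)s * st] * k[t + h];
        }
        tmp[v + (size_t)i * st] = acc;
      }
    }
    a.swap(tmp);
    (void)nlines;
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
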