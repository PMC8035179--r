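// Low-level volumetric kernels: affine resampling, separable Gaussian blur,
// 3x3x3 convolution forward/backward (via 27 shifted GEMMs), 2x2x2 max pooling,
// nearest-neighbour upsampling, 6-connected component labelling, and a 2D
// Euclidean distance transform. All tensors are plain R arrays; network
// tensors use channel-first layout (C, X, Y, Z) so each voxel's channel
// vector is contiguous.
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- affine resampling -----------------------------------------------------
// M is 3x4 mapping 0-based output voxel index (i,j,k) to continuous 0-based
// source voxel coordinates. interp: 0 = nearest, 1 = trilinear.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector sdim,
                                  IntegerVector odim, NumericMatrix M,
                                  int interp, double fill) {
  const int SX = sdim[0], SY = sdim[1], SZ = sdim[2];
  const int OX = odim[0], OY = odim[1], OZ = odim[2];
  NumericVector out((R_xlen_t)OX * OY * OZ);
  const double *s = src.begin();
  double *o = out.begin();
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t n = 0;
  for (int k = 0; k < OZ; ++k) {
    for (int j = 0; j < OY; ++j) {
      for (int i = 0; i < OX; ++i, ++n) {
        const double qx = m00*i + m01*j + m02*k + m03;
        const double qy = m10*i + m11*j + m12*k + m13;
        const double qz = m20*i + m21*j + m22*k + m23;
        if (interp == 0) {
          const int xi = (int)std::lround(qx), yi = (int)std::lround(qy),
                    zi = (int)std::lround(qz);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= SX || yi >= SY || zi >= SZ) {
            o[n] = fill;
          } else {
            o[n] = s[(R_xlen_t)xi + (R_xlen_t)SX*(yi + (R_xlen_t)SY*zi)];
          }
        } else {
          if (qx < 0 || qy < 0 || qz < 0 ||
              qx > SX - 1 || qy > SY - 1 || qz > SZ - 1) {
            o[n] = fill;
            continue;
          }
          int x0 = (int)std::floor(qx), y0 = (int)std::floor(qy),
              z0 = (int)std::floor(qz);
          if (x0 == SX - 1) x0--;
          if (y0 == SY - 1) y0--;
          if (z0 == SZ - 1) z0--;
          const double fx = qx - x0, fy = qy - y0, fz = qz - z0;
          const R_xlen_t base = (R_xlen_t)x0 + (R_xlen_t)SX*(y0 + (R_xlen_t)SY*z0);
          const R_xlen_t dy = SX, dz = (R_xlen_t)SX * SY;
          const double c000 = s[base],          c100 = s[base + 1];
          const double c010 = s[base + dy],     c110 = s[base + dy + 1];
          const double c001 = s[base + dz],     c101 = s[base + dz + 1];
          const double c011 = s[base + dy + dz], c111 = s[base + dy + dz + 1];
          const double c00 = c000*(1-fx) + c100*fx;
          const double c10 = c010*(1-fx) + c110*fx;
          const double c01 = c001*(1-fx) + c101*fx;
          const double c11 = c011*(1-fx) + c111*fx;
          const double c0 = c00*(1-fy) + c10*fy;
          const double c1 = c01*(1-fy) + c11*fy;
          o[n] = c0*(1-fz) + c1*fz;
        }
      }
    }
  }
  return out;
}

// ---- separable Gaussian blur ----------------------------------------------
static void blur_axis(std::vector<double> &v, int X, int Y, int Z,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> ker(2*r + 1);
  double ksum = 0.0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    ksum += ker[t + r];
  }
  for (double &kk : ker) kk /= ksum;
  const R_xlen_t sx = 1, sy = X, sz = (R_xlen_t)X * Y;
  const R_xlen_t stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;
  const int len = (axis == 0) ? X : (axis == 1) ? Y : Z;
  std::vector<double> line(len);
  // iterate over all lines along `axis`
  const int d1 = (axis == 0) ? Y : X;
  const int d2 = (axis == 2) ? Y : Z;
  const R_xlen_t s1 = (axis == 0) ? sy : sx;
  const R_xlen_t s2 = (axis == 2) ? sy : sz;
  for (int b = 0; b < d2; ++b) {
    for (int a = 0; a < d1; ++a) {
      const R_xlen_t base = a*s1 + b*s2;
      for (int t = 0; t < len; ++t) line[t] = v[base + t*stride];
      for (int t = 0; t < len; ++t) {
        double acc = 0.0;
        const int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
        for (int u = lo; u <= hi; ++u) acc += line[u] * ker[u - t + r];
        v[base + t*stride] = acc;
      }
    }
  }
}

// sigma given in voxel units per axis; zero-padding outside the field.
// [[Rcpp::export]]
NumericVector gauss_blur_cpp(NumericVector vol, IntegerVector dim,
                             NumericVector sigma) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, X, Y, Z, 0, sigma[0]);
  blur_axis(v, X, Y, Z, 1, sigma[1]);
  blur_axis(v, X, Y, Z, 2, sigma[2]);
  return NumericVector(v.begin(), v.end());
}

// ---- 3x3x3 convolution -----------------------------------------------------
// Blocked im2col: K holds, for a block of output voxels [n0, n1), the 27*Ci
// input values feeding each voxel (column-major, offset-major rows). A single
// (Co x 27Ci) x (27Ci x nb) GEMM per block keeps BLAS efficient even for a
// handful of channels.
static void im2col_block(const double *x, int Ci, int X, int Y, int Z,
                         R_xlen_t n0, R_xlen_t n1, arma::mat &K) {
  const int nb = (int)(n1 - n0);
  int i = (int)(n0 % X);
  int j = (int)((n0 / X) % Y);
  int k = (int)(n0 / ((R_xlen_t)X * Y));
  const size_t chunk = sizeof(double) * Ci;
  for (int n = 0; n < nb; ++n) {
    double *dst = K.colptr(n);
    for (int dz = -1; dz <= 1; ++dz) {
      const int sk = k + dz;
      const bool okz = sk >= 0 && sk < Z;
      for (int dy = -1; dy <= 1; ++dy) {
        const int sj = j + dy;
        const bool oky = okz && sj >= 0 && sj < Y;
        const R_xlen_t base = (R_xlen_t)X * (sj + (R_xlen_t)Y * sk);
        for (int dx = -1; dx <= 1; ++dx, dst += Ci) {
          const int si = i + dx;
          if (oky && si >= 0 && si < X)
            std::memcpy(dst, x + (base + si) * Ci, chunk);
          else
            std::memset(dst, 0, chunk);
        }
      }
    }
    if (++i == X) { i = 0; if (++j == Y) { j = 0; ++k; } }
  }
}

static const int CONV_BLOCK = 8192;

// x: (Ci, X, Y, Z); w: (Co, Ci, 3, 3, 3) reshaped as (Co x 27Ci) with
// offset-major column order matching im2col_block; b: Co. 'same' zero pad.
// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector w, NumericVector b) {
  const int Ci = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Co = b.size();
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  // reorder w (Co,Ci,3,3,3) -> Wm (Co x 27Ci), columns (offset, ci)
  arma::mat Wm(Co, 27 * Ci);
  for (int o = 0; o < 27; ++o)
    for (int c = 0; c < Ci; ++c)
      for (int r = 0; r < Co; ++r)
        Wm(r, o * Ci + c) = w[r + (R_xlen_t)Co * (c + (R_xlen_t)Ci * o)];
  arma::colvec bv(const_cast<double*>(b.begin()), Co, false, true);
  NumericVector out((R_xlen_t)Co * N);
  arma::mat K(27 * Ci, CONV_BLOCK);
  for (R_xlen_t n0 = 0; n0 < N; n0 += CONV_BLOCK) {
    const R_xlen_t n1 = std::min(n0 + CONV_BLOCK, N);
    const int nb = (int)(n1 - n0);
    arma::mat Kb = K.cols(0, nb - 1);
    im2col_block(x.begin(), Ci, X, Y, Z, n0, n1, Kb);
    arma::mat Yb(out.begin() + n0 * Co, Co, nb, false, true);
    Yb = Wm * Kb;
    Yb.each_col() += bv;
  }
  out.attr("dim") = IntegerVector::create(Co, X, Y, Z);
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericVector w, NumericVector dy_, IntegerVector ydim) {
  const int Ci = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Co = ydim[0];
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  arma::mat Wm(Co, 27 * Ci);
  for (int o = 0; o < 27; ++o)
    for (int c = 0; c < Ci; ++c)
      for (int r = 0; r < Co; ++r)
        Wm(r, o * Ci + c) = w[r + (R_xlen_t)Co * (c + (R_xlen_t)Ci * o)];
  NumericVector dxv((R_xlen_t)Ci * N);
  NumericVector dwv(w.size());
  NumericVector dbv(Co);
  arma::mat dWm(Co, 27 * Ci, arma::fill::zeros);
  arma::colvec db(Co, arma::fill::zeros);
  arma::mat K(27 * Ci, CONV_BLOCK);
  for (R_xlen_t n0 = 0; n0 < N; n0 += CONV_BLOCK) {
    const R_xlen_t n1 = std::min(n0 + CONV_BLOCK, N);
    const int nb = (int)(n1 - n0);
    arma::mat Kb = K.cols(0, nb - 1);
    im2col_block(x.begin(), Ci, X, Y, Z, n0, n1, Kb);
    arma::mat dYb(const_cast<double*>(dy_.begin()) + n0 * Co, Co, nb,
                  false, true);
    dWm += dYb * Kb.t();
    db += arma::sum(dYb, 1);
    arma::mat dK = Wm.t() * dYb;          // (27Ci x nb)
    // col2im scatter-add
    double *dxp = dxv.begin();
    int i = (int)(n0 % X);
    int j = (int)((n0 / X) % Y);
    int k = (int)(n0 / ((R_xlen_t)X * Y));
    for (int n = 0; n < nb; ++n) {
      const double *src = dK.colptr(n);
      for (int dz = -1; dz <= 1; ++dz) {
        const int sk = k + dz;
        const bool okz = sk >= 0 && sk < Z;
        for (int dy = -1; dy <= 1; ++dy) {
          const int sj = j + dy;
          const bool oky = okz && sj >= 0 && sj < Y;
          const R_xlen_t base = (R_xlen_t)X * (sj + (R_xlen_t)Y * sk);
          for (int dx = -1; dx <= 1; ++dx, src += Ci) {
            const int si = i + dx;
            if (!(oky && si >= 0 && si < X)) continue;
            double *dst = dxp + (base + si) * Ci;
            for (int c = 0; c < Ci; ++c) dst[c] += src[c];
          }
        }
      }
      if (++i == X) { i = 0; if (++j == Y) { j = 0; ++k; } }
    }
  }
  // reorder dWm back to (Co,Ci,3,3,3)
  for (int o = 0; o < 27; ++o)
    for (int c = 0; c < Ci; ++c)
      for (int r = 0; r < Co; ++r)
        dwv[r + (R_xlen_t)Co * (c + (R_xlen_t)Ci * o)] = dWm(r, o * Ci + c);
  std::memcpy(dbv.begin(), db.memptr(), sizeof(double) * Co);
  dxv.attr("dim") = xdim;
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// ---- 2x2x2 max pooling -----------------------------------------------------
// [[Rcpp::export]]
List pool2_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int OX = X/2, OY = Y/2, OZ = Z/2;
  const R_xlen_t NO = (R_xlen_t)C * OX * OY * OZ;
  NumericVector y(NO);
  IntegerVector idx(NO);  // 0-based linear index into x
  const double *xp = x.begin();
  R_xlen_t n = 0;
  for (int k = 0; k < OZ; ++k)
    for (int j = 0; j < OY; ++j)
      for (int i = 0; i < OX; ++i)
        for (int c = 0; c < C; ++c, ++n) {
          double best = -INFINITY; R_xlen_t bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dyy = 0; dyy < 2; ++dyy)
              for (int dxx = 0; dxx < 2; ++dxx) {
                const R_xlen_t p = c + (R_xlen_t)C*((2*i+dxx) +
                    (R_xlen_t)X*((2*j+dyy) + (R_xlen_t)Y*(2*k+dz)));
                if (xp[p] > best) { best = xp[p]; bidx = p; }
              }
          y[n] = best; idx[n] = (int)bidx;
        }
  y.attr("dim") = IntegerVector::create(C, OX, OY, OZ);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool2_bwd_cpp(NumericVector dy, IntegerVector idx,
                            IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0]*xdim[1]*xdim[2]*xdim[3]);
  for (R_xlen_t n = 0; n < dy.size(); ++n) dx[idx[n]] += dy[n];
  dx.attr("dim") = xdim;
  return dx;
}

// ---- nearest-neighbour 2x upsampling ---------------------------------------
// [[Rcpp::export]]
NumericVector upsample2_cpp(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int OX = 2*X, OY = 2*Y, OZ = 2*Z;
  NumericVector y((R_xlen_t)C * OX * OY * OZ);
  const double *xp = x.begin();
  double *yp = y.begin();
  R_xlen_t n = 0;
  for (int k = 0; k < OZ; ++k)
    for (int j = 0; j < OY; ++j)
      for (int i = 0; i < OX; ++i, n += C) {
        const R_xlen_t p = (R_xlen_t)C*((i/2) + (R_xlen_t)X*((j/2) + (R_xlen_t)Y*(k/2)));
        std::memcpy(yp + n, xp + p, sizeof(double)*C);
      }
  y.attr("dim") = IntegerVector::create(C, OX, OY, OZ);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector dy, IntegerVector ydim) {
  const int C = ydim[0], OX = ydim[1], OY = ydim[2], OZ = ydim[3];
  const int X = OX/2, Y = OY/2, Z = OZ/2;
  NumericVector dx((R_xlen_t)C * X * Y * Z);
  const double *dyp = dy.begin();
  double *dxp = dx.begin();
  R_xlen_t n = 0;
  for (int k = 0; k < OZ; ++k)
    for (int j = 0; j < OY; ++j)
      for (int i = 0; i < OX; ++i, n += C) {
        double *dst = dxp + (R_xlen_t)C*((i/2) + (R_xlen_t)X*((j/2) + (R_xlen_t)Y*(k/2)));
        const double *src = dyp + n;
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  dx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return dx;
}

// ---- 6-connected component labelling ---------------------------------------
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  IntegerVector lab(N);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      const R_xlen_t p = stack.back(); stack.pop_back();
      const int i = p % X, j = (p / X) % Y, k = p / ((R_xlen_t)X * Y);
      const int di[6] = {-1,1,0,0,0,0}, dj[6] = {0,0,-1,1,0,0},
                dk[6] = {0,0,0,0,-1,1};
      for (int t = 0; t < 6; ++t) {
        const int ii = i+di[t], jj = j+dj[t], kk = k+dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= X || jj >= Y || kk >= Z) continue;
        const R_xlen_t q = ii + (R_xlen_t)X*(jj + (R_xlen_t)Y*kk);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- exact 2D Euclidean distance transform (Felzenszwalb-Huttenlocher) -----
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q*q) - (f[v[k]] + v[k]*v[k])) / (2.0*q - 2.0*v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k+1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k+1] < q) ++k;
    d[q] = (q - v[k])*(q - v[k]) + f[v[k]];
  }
}

// distance (in voxels) from every pixel to the nearest true pixel
// [[Rcpp::export]]
NumericMatrix edt2d_cpp(LogicalMatrix mask) {
  const int X = mask.nrow(), Y = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(X, Y);
  for (int j = 0; j < Y; ++j)
    for (int i = 0; i < X; ++i) g(i, j) = mask(i, j) ? 0.0 : INF;
  std::vector<double> f(std::max(X, Y)), d(std::max(X, Y));
  for (int j = 0; j < Y; ++j) {           // along rows (x)
    for (int i = 0; i < X; ++i) f[i] = g(i, j);
    dt1d(f, d, X);
    for (int i = 0; i < X; ++i) g(i, j) = d[i];
  }
  for (int i = 0; i < X; ++i) {           // along columns (y)
    for (int j = 0; j < Y; ++j) f[j] = g(i, j);
    dt1d(f, d, Y);
    for (int j = 0; j < Y; ++j) g(i, j) = std::sqrt(d[j]);
  }
  return g;
}
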