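// Minimal 3D convolution / pooling kernels for the frame-wise spatial
// feature extractor.  Activations are cubes (channels x voxels x frames);
// the voxel axis linearises a (depth, height, width) grid column-major,
// i.e. index = d + D*(h + H*w), matching R's array layout.
// Weight matrices are (out_channels x in_channels*K) with column order
// kidx*Cin + c, kidx = kd + KD*(kh + KH*kw), K = KD*KH*KW — channels
// innermost, so each kernel tap is a contiguous (Cout x Cin) block.
//
// Same-padded convolutions use a shift decomposition: on the zero-padded
// grid, kernel tap kidx is an exact linear index shift, so the whole
// convolution is K accumulated GEMMs over contiguous memory (including
// across frames: a shift never carries a real voxel past its own slice's
// trailing padding).  Garbage computed in padding cells is cropped away;
// in the backward pass the padded output gradient is zero there, so no
// garbage reaches the weight gradients.  Valid (unpadded) convolutions
// fall back to an im2col path; they only run on tiny late-stage grids.

#include <RcppArmadillo.h>
#define USE_FC_LEN_T
#include <Rconfig.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void out_dims(const ivec& dims, const ivec& kernel,
                            const ivec& pad, int& Do, int& Ho, int& Wo) {
  Do = dims[0] + 2 * pad[0] - kernel[0] + 1;
  Ho = dims[1] + 2 * pad[1] - kernel[1] + 1;
  Wo = dims[2] + 2 * pad[2] - kernel[2] + 1;
  if (Do < 1 || Ho < 1 || Wo < 1)
    Rcpp::stop("kernel larger than padded input volume");
}

// C (m x n, ld m) += A (m x k, ld m) * op(B)
static inline void gemm_acc(bool transB, int m, int n, int k,
                            const double* A, const double* B, int ldb,
                            double* C) {
  const double one = 1.0;
  F77_CALL(dgemm)("N", transB ? "T" : "N",
                  &m, &n, &k, &one, A, &m, B, &ldb, &one, C, &m FCONE FCONE);
}

// Copy X (Cin x D*H*W x T) into a zero-padded (Cin x Dp*Hp*Wp x T) cube.
static cube pad_cube(const cube& X, const ivec& dims, const ivec& pad) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int Dp = D + 2 * pad[0], Hp = H + 2 * pad[1], Wp = W + 2 * pad[2];
  const uword Cin = X.n_rows, T = X.n_slices;
  cube P(Cin, (uword)Dp * Hp * Wp, T, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const double* src = X.slice_memptr(t);
    double* dst = P.slice_memptr(t);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        std::memcpy(dst + Cin * (pad[0] + (uword)Dp * ((h + pad[1]) + (uword)Hp * (w + pad[2]))),
                    src + Cin * ((uword)D * (h + (uword)H * w)),
                    (uword)D * Cin * sizeof(double));
  }
  return P;
}

// Crop the padded layout back to the original grid.
static cube crop_cube(const cube& P, uword C, const ivec& dims, const ivec& pad) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int Dp = D + 2 * pad[0], Hp = H + 2 * pad[1];
  const uword T = P.n_slices;
  cube X(C, (uword)D * H * W, T);
  for (uword t = 0; t < T; ++t) {
    const double* src = P.slice_memptr(t);
    double* dst = X.slice_memptr(t);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        std::memcpy(dst + C * ((uword)D * (h + (uword)H * w)),
                    src + C * (pad[0] + (uword)Dp * ((h + pad[1]) + (uword)Hp * (w + pad[2]))),
                    (uword)D * C * sizeof(double));
  }
  return X;
}

static bool is_same_conv(const ivec& dims, const ivec& kernel, const ivec& pad) {
  for (int a = 0; a < 3; ++a)
    if (kernel[a] != 2 * pad[a] + 1) return false;
  return true;
}

// ---------- same-padded path: shift-decomposed GEMMs ----------

static cube conv_same_fw(const cube& X, const mat& W, const vec& b,
                         const ivec& dims, const ivec& kernel, const ivec& pad) {
  const int Dp = dims[0] + 2 * pad[0], Hp = dims[1] + 2 * pad[1];
  const int KD = kernel[0], KH = kernel[1], KW = kernel[2];
  const int Cin = X.n_rows, Cout = W.n_rows;
  cube P = pad_cube(X, dims, pad);
  const long long M = (long long)P.n_cols * P.n_slices;
  mat Yp(Cout, (uword)M, fill::zeros);
  for (int kw = 0; kw < KW; ++kw)
    for (int kh = 0; kh < KH; ++kh)
      for (int kd = 0; kd < KD; ++kd) {
        const long long s = (kd - pad[0]) + (long long)Dp * ((kh - pad[1]) + (long long)Hp * (kw - pad[2]));
        const long long jlo = std::max(0LL, -s);
        const long long jhi = std::min(M - 1, M - 1 - s);
        if (jhi < jlo) continue;
        const int kidx = kd + KD * (kh + KH * kw);
        gemm_acc(false, Cout, (int)(jhi - jlo + 1), Cin,
                 W.colptr((uword)kidx * Cin),
                 P.memptr() + (uword)(jlo + s) * Cin, Cin,
                 Yp.colptr((uword)jlo));
      }
  cube Y = crop_cube(cube(Yp.memptr(), Cout, P.n_cols, P.n_slices, false),
                     Cout, dims, pad);
  for (uword t = 0; t < Y.n_slices; ++t) Y.slice(t).each_col() += b;
  return Y;
}

static void conv_same_bw(const cube& X, const cube& dY, const mat& W,
                         const ivec& dims, const ivec& kernel, const ivec& pad,
                         cube& dX, mat& dW, vec& db) {
  const int Dp = dims[0] + 2 * pad[0], Hp = dims[1] + 2 * pad[1];
  const int KD = kernel[0], KH = kernel[1], KW = kernel[2];
  const int Cin = X.n_rows, Cout = W.n_rows;
  cube P = pad_cube(X, dims, pad);
  cube dYp = pad_cube(dY, dims, pad);
  const long long M = (long long)P.n_cols * P.n_slices;
  mat dPm(Cin, (uword)M, fill::zeros);
  for (int kw = 0; kw < KW; ++kw)
    for (int kh = 0; kh < KH; ++kh)
      for (int kd = 0; kd < KD; ++kd) {
        const long long s = (kd - pad[0]) + (long long)Dp * ((kh - pad[1]) + (long long)Hp * (kw - pad[2]));
        const long long jlo = std::max(0LL, -s);
        const long long jhi = std::min(M - 1, M - 1 - s);
        if (jhi < jlo) continue;
        const int kidx = kd + KD * (kh + KH * kw);
        const int len = (int)(jhi - jlo + 1);
        // dW_k += dYp[, j] * P[, j+s]^T
        gemm_acc(true, Cout, Cin, len,
                 dYp.memptr() + (uword)jlo * Cout,
                 P.memptr() + (uword)(jlo + s) * Cin, Cin,
                 dW.colptr((uword)kidx * Cin));
        // dP[, j+s] += W_k^T * dYp[, j]
        const mat Wk(const_cast<double*>(W.colptr((uword)kidx * Cin)), Cout, Cin, false, true);
        const mat WkT = Wk.t();
        gemm_acc(false, Cin, len, Cout,
                 WkT.memptr(),
                 dYp.memptr() + (uword)jlo * Cout, Cout,
                 dPm.colptr((uword)(jlo + s)));
      }
  dX = crop_cube(cube(dPm.memptr(), Cin, P.n_cols, P.n_slices, false),
                 Cin, dims, pad);
  for (uword t = 0; t < dY.n_slices; ++t) db += sum(dY.slice(t), 1);
}

// ---------- valid path: im2col (small late-stage grids only) ----------

static mat im2col_valid(const cube& X, const ivec& dims, const ivec& kernel) {
  const int D = dims[0], H = dims[1];
  const int KD = kernel[0], KH = kernel[1], KW = kernel[2];
  int Do, Ho, Wo;
  ivec zero = {0, 0, 0};
  out_dims(dims, kernel, zero, Do, Ho, Wo);
  const uword Cin = X.n_rows, T = X.n_slices, Nout = (uword)Do * Ho * Wo;
  const uword K = (uword)KD * KH * KW;
  mat col(Cin * K, Nout * T);
  for (uword t = 0; t < T; ++t) {
    const double* xp = X.slice_memptr(t);
    for (int kw = 0; kw < KW; ++kw)
      for (int kh = 0; kh < KH; ++kh)
        for (int kd = 0; kd < KD; ++kd) {
          const uword row0 = (uword)(kd + KD * (kh + KH * kw)) * Cin;
          for (int wo = 0; wo < Wo; ++wo)
            for (int ho = 0; ho < Ho; ++ho)
              for (int dout = 0; dout < Do; ++dout) {
                const uword i = (dout + kd) + (uword)D * ((ho + kh) + (uword)H * (wo + kw));
                const uword j = t * Nout + dout + (uword)Do * (ho + (uword)Ho * wo);
                std::memcpy(col.colptr(j) + row0, xp + i * Cin, Cin * sizeof(double));
              }
        }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube conv3d_fw(const arma::cube& X, const arma::mat& W,
                     const arma::vec& b, const arma::ivec& dims,
                     const arma::ivec& kernel, const arma::ivec& pad) {
  int Do, Ho, Wo;
  out_dims(dims, kernel, pad, Do, Ho, Wo);
  if (is_same_conv(dims, kernel, pad))
    return conv_same_fw(X, W, b, dims, kernel, pad);
  if (pad[0] || pad[1] || pad[2])
    Rcpp::stop("only zero or 'same' padding is supported");
  const uword T = X.n_slices, Nout = (uword)Do * Ho * Wo;
  mat col = im2col_valid(X, dims, kernel);
  mat out = W * col;
  out.each_col() += b;
  cube Y(W.n_rows, Nout, T);
  std::memcpy(Y.memptr(), out.memptr(), out.n_elem * sizeof(double));
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3d_bw(const arma::cube& X, const arma::cube& dY,
                     const arma::mat& W, const arma::ivec& dims,
                     const arma::ivec& kernel, const arma::ivec& pad) {
  mat dW(size(W), fill::zeros);
  vec db(W.n_rows, fill::zeros);
  cube dX;
  if (is_same_conv(dims, kernel, pad)) {
    conv_same_bw(X, dY, W, dims, kernel, pad, dX, dW, db);
  } else {
    if (pad[0] || pad[1] || pad[2])
      Rcpp::stop("only zero or 'same' padding is supported");
    const int KD = kernel[0], KH = kernel[1];
    const int D = dims[0], H = dims[1];
    int Do, Ho, Wo;
    out_dims(dims, kernel, pad, Do, Ho, Wo);
    const uword T = X.n_slices, Nout = (uword)Do * Ho * Wo, Cin = X.n_rows;
    mat col = im2col_valid(X, dims, kernel);
    const mat dYf(const_cast<double*>(dY.memptr()), dY.n_rows, Nout * T, false, true);
    dW = dYf * col.t();
    db = sum(dYf, 1);
    mat dcol = W.t() * dYf;
    dX = cube(Cin, (uword)D * H * dims[2], T, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      double* xp = dX.slice_memptr(t);
      for (int kw = 0; kw < kernel[2]; ++kw)
        for (int kh = 0; kh < KH; ++kh)
          for (int kd = 0; kd < KD; ++kd) {
            const uword row0 = (uword)(kd + KD * (kh + KH * kw)) * Cin;
            for (int wo = 0; wo < Wo; ++wo)
              for (int ho = 0; ho < Ho; ++ho)
                for (int dout = 0; dout < Do; ++dout) {
                  const uword i = (dout + kd) + (uword)D * ((ho + kh) + (uword)H * (wo + kw));
                  const uword j = t * Nout + dout + (uword)Do * (ho + (uword)Ho * wo);
                  const double* src = dcol.colptr(j) + row0;
                  double* dst = xp + i * Cin;
                  for (uword c = 0; c < Cin; ++c) dst[c] += src[c];
                }
          }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2x2 max pooling, stride 2; dims must be even.  Returns pooled values
// and the 1-based flat argmax index into the input voxel axis.
// [[Rcpp::export]]
Rcpp::List maxpool3d_fw(const arma::cube& X, const arma::ivec& dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  if (D % 2 || H % 2 || W % 2)
    Rcpp::stop("max pooling requires even spatial dimensions");
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const uword C = X.n_rows, T = X.n_slices, Nout = (uword)Do * Ho * Wo;
  cube Y(C, Nout, T);
  cube idx(C, Nout, T);  // stored as double; exact for these magnitudes
  for (uword t = 0; t < T; ++t) {
    const mat& S = X.slice(t);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int dout = 0; dout < Do; ++dout) {
          const uword j = dout + (uword)Do * (ho + (uword)Ho * wo);
          for (uword c = 0; c < C; ++c) {
            double best = -datum::inf; uword bi = 0;
            for (int kw = 0; kw < 2; ++kw)
              for (int kh = 0; kh < 2; ++kh)
                for (int kd = 0; kd < 2; ++kd) {
                  const uword i = (2 * dout + kd) +
                    (uword)D * ((2 * ho + kh) + (uword)H * (2 * wo + kw));
                  if (S(c, i) > best) { best = S(c, i); bi = i; }
                }
            Y(c, j, t) = best;
            idx(c, j, t) = (double)(bi + 1);
          }
        }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool3d_bw(const arma::cube& dY, const arma::cube& idx,
                        int n_in) {
  const uword C = dY.n_rows, Nout = dY.n_cols, T = dY.n_slices;
  cube dX(C, (uword)n_in, T, fill::zeros);
  for (uword t = 0; t < T; ++t)
    for (uword j = 0; j < Nout; ++j)
      for (uword c = 0; c < C; ++c)
        dX(c, (uword)idx(c, j, t) - 1, t) += dY(c, j, t);
  return dX;
}
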