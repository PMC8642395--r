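// Convolution and max-pooling primitives for the residual network.
// Activations are 3-d arrays dim (H, W, B*C); slice s = b*C + c.
// Weight matrices are (Cout x Cin*kh*kw); im2col row r = (c*kh + ki)*kw + kj.
//
// The im2col buffer is stored transposed (Q x K, Q = OH*OW output positions
// column-major), so the GEMM result lands column-contiguous per output
// channel and moves into the output cube with memcpy. Input arrays are
// wrapped without copying.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static arma::cube view_cube(NumericVector x, const IntegerVector& d) {
  return arma::cube(x.begin(), d[0], d[1], d[2], false, true);
}

// Fill A (Q x K) for batch item b: column r = (c*kh + ki)*kw + kj holds the
// input value at each output position (contiguous writes down the column).
static void im2col_t(const arma::cube& x, int b, int Cin,
                     int kh, int kw, int sh, int sw, int ph, int pw,
                     int OH, int OW, arma::mat& A) {
  const int H = x.n_rows, W = x.n_cols;
  for (int c = 0; c < Cin; ++c) {
    const arma::mat& xs = x.slice((size_t)b * Cin + c);
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        double* col = A.colptr((c * kh + ki) * kw + kj);
        for (int ox = 0; ox < OW; ++ox) {
          const int ix = ox * sw - pw + kj;
          double* dst = col + (size_t)ox * OH;
          if (ix < 0 || ix >= W) {
            std::memset(dst, 0, sizeof(double) * OH);
            continue;
          }
          const double* src = xs.colptr(ix);
          for (int oy = 0; oy < OH; ++oy) {
            const int iy = oy * sh - ph + ki;
            dst[oy] = (iy >= 0 && iy < H) ? src[iy] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-accumulate the transposed column buffer back onto the input grid.
static void col2im_t(const arma::mat& dA, int b, int Cin,
                     int kh, int kw, int sh, int sw, int ph, int pw,
                     int OH, int OW, arma::cube& dx) {
  const int H = dx.n_rows, W = dx.n_cols;
  for (int c = 0; c < Cin; ++c) {
    arma::mat& xs = dx.slice((size_t)b * Cin + c);
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const double* col = dA.colptr((c * kh + ki) * kw + kj);
        for (int ox = 0; ox < OW; ++ox) {
          const int ix = ox * sw - pw + kj;
          if (ix < 0 || ix >= W) continue;
          double* dst = xs.colptr(ix);
          const double* src = col + (size_t)ox * OH;
          for (int oy = 0; oy < OH; ++oy) {
            const int iy = oy * sh - ph + ki;
            if (iy >= 0 && iy < H) dst[iy] += src[oy];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xdim,
                         const arma::mat& w,
                         int B, int Cin, int Cout,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  arma::cube xc = view_cube(x, xdim);
  const int OH = out_dim(xdim[0], kh, sh, ph);
  const int OW = out_dim(xdim[1], kw, sw, pw);
  const int Q = OH * OW, K = Cin * kh * kw;
  NumericVector out((R_xlen_t)Q * B * Cout);
  out.attr("dim") = IntegerVector::create(OH, OW, B * Cout);
  arma::mat A(Q, K);
  arma::mat wt = w.t();                          // K x Cout
  for (int b = 0; b < B; ++b) {
    im2col_t(xc, b, Cin, kh, kw, sh, sw, ph, pw, OH, OW, A);
    arma::mat yt = A * wt;                       // Q x Cout
    std::memcpy(out.begin() + (size_t)b * Cout * Q, yt.memptr(),
                sizeof(double) * Q * Cout);
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, IntegerVector xdim,
                const arma::mat& w,
                NumericVector dy, int B, int Cin, int Cout,
                int kh, int kw, int sh, int sw, int ph, int pw) {
  arma::cube xc = view_cube(x, xdim);
  const int OH = out_dim(xdim[0], kh, sh, ph);
  const int OW = out_dim(xdim[1], kw, sw, pw);
  const int Q = OH * OW, K = Cin * kh * kw;
  NumericVector dxv((R_xlen_t)xdim[0] * xdim[1] * xdim[2]);
  dxv.attr("dim") = xdim;
  arma::cube dxc = view_cube(dxv, xdim);
  arma::mat dw(Cout, K, arma::fill::zeros);
  arma::mat A(Q, K);
  for (int b = 0; b < B; ++b) {
    im2col_t(xc, b, Cin, kh, kw, sh, sw, ph, pw, OH, OW, A);
    const arma::mat dY(dy.begin() + (size_t)b * Cout * Q, Q, Cout, false);
    dw += dY.t() * A;                            // Cout x K
    arma::mat dA = dY * w;                       // Q x K
    col2im_t(dA, b, Cin, kh, kw, sh, sw, ph, pw, OH, OW, dxc);
  }
  return List::create(Named("dx") = dxv, Named("dw") = dw);
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, IntegerVector xdim,
                 int kh, int kw, int sh, int sw, int ph, int pw) {
  arma::cube xc = view_cube(x, xdim);
  const int H = xdim[0], W = xdim[1], S = xdim[2];
  const int OH = out_dim(H, kh, sh, ph);
  const int OW = out_dim(W, kw, sw, pw);
  NumericVector y((R_xlen_t)OH * OW * S), idx((R_xlen_t)OH * OW * S);
  y.attr("dim") = IntegerVector::create(OH, OW, S);
  double* yp = y.begin(); double* ip = idx.begin();
  for (int s = 0; s < S; ++s) {
    const arma::mat& xs = xc.slice(s);
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        double best = -std::numeric_limits<double>::infinity();
        size_t best_ix = 0;
        for (int kj = 0; kj < kw; ++kj) {
          const int ix = ox * sw - pw + kj;
          if (ix < 0 || ix >= W) continue;
          const double* src = xs.colptr(ix);
          for (int ki = 0; ki < kh; ++ki) {
            const int iy = oy * sh - ph + ki;
            if (iy < 0 || iy >= H) continue;
            if (src[iy] > best) { best = src[iy]; best_ix = (size_t)ix * H + iy; }
          }
        }
        const size_t flat = ((size_t)s * OW + ox) * OH + oy;
        yp[flat] = best;
        ip[flat] = (double)best_ix;
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector ydim,
                          NumericVector idx, int H, int W) {
  const int OH = ydim[0], OW = ydim[1], S = ydim[2];
  NumericVector dxv((R_xlen_t)H * W * S);
  dxv.attr("dim") = IntegerVector::create(H, W, S);
  double* dx = dxv.begin();
  const double* dp = dy.begin();
  const double* ip = idx.begin();
  const size_t n = (size_t)OH * OW * S;
  const size_t hw = (size_t)H * W;
  for (size_t q = 0; q < n; ++q) {
    const size_t s = q / ((size_t)OH * OW);
    dx[s * hw + (size_t)ip[q]] += dp[q];
  }
  return dxv;
}

// Fused per-channel affine: y = x * scale[channel] + shift[channel],
// channel = (slice index) mod C. Used by batch norm to avoid sweep().
// [[Rcpp::export]]
NumericVector channel_affine(NumericVector x, IntegerVector xdim,
                             const arma::vec& scale, const arma::vec& shift,
                             int C) {
  const size_t hw = (size_t)xdim[0] * xdim[1];
  const int S = xdim[2];
  NumericVector y((R_xlen_t)hw * S);
  y.attr("dim") = xdim;
  const double* xp = x.begin(); double* yp = y.begin();
  for (int s = 0; s < S; ++s) {
    const double a = scale[s % C], b = shift[s % C];
    const double* xs = xp + (size_t)s * hw;
    double* ys = yp + (size_t)s * hw;
    for (size_t i = 0; i < hw; ++i) ys[i] = xs[i] * a + b;
  }
  return y;
}

// Per-channel sums of x and x*y over (H, W, B): returns a C x 2 matrix.
// [[Rcpp::export]]
arma::mat channel_sums(NumericVector x, NumericVector y, IntegerVector xdim,
                       int C) {
  const size_t hw = (size_t)xdim[0] * xdim[1];
  const int S = xdim[2];
  arma::mat out(C, 2, arma::fill::zeros);
  const double* xp = x.begin(); const double* yp = y.begin();
  for (int s = 0; s < S; ++s) {
    const int c = s % C;
    const double* xs = xp + (size_t)s * hw;
    const double* ys = yp + (size_t)s * hw;
    double sx = 0.0, sxy = 0.0;
    for (size_t i = 0; i < hw; ++i) { sx += xs[i]; sxy += xs[i] * ys[i]; }
    out(c, 0) += sx;
    out(c, 1) += sxy;
  }
  return out;
}
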