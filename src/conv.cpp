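// Minimal convolution kernels for the segmentation network.
//
// Tensor layout throughout: R numeric arrays dim (H, W, C, N), column-major,
// so each sample is an arma::cube whose slices are per-channel H x W images.
// Convolution weights: dim (k, k, Cin, Cout); transposed-convolution weights:
// dim (k, k, Cin, Cout) with Cin the coarse (input) channels.
//
// Convolutions are im2col + GEMM, batched over samples. The column matrix is
// kept transposed -- rows are output pixels, columns are (channel, kernel
// offset) -- so the inner copy loops run over contiguous memory. The
// transposed convolution is the exact adjoint of a strided convolution
// (col2im of x W), so the forward/backward pairs are adjoint by construction.

#include <RcppArmadillo.h>
using namespace Rcpp;

// valid output-pixel range for one kernel offset: hi = ho*s + ki - p in [0,H)
static inline void orange(int k_off, int s, int p, int n_in, int n_out,
                          int& lo, int& hi) {
  lo = 0;
  while (lo < n_out && lo * s + k_off - p < 0) ++lo;
  hi = n_out - 1;
  while (hi >= 0 && hi * s + k_off - p >= n_in) --hi;
}

// colsT: (N*Ho*Wo) x (C*k*k); row block n*Ho*Wo + (ho + Ho*wo),
// column r = c*k*k + ki*k + kj
static void im2colT(const double* x, int H, int W, int C, int N,
                    int k, int s, int p, int Ho, int Wo, arma::mat& colsT) {
  const arma::uword rows = (arma::uword)N * Ho * Wo;
  colsT.zeros(rows, (arma::uword)C * k * k);
  for (int c = 0; c < C; ++c)
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        const int r = c * k * k + ki * k + kj;
        double* col = colsT.colptr(r);
        int ho0, ho1, wo0, wo1;
        orange(ki, s, p, H, Ho, ho0, ho1);
        orange(kj, s, p, W, Wo, wo0, wo1);
        for (int n = 0; n < N; ++n) {
          const double* xs = x + (size_t)H * W * (c + (size_t)C * n);
          double* cb = col + (size_t)n * Ho * Wo;
          for (int wo = wo0; wo <= wo1; ++wo) {
            const int wi = wo * s + kj - p;
            const double* src = xs + (size_t)H * wi + (ho0 * s + ki - p);
            double* dst = cb + (size_t)Ho * wo + ho0;
            if (s == 1)
              for (int ho = ho0; ho <= ho1; ++ho) *dst++ = *src++;
            else
              for (int ho = ho0; ho <= ho1; ++ho, src += s) *dst++ = *src;
          }
        }
      }
}

// adjoint: scatter-add colsT back into x
static void col2imT(const arma::mat& colsT, int H, int W, int C, int N,
                    int k, int s, int p, int Ho, int Wo, double* x) {
  for (int c = 0; c < C; ++c)
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        const int r = c * k * k + ki * k + kj;
        const double* col = colsT.colptr(r);
        int ho0, ho1, wo0, wo1;
        orange(ki, s, p, H, Ho, ho0, ho1);
        orange(kj, s, p, W, Wo, wo0, wo1);
        for (int n = 0; n < N; ++n) {
          double* xs = x + (size_t)H * W * (c + (size_t)C * n);
          const double* cb = col + (size_t)n * Ho * Wo;
          for (int wo = wo0; wo <= wo1; ++wo) {
            const int wi = wo * s + kj - p;
            double* dst = xs + (size_t)H * wi + (ho0 * s + ki - p);
            const double* src = cb + (size_t)Ho * wo + ho0;
            if (s == 1)
              for (int ho = ho0; ho <= ho1; ++ho) *dst++ += *src++;
            else
              for (int ho = ho0; ho <= ho1; ++ho, dst += s) *dst += *src++;
          }
        }
      }
}

// weight matrix (C*k*k) x Cout from an R array dim (k,k,C,Cout)
static arma::mat weight_mat(const NumericVector& w, int k, int C, int Cout) {
  arma::mat Wm((arma::uword)C * k * k, Cout);
  const double* wp = w.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki)
          Wm(c * k * k + ki * k + kj, o) = wp[ki + k * (kj + k * (c + C * o))];
  return Wm;
}

static void weight_scatter(const arma::mat& Wm, NumericVector& w,
                           int k, int C, int Cout) {
  double* wp = w.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki)
          wp[ki + k * (kj + k * (c + C * o))] = Wm(c * k * k + ki * k + kj, o);
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// gather (H,W,Cout,N) array into (N*Ho*Wo) x Cout matrix and back
static arma::mat gather_out(const NumericVector& y, int Ho, int Wo,
                            int Cout, int N) {
  arma::mat Y((arma::uword)N * Ho * Wo, Cout);
  const double* yp = y.begin();
  for (int o = 0; o < Cout; ++o) {
    double* col = Y.colptr(o);
    for (int n = 0; n < N; ++n)
      std::copy(yp + (size_t)Ho * Wo * (o + (size_t)Cout * n),
                yp + (size_t)Ho * Wo * (o + (size_t)Cout * n) + (size_t)Ho * Wo,
                col + (size_t)n * Ho * Wo);
  }
  return Y;
}

static void scatter_out(const arma::mat& Y, NumericVector& y, int Ho, int Wo,
                        int Cout, int N) {
  double* yp = y.begin();
  for (int o = 0; o < Cout; ++o) {
    const double* col = Y.colptr(o);
    for (int n = 0; n < N; ++n)
      std::copy(col + (size_t)n * Ho * Wo, col + (size_t)(n + 1) * Ho * Wo,
                yp + (size_t)Ho * Wo * (o + (size_t)Cout * n));
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("channel mismatch in conv2d_fwd");
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm = weight_mat(w, k, Cin, Cout);
  arma::mat colsT;
  im2colT(x.begin(), H, W, C, N, k, stride, pad, Ho, Wo, colsT);
  arma::mat Y = colsT * Wm;
  Y.each_row() += arma::rowvec(b.begin(), Cout);
  scatter_out(Y, y, Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector dx_ = dims4(x), dw_ = dims4(w), ddy = dims4(dy);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], Cin = dw_[2], Cout = dw_[3];
  const int Ho = ddy[0], Wo = ddy[1];
  arma::mat Wm = weight_mat(w, k, Cin, Cout);
  NumericVector dxv(x.size());
  dxv.attr("dim") = dx_;
  NumericVector dwv(w.size());
  dwv.attr("dim") = dw_;
  arma::mat dY = gather_out(dy, Ho, Wo, Cout, N);
  arma::mat colsT;
  im2colT(x.begin(), H, W, C, N, k, stride, pad, Ho, Wo, colsT);
  arma::mat dWm = colsT.t() * dY;
  weight_scatter(dWm, dwv, k, Cin, Cout);
  arma::mat dcolsT = dY * Wm.t();
  col2imT(dcolsT, H, W, C, N, k, stride, pad, Ho, Wo, dxv.begin());
  NumericVector db(Cout);
  arma::rowvec dbv = arma::sum(dY, 0);
  std::copy(dbv.begin(), dbv.end(), db.begin());
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = db);
}

// Transposed convolution, x (H,W,Cin,N) -> y (Hh,Wh,Cout,N) with
// Hh = (H-1)*stride - 2*pad + k + opad. Implemented as the adjoint of the
// conv mapping the fine grid (Cout channels) to the coarse grid (Cin).
// For that conv, Wm is (Cout*k*k) x Cin with column order r = o*k*k + ...

static arma::mat weight_mat_t(const NumericVector& w, int k, int Cin,
                              int Cout) {
  arma::mat Wm((arma::uword)Cout * k * k, Cin);
  const double* wp = w.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki)
          Wm(o * k * k + ki * k + kj, c) = wp[ki + k * (kj + k * (c + Cin * o))];
  return Wm;
}

static void weight_scatter_t(const arma::mat& Wm, NumericVector& w,
                             int k, int Cin, int Cout) {
  double* wp = w.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki)
          wp[ki + k * (kj + k * (c + Cin * o))] = Wm(o * k * k + ki * k + kj, c);
}

// [[Rcpp::export(name = ".convt2d_fwd")]]
NumericVector convt2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad, int opad) {
  IntegerVector dx_ = dims4(x), dw_ = dims4(w);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], Cin = dw_[2], Cout = dw_[3];
  if (Cin != C) stop("channel mismatch in convt2d_fwd");
  const int Hh = (H - 1) * stride - 2 * pad + k + opad;
  const int Wh = (W - 1) * stride - 2 * pad + k + opad;
  NumericVector y((size_t)Hh * Wh * Cout * N);
  y.attr("dim") = IntegerVector::create(Hh, Wh, Cout, N);
  arma::mat Wm = weight_mat_t(w, k, Cin, Cout);
  arma::mat Xm = gather_out(x, H, W, Cin, N);       // (N*H*W) x Cin
  arma::mat colsT = Xm * Wm.t();                    // (N*H*W) x Cout*k*k
  col2imT(colsT, Hh, Wh, Cout, N, k, stride, pad, H, W, y.begin());
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      double* ys = yp + (size_t)Hh * Wh * (o + (size_t)Cout * n);
      const double bo = b[o];
      for (size_t q = 0; q < (size_t)Hh * Wh; ++q) ys[q] += bo;
    }
  return y;
}

// [[Rcpp::export(name = ".convt2d_bwd")]]
List convt2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 int stride, int pad) {
  IntegerVector dx_ = dims4(x), dw_ = dims4(w), ddy = dims4(dy);
  const int H = dx_[0], W = dx_[1], N = dx_[3];
  const int k = dw_[0], Cin = dw_[2], Cout = dw_[3];
  const int Hh = ddy[0], Wh = ddy[1];
  arma::mat Wm = weight_mat_t(w, k, Cin, Cout);
  arma::mat colsT;
  im2colT(dy.begin(), Hh, Wh, Cout, N, k, stride, pad, H, W, colsT);
  arma::mat Xm = gather_out(x, H, W, Cin, N);
  arma::mat dWm = colsT.t() * Xm;                   // (Cout*k*k) x Cin
  NumericVector dwv(w.size());
  dwv.attr("dim") = dw_;
  weight_scatter_t(dWm, dwv, k, Cin, Cout);
  arma::mat dXm = colsT * Wm;                       // (N*H*W) x Cin
  NumericVector dxv(x.size());
  dxv.attr("dim") = dx_;
  scatter_out(dXm, dxv, H, W, Cin, N);
  NumericVector db(Cout);
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const double* ds = dyp + (size_t)Hh * Wh * (o + (size_t)Cout * n);
      double acc = 0;
      for (size_t q = 0; q < (size_t)Hh * Wh; ++q) acc += ds[q];
      db[o] += acc;
    }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pooling requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  idx.attr("dim") = y.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      const size_t yoff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL;
          int barg = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const int hi = 2 * ho + di, wi = 2 * wo + dj;
              const double v = xp[xoff + hi + (size_t)H * wi];
              if (v > best) { best = v; barg = hi + H * wi; }
            }
          yp[yoff + ho + (size_t)Ho * wo] = best;
          ip[yoff + ho + (size_t)Ho * wo] = barg;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector d = dims4(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      const size_t yoff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (size_t q = 0; q < (size_t)Ho * Wo; ++q)
        dxp[xoff + ip[yoff + q]] += dyp[yoff + q];
    }
  return dx;
}
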