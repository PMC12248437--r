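// Low-level tensor kernels for the CNN engine.
//
// Layout convention: activation tensors are R arrays with dim (H, W, C, N)
// (column-major, so one image channel is contiguous); convolution weights
// have dim (kh, kw, Cin/groups, Cout).  Convolutions are evaluated by
// im2col + GEMM per channel group, batched over images so the matrix
// multiplications are large enough to hit BLAS speed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill the im2col matrix A (K x P) for channel group g.
// K = kh*kw*cing, P = Ho*Wo*N; column index = ho + Ho*(wo + Wo*n).
static void im2col_group(const double* x, int H, int W, int C, int N,
                         int kh, int kw, int cing, int g,
                         int stride, int pad, int Ho, int Wo, arma::mat& A) {
  const int c0 = g * cing;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const arma::uword col = (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
        double* acol = A.colptr(col);
        int r = 0;
        for (int ci = 0; ci < cing; ++ci) {
          const double* xc = x + (size_t)H * W * ((c0 + ci) + (size_t)C * n);
          for (int dw = 0; dw < kw; ++dw) {
            const int w = wo * stride - pad + dw;
            for (int dh = 0; dh < kh; ++dh, ++r) {
              const int h = ho * stride - pad + dh;
              acol[r] = (h >= 0 && h < H && w >= 0 && w < W) ? xc[h + (size_t)H * w] : 0.0;
            }
          }
        }
      }
    }
  }
}

// Reverse of im2col_group: scatter-add columns of A back into dx.
static void col2im_group(double* dx, int H, int W, int C, int N,
                         int kh, int kw, int cing, int g,
                         int stride, int pad, int Ho, int Wo, const arma::mat& A) {
  const int c0 = g * cing;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const arma::uword col = (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
        const double* acol = A.colptr(col);
        int r = 0;
        for (int ci = 0; ci < cing; ++ci) {
          double* xc = dx + (size_t)H * W * ((c0 + ci) + (size_t)C * n);
          for (int dw = 0; dw < kw; ++dw) {
            const int w = wo * stride - pad + dw;
            for (int dh = 0; dh < kh; ++dh, ++r) {
              const int h = ho * stride - pad + dh;
              if (h >= 0 && h < H && w >= 0 && w < W) xc[h + (size_t)H * w] += acol[r];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int groups) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cing = wd[2], Cout = wd[3];
  if (C != cing * groups) stop("input channels do not match weight shape");
  const int coutg = Cout / groups;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  NumericVector y(R_xlen_t(Ho) * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const int K = kh * kw * cing;
  const arma::uword P = (arma::uword)Ho * Wo * N;
  arma::mat A(K, P);
  const bool has_b = b.size() == Cout;

  for (int g = 0; g < groups; ++g) {
    im2col_group(REAL(x), H, W, C, N, kh, kw, cing, g, stride, pad, Ho, Wo, A);
    // weight matrix for this group: coutg x K, row co = w[,,ci,g*coutg+co]
    arma::mat Wm(coutg, K);
    for (int co = 0; co < coutg; ++co) {
      const double* wp = REAL(w) + (size_t)kh * kw * cing * (g * coutg + co);
      for (int k = 0; k < K; ++k) {
        // w layout within one output channel: dh + kh*(dw + kw*ci); our A rows
        // are ordered dh fastest, then dw, then ci -- identical order.
        Wm(co, k) = wp[k];
      }
    }
    arma::mat Y = Wm * A;  // coutg x P
    double* yp = REAL(y);
    for (int co = 0; co < coutg; ++co) {
      const int c = g * coutg + co;
      const double bias = has_b ? b[c] : 0.0;
      for (int n = 0; n < N; ++n) {
        double* dst = yp + (size_t)Ho * Wo * (c + (size_t)Cout * n);
        const arma::uword base = (arma::uword)Ho * Wo * n;
        for (arma::uword p = 0; p < (arma::uword)Ho * Wo; ++p)
          dst[p] = Y(co, base + p) + bias;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad, int groups, bool need_dx = true) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cing = wd[2], Cout = wd[3];
  const int coutg = Cout / groups;
  int Ho, Wo, Cdy, Ndy;
  get_dims4(dy, Ho, Wo, Cdy, Ndy);
  if (Cdy != Cout || Ndy != N) stop("dy shape mismatch");

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);

  const int K = kh * kw * cing;
  const arma::uword P = (arma::uword)Ho * Wo * N;
  arma::mat A(K, P), dY(coutg, P);

  for (int g = 0; g < groups; ++g) {
    im2col_group(REAL(x), H, W, C, N, kh, kw, cing, g, stride, pad, Ho, Wo, A);
    const double* dyp = REAL(dy);
    for (int co = 0; co < coutg; ++co) {
      const int c = g * coutg + co;
      double acc = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* src = dyp + (size_t)Ho * Wo * (c + (size_t)Cout * n);
        const arma::uword base = (arma::uword)Ho * Wo * n;
        for (arma::uword p = 0; p < (arma::uword)Ho * Wo; ++p) {
          dY(co, base + p) = src[p];
          acc += src[p];
        }
      }
      db[c] = acc;
    }
    arma::mat dWm = dY * A.t();           // coutg x K
    for (int co = 0; co < coutg; ++co) {
      double* dwp = REAL(dw) + (size_t)kh * kw * cing * (g * coutg + co);
      for (int k = 0; k < K; ++k) dwp[k] = dWm(co, k);
    }
    if (need_dx) {
      arma::mat Wm(coutg, K);
      for (int co = 0; co < coutg; ++co) {
        const double* wp = REAL(w) + (size_t)kh * kw * cing * (g * coutg + co);
        for (int k = 0; k < K; ++k) Wm(co, k) = wp[k];
      }
      arma::mat dA = Wm.t() * dY;         // K x P
      col2im_group(REAL(dx), H, W, C, N, kh, kw, cing, g, stride, pad, Ho, Wo, dA);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxPoolForward")]]
List maxpool_forward(NumericVector x, int k, int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 1-based linear index into x of each max
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          size_t bi = 0;
          for (int dw = 0; dw < k; ++dw) {
            const int w = wo * stride - pad + dw;
            if (w < 0 || w >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              const int h = ho * stride - pad + dh;
              if (h < 0 || h >= H) continue;
              const size_t xi = off + h + (size_t)H * w;
              if (xp[xi] > best) { best = xp[xi]; bi = xi; }
            }
          }
          // y is filled in (ho fastest within wo) but its layout wants
          // ho + Ho*(wo + Wo*(c + C*n)) -- compute explicitly.
          const R_xlen_t yi = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (c + (R_xlen_t)C * n));
          yp[yi] = best;
          ip[yi] = (int)(bi + 1);
          ++q;
        }
    }
  (void)q;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxPoolBackward")]]
NumericVector maxpool_backward(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  const int* ip = INTEGER(idx);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[ip[i] - 1] += dyp[i];
  return dx;
}

// Column-wise max with argmax (1-based row index).  Used for global max
// pooling and channel-wise max maps where R-level apply() would dominate.
// [[Rcpp::export(name = ".colMaxIdx")]]
List colmax_idx(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector mx(nc);
  IntegerVector ix(nc);
  for (int j = 0; j < nc; ++j) {
    double best = R_NegInf;
    int bi = 1;
    const double* col = &m(0, j);
    for (int i = 0; i < nr; ++i)
      if (col[i] > best) { best = col[i]; bi = i + 1; }
    mx[j] = best;
    ix[j] = bi;
  }
  return List::create(_["max"] = mx, _["idx"] = ix);
}
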