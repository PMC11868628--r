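// Convolution / pooling kernels for the lightweight training engine.
// Tensor layout throughout: column-major R arrays dim = (H, W, C, N).
// Convolutions are "same": zero padding of (k-1)/2 on each side, stride 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uvec tensor_dims(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  arma::uvec out(d.size());
  for (int i = 0; i < d.size(); ++i) out[i] = d[i];
  return out;
}

// im2col for one sample: rows = H*W output positions, cols = k*k*Cin
// column index = kh + k*(kw + k*ci)  (matches memory order of a (k,k,Cin,Cout) weight array)
static void im2col(const double *x, int H, int W, int C, int k, int pad,
                   arma::mat &M) {
  const int HW = H * W;
  for (int ci = 0; ci < C; ++ci) {
    const double *xc = x + (size_t)ci * HW;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * (kw + k * ci);
        double *Mcol = M.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - pad;
          if (ws < 0 || ws >= W) {
            for (int h = 0; h < H; ++h) Mcol[h + H * w] = 0.0;
            continue;
          }
          const double *xcol = xc + (size_t)ws * H;
          for (int h = 0; h < H; ++h) {
            const int hs = h + kh - pad;
            Mcol[h + H * w] = (hs < 0 || hs >= H) ? 0.0 : xcol[hs];
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im_acc(const arma::mat &M, int H, int W, int C, int k, int pad,
                       double *dx) {
  const int HW = H * W;
  for (int ci = 0; ci < C; ++ci) {
    double *dxc = dx + (size_t)ci * HW;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * (kw + k * ci);
        const double *Mcol = M.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - pad;
          if (ws < 0 || ws >= W) continue;
          double *dxcol = dxc + (size_t)ws * H;
          for (int h = 0; h < H; ++h) {
            const int hs = h + kh - pad;
            if (hs >= 0 && hs < H) dxcol[hs] += Mcol[h + H * w];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  arma::uvec xd = tensor_dims(x), wd = tensor_dims(w);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2, HW = H * W, kkC = k * k * C;
  arma::mat Wmat(const_cast<double *>(w.begin()), kkC, Cout, false, true);
  NumericVector y((size_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat M(HW, kkC);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, k, pad, M);
    arma::mat Y(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    Y = M * Wmat;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  arma::uvec xd = tensor_dims(x), wd = tensor_dims(w);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2, HW = H * W, kkC = k * k * C;
  arma::mat Wmat(const_cast<double *>(w.begin()), kkC, Cout, false, true);
  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  arma::mat dWmat(dw.begin(), kkC, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat M(HW, kkC), dXcol;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, k, pad, M);
    arma::mat dY(dy.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    dWmat += M.t() * dY;
    dbv += arma::sum(dY, 0).t();
    dXcol = dY * Wmat.t();
    col2im_acc(dXcol, H, W, C, k, pad, dx.begin() + (size_t)n * HW * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  arma::uvec xd = tensor_dims(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size()); // 0-based linear index into x of each max
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = base + (size_t)(2 * w) * H + 2 * h;
          size_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          size_t best = cand[0];
          for (int t = 1; t < 4; ++t)
            if (xp[cand[t]] > xp[best]) best = cand[t];
          yp[o] = xp[best];
          ip[o] = (int)best;
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(IntegerVector idx, NumericVector dy,
                              IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  double *dxp = dx.begin();
  const double *dyp = dy.begin();
  const int *ip = idx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[ip[i]] += dyp[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  arma::uvec xd = tensor_dims(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double v = xp[bi + (size_t)w * H + h];
          size_t o00 = bo + (size_t)(2 * w) * Ho + 2 * h;
          yp[o00] = v;
          yp[o00 + 1] = v;
          yp[o00 + Ho] = v;
          yp[o00 + Ho + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector dy) {
  arma::uvec yd = tensor_dims(dy);
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *dyp = dy.begin();
  double *dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      const size_t bi = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          size_t o00 = bo + (size_t)(2 * w) * Ho + 2 * h;
          dxp[bi + (size_t)w * H + h] =
              dyp[o00] + dyp[o00 + 1] + dyp[o00 + Ho] + dyp[o00 + Ho + 1];
        }
    }
  return dx;
}
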