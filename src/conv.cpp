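// Convolution kernels for the neural-network core. Tensors are passed as
// numeric vectors with dim attributes [H, W, C, N] (column-major,
// spatial-first, matching the R side); im2col columns are ordered
// (patch offset, row-fastest) within (input channel).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col_core(const double* x, int H, int W, int C, int N,
                             int k, int stride, int pad, int Ho, int Wo) {
  const long P = (long)Ho * Wo;
  arma::mat out(P * N, (long)k * k * C);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (long)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (long)c * H * W;
      for (int dx = 0; dx < k; ++dx) {
        for (int dy = 0; dy < k; ++dy) {
          const long col = (long)c * k * k + (long)dx * k + dy;
          double* ocol = out.colptr(col);
          for (int ox = 0; ox < Wo; ++ox) {
            const int xx = ox * stride - pad + dx;
            const bool xin = xx >= 0 && xx < W;
            const double* xcol_src = xin ? xc + (long)xx * H : nullptr;
            double* orow = ocol + (long)n * P + (long)ox * Ho;
            for (int oy = 0; oy < Ho; ++oy) {
              const int yy = oy * stride - pad + dy;
              orow[oy] = (xin && yy >= 0 && yy < H) ? xcol_src[yy] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// ycol rows are sample-major blocks of output pixels; reshape to the
// [Ho, Wo, Cout, N] tensor layout.
static NumericVector col2tensor_cpp(const arma::mat& ycol, int Ho, int Wo,
                                    int N) {
  const int Cout = ycol.n_cols;
  const long P = (long)Ho * Wo;
  NumericVector y((long)P * Cout * N);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double* src = ycol.colptr(co) + (long)n * P;
      double* dst = yp + ((long)n * Cout + co) * P;
      std::copy(src, src + P, dst);
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

static arma::mat tensor2col_cpp(const double* y, int Ho, int Wo, int Cout,
                                int N) {
  const long P = (long)Ho * Wo;
  arma::mat out(P * N, Cout);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double* src = y + ((long)n * Cout + co) * P;
      double* dst = out.colptr(co) + (long)n * P;
      std::copy(src, src + P, dst);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, const arma::mat& Wt,
                           const arma::vec& b, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat xcol = im2col_core(REAL(x), H, W, C, N, k, stride, pad, Ho, Wo);
  arma::mat ycol = xcol * Wt;
  ycol.each_row() += b.t();
  return col2tensor_cpp(ycol, Ho, Wo, N);
}

// The input tensor is cached and unfolded again here: rebuilding xcol costs
// less than shipping the (much larger) unfolded matrix across the R/C++
// boundary twice.
// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector dy, NumericVector x,
                  const arma::mat& Wt, int k, int stride, int pad) {
  IntegerVector dxdim = x.attr("dim");
  const int H = dxdim[0], W = dxdim[1], C = dxdim[2];
  IntegerVector d = dy.attr("dim");
  const int Ho = d[0], Wo = d[1], Cout = d[2], N = d[3];
  arma::mat xcol = im2col_core(REAL(x), H, W, C, N, k, stride, pad, Ho, Wo);
  arma::mat dycol = tensor2col_cpp(REAL(dy), Ho, Wo, Cout, N);
  arma::mat dW = xcol.t() * dycol;
  arma::rowvec db = arma::sum(dycol, 0);

  // backward-data: scatter-add the unfolded gradient back onto the input
  // grid (exact adjoint of im2col)
  arma::mat dxcol = dycol * Wt.t();  // [(Ho*Wo*N) x (k*k*C)]
  const long P = (long)Ho * Wo;
  NumericVector dx((long)H * W * C * N);
  double* dstv = REAL(dx);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dst = dstv + ((long)n * C + c) * H * W;
      for (int dxo = 0; dxo < k; ++dxo) {
        for (int dyo = 0; dyo < k; ++dyo) {
          const long col = (long)c * k * k + (long)dxo * k + dyo;
          const double* src = dxcol.colptr(col) + (long)n * P;
          for (int ox = 0; ox < Wo; ++ox) {
            const int xx = ox * stride - pad + dxo;
            if (xx < 0 || xx >= W) continue;
            double* dcolp = dst + (long)xx * H;
            const double* srow = src + (long)ox * Ho;
            for (int oy = 0; oy < Ho; ++oy) {
              const int yy = oy * stride - pad + dyo;
              if (yy >= 0 && yy < H) dcolp[yy] += srow[oy];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dW"] = dW,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
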