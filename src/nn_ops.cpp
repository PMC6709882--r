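#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Kernels for the compact neural-network engine: patch extraction for
// convolutions (im2col / col2im), spatial max pooling with argmax, and
// per-blob group max for the symmetric aggregation of point features.
// Activation layout is (H, W, C, B) column-major arrays; patch matrices are
// (kh*kw*C) x (OH*OW*B) with kernel-row fastest, columns ordered (oh, ow, b).

// [[Rcpp::export(name = "cpp_im2col")]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int B,
                         int k, int stride, int pad) {
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, OH * OW * B);
  const double* px = x.begin();
  double* po = out.begin();
  const int nr = k * k * C;
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        double* col = po + (size_t)nr * (oh + OH * (ow + (size_t)OW * b));
        for (int c = 0; c < C; ++c) {
          const double* plane = px + (size_t)H * W * (c + (size_t)C * b);
          for (int kj = 0; kj < k; ++kj) {
            int wj = ow * stride - pad + kj;
            for (int ki = 0; ki < k; ++ki) {
              int hi = oh * stride - pad + ki;
              double v = 0.0;
              if (hi >= 0 && hi < H && wj >= 0 && wj < W)
                v = plane[hi + (size_t)H * wj];
              col[ki + k * (kj + k * c)] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = "cpp_col2im")]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int B,
                         int k, int stride, int pad) {
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  NumericVector x((size_t)H * W * C * B);
  double* px = x.begin();
  const double* pc = cols.begin();
  const int nr = k * k * C;
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double* col = pc + (size_t)nr * (oh + OH * (ow + (size_t)OW * b));
        for (int c = 0; c < C; ++c) {
          double* plane = px + (size_t)H * W * (c + (size_t)C * b);
          for (int kj = 0; kj < k; ++kj) {
            int wj = ow * stride - pad + kj;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = oh * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              plane[hi + (size_t)H * wj] += col[ki + k * (kj + k * c)];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, B);
  return x;
}

// [[Rcpp::export(name = "cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(NumericVector x, int H, int W, int C, int B,
                     int k, int stride) {
  const int OH = (H - k) / stride + 1;
  const int OW = (W - k) / stride + 1;
  NumericVector out((size_t)OH * OW * C * B);
  IntegerVector arg((size_t)OH * OW * C * B);
  const double* px = x.begin();
  double* po = out.begin();
  int* pa = arg.begin();
  size_t idx = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* plane = px + (size_t)H * W * (c + (size_t)C * b);
      const size_t base = (size_t)H * W * (c + (size_t)C * b);
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int kj = 0; kj < k; ++kj) {
            int wj = ow * stride + kj;
            for (int ki = 0; ki < k; ++ki) {
              int hi = oh * stride + ki;
              double v = plane[hi + (size_t)H * wj];
              if (v > best) { best = v; besti = base + hi + (size_t)H * wj; }
            }
          }
          // output ordered (oh, ow, c, b)
          idx = (size_t)oh + OH * ((size_t)ow + OW * ((size_t)c + (size_t)C * b));
          po[idx] = best;
          pa[idx] = (int)besti; // 0-based linear index into x
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(OH, OW, C, B);
  arg.attr("dim") = IntegerVector::create(OH, OW, C, B);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = "cpp_maxpool_bwd")]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector argmax,
                              int H, int W, int C, int B) {
  NumericVector dx((size_t)H * W * C * B);
  double* pdx = dx.begin();
  const double* pd = dout.begin();
  const int* pa = argmax.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) pdx[pa[i]] += pd[i];
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  return dx;
}

// x: (B*P) x F matrix, rows blob-major (blob b owns rows b*P .. b*P+P-1)
// [[Rcpp::export(name = "cpp_group_max_fwd")]]
List cpp_group_max_fwd(NumericMatrix x, int P) {
  const int n = x.nrow(), F = x.ncol();
  const int B = n / P;
  NumericMatrix out(B, F);
  IntegerMatrix arg(B, F);
  for (int f = 0; f < F; ++f) {
    const double* col = &x(0, f);
    for (int b = 0; b < B; ++b) {
      const double* seg = col + (size_t)b * P;
      double best = seg[0];
      int besti = 0;
      for (int p = 1; p < P; ++p)
        if (seg[p] > best) { best = seg[p]; besti = p; }
      out(b, f) = best;
      arg(b, f) = b * P + besti; // 0-based row index into x
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = "cpp_group_max_bwd")]]
NumericMatrix cpp_group_max_bwd(NumericMatrix dout, IntegerMatrix argmax,
                                int nrow_x) {
  const int B = dout.nrow(), F = dout.ncol();
  NumericMatrix dx(nrow_x, F);
  for (int f = 0; f < F; ++f)
    for (int b = 0; b < B; ++b)
      dx(argmax(b, f), f) += dout(b, f);
  return dx;
}
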