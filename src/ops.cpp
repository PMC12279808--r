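// Low-level tensor kernels for the conv-net engine.
// Feature maps are dense double arrays with dim (H, W, C, N), column-major.
// Convolution is done as im2col + BLAS GEMM on the R side; the depthwise,
// pooling and resampling kernels are direct loops here.
#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericMatrix cols(k * k * C, Ho * Wo * N);
  const double* xp = x.begin();
  double* cp = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * wo + (R_xlen_t)Ho * Wo * n;
        double* dst = cp + col * nrow;
        for (int c = 0; c < C; ++c) {
          const double* plane = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              double v = 0.0;
              if (hi >= 0 && hi < H && wi >= 0 && wi < W)
                v = plane[hi + (R_xlen_t)H * wi];
              dst[kh + k * kw + k * k * c] = v;
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector dx((R_xlen_t)H * W * C * N);
  double* xp = dx.begin();
  const double* cp = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * wo + (R_xlen_t)Ho * Wo * n;
        const double* src = cp + col * nrow;
        for (int c = 0; c < C; ++c) {
          double* plane = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              plane[hi + (R_xlen_t)H * wi] += src[kh + k * kw + k * k * c];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Depthwise convolution, one k x k kernel per channel, weight dim (k, k, C).
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, int H, int W, int C, int N,
                             NumericVector w, int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      const double* ker = wp + (R_xlen_t)k * k * c;
      double* out = yp + ((R_xlen_t)c + (R_xlen_t)C * n) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              acc += plane[hi + (R_xlen_t)H * wi] * ker[kh + k * kw];
            }
          }
          out[ho + (R_xlen_t)Ho * wo] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, int H, int W, int C, int N,
                    NumericVector w, int k, int stride, int pad,
                    NumericVector dy) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dw((R_xlen_t)k * k * C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      const double* ker = wp + (R_xlen_t)k * k * c;
      double* dplane = dxp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      double* dker = dwp + (R_xlen_t)k * k * c;
      const double* g = gp + ((R_xlen_t)c + (R_xlen_t)C * n) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double gv = g[ho + (R_xlen_t)Ho * wo];
          if (gv == 0.0) continue;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              dplane[hi + (R_xlen_t)H * wi] += gv * ker[kh + k * kw];
              dker[kh + k * kw] += gv * plane[hi + (R_xlen_t)H * wi];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  dw.attr("dim") = IntegerVector::create(k, k, C);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Max pooling with stride 1 and symmetric padding (used by the SPPF block).
// Returns pooled values and 0-based winner offsets within each (H, W) plane.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int H, int W, int C, int N,
                     int k, int pad) {
  const int Ho = out_size(H, k, 1, pad);
  const int Wo = out_size(W, k, 1, pad);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      R_xlen_t base = ((R_xlen_t)c + (R_xlen_t)C * n) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -DBL_MAX;
          int besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho - pad + kh;
              if (hi < 0 || hi >= H) continue;
              double v = plane[hi + (R_xlen_t)H * wi];
              if (v > best) { best = v; besti = hi + H * wi; }
            }
          }
          y[base + ho + (R_xlen_t)Ho * wo] = best;
          ip[base + ho + (R_xlen_t)Ho * wo] = besti;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx,
                      _["Ho"] = Ho, _["Wo"] = Wo);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              int H, int W, int C, int N, int Ho, int Wo) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  double* dxp = dx.begin();
  const double* gp = dy.begin();
  const int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      R_xlen_t base_o = ((R_xlen_t)c + (R_xlen_t)C * n) * Ho * Wo;
      R_xlen_t base_i = ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      for (R_xlen_t j = 0; j < (R_xlen_t)Ho * Wo; ++j) {
        int winner = ip[base_o + j];
        if (winner >= 0) dxp[base_i + winner] += gp[base_o + j];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Adaptive average pooling to a gh x gw grid (torch-style bin boundaries).
// [[Rcpp::export]]
NumericVector cpp_avgpool_adapt_fwd(NumericVector x, int H, int W, int C,
                                    int N, int gh, int gw) {
  NumericVector y((R_xlen_t)gh * gw * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      double* out = yp + ((R_xlen_t)c + (R_xlen_t)C * n) * gh * gw;
      for (int j = 0; j < gw; ++j) {
        int w0 = (int)std::floor((double)j * W / gw);
        int w1 = (int)std::ceil((double)(j + 1) * W / gw);
        for (int i = 0; i < gh; ++i) {
          int h0 = (int)std::floor((double)i * H / gh);
          int h1 = (int)std::ceil((double)(i + 1) * H / gh);
          double acc = 0.0;
          for (int wv = w0; wv < w1; ++wv)
            for (int hv = h0; hv < h1; ++hv)
              acc += plane[hv + (R_xlen_t)H * wv];
          out[i + (R_xlen_t)gh * j] = acc / ((h1 - h0) * (w1 - w0));
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(gh, gw, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_adapt_bwd(NumericVector dy, int H, int W, int C,
                                    int N, int gh, int gw) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  double* dxp = dx.begin();
  const double* gp = dy.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* plane = dxp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      const double* g = gp + ((R_xlen_t)c + (R_xlen_t)C * n) * gh * gw;
      for (int j = 0; j < gw; ++j) {
        int w0 = (int)std::floor((double)j * W / gw);
        int w1 = (int)std::ceil((double)(j + 1) * W / gw);
        for (int i = 0; i < gh; ++i) {
          int h0 = (int)std::floor((double)i * H / gh);
          int h1 = (int)std::ceil((double)(i + 1) * H / gh);
          double gv = g[i + (R_xlen_t)gh * j] / ((h1 - h0) * (w1 - w0));
          for (int wv = w0; wv < w1; ++wv)
            for (int hv = h0; hv < h1; ++hv)
              plane[hv + (R_xlen_t)H * wv] += gv;
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Nearest-neighbour resampling to (H2, W2); source index floor(i * H / H2).
// [[Rcpp::export]]
NumericVector cpp_upsample_nearest_fwd(NumericVector x, int H, int W, int C,
                                       int N, int H2, int W2) {
  NumericVector y((R_xlen_t)H2 * W2 * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      double* out = yp + ((R_xlen_t)c + (R_xlen_t)C * n) * H2 * W2;
      for (int j = 0; j < W2; ++j) {
        int ws = (int)((R_xlen_t)j * W / W2);
        for (int i = 0; i < H2; ++i) {
          int hs = (int)((R_xlen_t)i * H / H2);
          out[i + (R_xlen_t)H2 * j] = plane[hs + (R_xlen_t)H * ws];
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nearest_bwd(NumericVector dy, int H, int W, int C,
                                       int N, int H2, int W2) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  double* dxp = dx.begin();
  const double* gp = dy.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* plane = dxp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      const double* g = gp + ((R_xlen_t)c + (R_xlen_t)C * n) * H2 * W2;
      for (int j = 0; j < W2; ++j) {
        int ws = (int)((R_xlen_t)j * W / W2);
        for (int i = 0; i < H2; ++i) {
          int hs = (int)((R_xlen_t)i * H / H2);
          plane[hs + (R_xlen_t)H * ws] += g[i + (R_xlen_t)H2 * j];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
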