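#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Volumes are stored channels-first in R array layout: dim = (C, D, H, W),
// column-major, so element (c,d,h,w) sits at c + C*(d + D*(h + H*w)) (0-based).

// Unfold a (C,D,H,W) volume into a (C*k^3) x (outD*outH*outW) matrix so a 3D
// convolution becomes a single GEMM.  Out-of-bounds taps (zero padding) yield 0.
// [[Rcpp::export]]
NumericMatrix cpp_vol2col(NumericVector x, IntegerVector dims,
                          int k, int stride, int pad) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int od = (D + 2 * pad - k) / stride + 1;
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  NumericMatrix col(C * k * k * k, od * oh * ow);
  double *pc = REAL(col);
  const double *px = REAL(x);
  const int nrow = C * k * k * k;
  for (int wo = 0; wo < ow; ++wo) {
    for (int ho = 0; ho < oh; ++ho) {
      for (int dd = 0; dd < od; ++dd) {
        const R_xlen_t cidx = (R_xlen_t)(dd + od * (ho + (R_xlen_t)oh * wo)) * nrow;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh;
            for (int kd = 0; kd < k; ++kd) {
              const int di = dd * stride - pad + kd;
              const R_xlen_t r0 = cidx + (R_xlen_t)C * (kd + k * (kh + k * kw));
              if (di < 0 || di >= D || hi < 0 || hi >= H || wi < 0 || wi >= W) {
                std::memset(pc + r0, 0, C * sizeof(double));
              } else {
                const R_xlen_t xi = (R_xlen_t)C * (di + (R_xlen_t)D * (hi + (R_xlen_t)H * wi));
                std::memcpy(pc + r0, px + xi, C * sizeof(double));
              }
            }
          }
        }
      }
    }
  }
  return col;
}

// Adjoint of cpp_vol2col: scatter-add a column matrix back into a (C,D,H,W)
// volume.  Also serves as the forward pass of the kernel-2/stride-2
// transposed convolution (whose taps never overlap in the overlapping sense
// but share the same indexing).
// [[Rcpp::export]]
NumericVector cpp_col2vol(NumericMatrix col, IntegerVector dims,
                          int k, int stride, int pad) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int od = (D + 2 * pad - k) / stride + 1;
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)C * D * H * W);
  double *px = REAL(x);
  const double *pc = REAL(col);
  const int nrow = C * k * k * k;
  for (int wo = 0; wo < ow; ++wo) {
    for (int ho = 0; ho < oh; ++ho) {
      for (int dd = 0; dd < od; ++dd) {
        const R_xlen_t cidx = (R_xlen_t)(dd + od * (ho + (R_xlen_t)oh * wo)) * nrow;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            for (int kd = 0; kd < k; ++kd) {
              const int di = dd * stride - pad + kd;
              if (di < 0 || di >= D) continue;
              const R_xlen_t r0 = cidx + (R_xlen_t)C * (kd + k * (kh + k * kw));
              const R_xlen_t xi = (R_xlen_t)C * (di + (R_xlen_t)D * (hi + (R_xlen_t)H * wi));
              for (int c = 0; c < C; ++c) px[xi + c] += pc[r0 + c];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = dims;
  return x;
}

// Label connected components of a binary 3D mask (D,H,W) under 6/18/26
// connectivity.  Returns an integer volume: 0 background, 1..n component ids.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const R_xlen_t n = (R_xlen_t)D * H * W;
  IntegerVector lab(n, 0);
  // neighbor offsets
  std::vector<int> dd, dh, dw;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        const int man = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && man > 1) continue;
        if (connectivity == 18 && man > 2) continue;
        dd.push_back(a); dh.push_back(b); dw.push_back(c);
      }
  const int nn = (int)dd.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back(); stack.pop_back();
      const int wv = (int)(v / ((R_xlen_t)D * H));
      const int hv = (int)((v / D) % H);
      const int dv = (int)(v % D);
      for (int j = 0; j < nn; ++j) {
        const int d2 = dv + dd[j], h2 = hv + dh[j], w2 = wv + dw[j];
        if (d2 < 0 || d2 >= D || h2 < 0 || h2 >= H || w2 < 0 || w2 >= W) continue;
        const R_xlen_t u = d2 + (R_xlen_t)D * (h2 + (R_xlen_t)H * w2);
        if (mask[u] && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
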