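#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix extraction for 2-D convolution on a single H x W x C
// feature map (R column-major layout). Row index runs over
// (kernel row, kernel col, channel) in R array order; column p over
// output positions (row fastest), so matrix products against a
// (kh*kw*C) x Cout weight matrix give the convolution directly.
// Out-of-image taps read as zero (zero padding).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int padh, int padw,
                         int stride, int dil, int Hout, int Wout) {
  const int K = kh * kw * C;
  const int P = Hout * Wout;
  NumericMatrix cols(K, P);
  const double *px = x.begin();
  double *pc = cols.begin();
  for (int co = 0; co < Wout; ++co) {
    for (int ro = 0; ro < Hout; ++ro) {
      const int p = ro + Hout * co;
      double *col = pc + (R_xlen_t)p * K;
      for (int ci = 0; ci < C; ++ci) {
        const double *chan = px + (R_xlen_t)ci * H * W;
        for (int kc = 0; kc < kw; ++kc) {
          const int c_in = co * stride - padw + kc * dil;
          const int base = ci * kh * kw + kc * kh;
          if (c_in < 0 || c_in >= W) {
            for (int kr = 0; kr < kh; ++kr) col[base + kr] = 0.0;
            continue;
          }
          const double *colp = chan + (R_xlen_t)c_in * H;
          for (int kr = 0; kr < kh; ++kr) {
            const int r_in = ro * stride - padh + kr * dil;
            col[base + kr] = (r_in < 0 || r_in >= H) ? 0.0 : colp[r_in];
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col_cpp: scatter-add patch columns back onto an
// H x W x C grid. Used for convolution input gradients and for the
// forward pass of stride-2 transposed convolution.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int padh, int padw,
                         int stride, int dil, int Hout, int Wout) {
  NumericVector x((R_xlen_t)H * W * C);
  double *px = x.begin();
  const double *pc = cols.begin();
  const int K = kh * kw * C;
  for (int co = 0; co < Wout; ++co) {
    for (int ro = 0; ro < Hout; ++ro) {
      const int p = ro + Hout * co;
      const double *col = pc + (R_xlen_t)p * K;
      for (int ci = 0; ci < C; ++ci) {
        double *chan = px + (R_xlen_t)ci * H * W;
        for (int kc = 0; kc < kw; ++kc) {
          const int c_in = co * stride - padw + kc * dil;
          if (c_in < 0 || c_in >= W) continue;
          const int base = ci * kh * kw + kc * kh;
          double *colp = chan + (R_xlen_t)c_in * H;
          for (int kr = 0; kr < kh; ++kr) {
            const int r_in = ro * stride - padh + kr * dil;
            if (r_in >= 0 && r_in < H) colp[r_in] += col[base + kr];
          }
        }
      }
    }
  }
  return x;
}

// 8-connected component labelling of a binary H x W mask, visiting
// pixels in raster (column-major) order so label ranks are
// deterministic: the component containing the first foreground pixel
// encountered gets label 1, and so on.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, int H, int W) {
  IntegerVector lab((R_xlen_t)H * W);
  std::vector<int> stack;
  int next = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int idx = r + H * c;
      if (mask[idx] == 0 || lab[idx] != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(idx);
      lab[idx] = next;
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        const int cr = cur % H, cc = cur / H;
        for (int k = 0; k < 8; ++k) {
          const int nr = cr + dr[k], nc = cc + dc[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          const int ni = nr + H * nc;
          if (mask[ni] != 0 && lab[ni] == 0) {
            lab[ni] = next;
            stack.push_back(ni);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
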