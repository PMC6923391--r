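#include <Rcpp.h>
using namespace Rcpp;

// im2col / col2im for stride-1, zero-padded "same" convolution. Images are R
// arrays in (h, w, c) order (2D) or (d, h, w, c) order (3D), column-major.
// Column layout: row = output pixel (storage order), col = ki + k*(kj + k*ch),
// matching weight matrices of shape (k*k*c_in) x c_out.

// [[Rcpp::export(name = ".im2col2d_cpp")]]
NumericMatrix im2col2d_cpp(NumericVector x, int h, int w, int c, int k) {
  const int r = k / 2;
  NumericMatrix out((R_xlen_t)h * w, (R_xlen_t)k * k * c);
  for (int ch = 0; ch < c; ++ch) {
    const R_xlen_t choff = (R_xlen_t)h * w * ch;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)k * (kj + (R_xlen_t)k * ch);
        for (int j = 0; j < w; ++j) {
          const int sj = j + kj - r;
          if (sj < 0 || sj >= w) continue;
          const int i0 = std::max(0, r - ki), i1 = std::min(h, h + r - ki);
          const R_xlen_t src0 = choff + (R_xlen_t)h * sj;
          const R_xlen_t dst0 = (R_xlen_t)h * j;
          for (int i = i0; i < i1; ++i) {
            out(dst0 + i, col) = x[src0 + i + ki - r];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".col2im2d_cpp")]]
NumericVector col2im2d_cpp(NumericMatrix cols, int h, int w, int c, int k) {
  const int r = k / 2;
  NumericVector x((R_xlen_t)h * w * c);
  for (int ch = 0; ch < c; ++ch) {
    const R_xlen_t choff = (R_xlen_t)h * w * ch;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)k * (kj + (R_xlen_t)k * ch);
        for (int j = 0; j < w; ++j) {
          const int sj = j + kj - r;
          if (sj < 0 || sj >= w) continue;
          const int i0 = std::max(0, r - ki), i1 = std::min(h, h + r - ki);
          const R_xlen_t src0 = choff + (R_xlen_t)h * sj;
          const R_xlen_t dst0 = (R_xlen_t)h * j;
          for (int i = i0; i < i1; ++i) {
            x[src0 + i + ki - r] += cols(dst0 + i, col);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".im2col3d_cpp")]]
NumericMatrix im2col3d_cpp(NumericVector x, int d, int h, int w, int c, int k) {
  const int r = k / 2;
  NumericMatrix out((R_xlen_t)d * h * w, (R_xlen_t)k * k * k * c);
  for (int ch = 0; ch < c; ++ch) {
    const R_xlen_t choff = (R_xlen_t)d * h * w * ch;
    for (int kk = 0; kk < k; ++kk)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          const R_xlen_t col =
            ki + (R_xlen_t)k * (kj + (R_xlen_t)k * (kk + (R_xlen_t)k * ch));
          for (int xw = 0; xw < w; ++xw) {
            const int sw = xw + kk - r;
            if (sw < 0 || sw >= w) continue;
            for (int xh = 0; xh < h; ++xh) {
              const int sh = xh + kj - r;
              if (sh < 0 || sh >= h) continue;
              const R_xlen_t src0 = choff + (R_xlen_t)d * (sh + (R_xlen_t)h * sw);
              const R_xlen_t dst0 = (R_xlen_t)d * (xh + (R_xlen_t)h * xw);
              const int i0 = std::max(0, r - ki), i1 = std::min(d, d + r - ki);
              for (int i = i0; i < i1; ++i) {
                out(dst0 + i, col) = x[src0 + i + ki - r];
              }
            }
          }
        }
  }
  return out;
}

// [[Rcpp::export(name = ".col2im3d_cpp")]]
NumericVector col2im3d_cpp(NumericMatrix cols, int d, int h, int w, int c,
                           int k) {
  const int r = k / 2;
  NumericVector x((R_xlen_t)d * h * w * c);
  for (int ch = 0; ch < c; ++ch) {
    const R_xlen_t choff = (R_xlen_t)d * h * w * ch;
    for (int kk = 0; kk < k; ++kk)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          const R_xlen_t col =
            ki + (R_xlen_t)k * (kj + (R_xlen_t)k * (kk + (R_xlen_t)k * ch));
          for (int xw = 0; xw < w; ++xw) {
            const int sw = xw + kk - r;
            if (sw < 0 || sw >= w) continue;
            for (int xh = 0; xh < h; ++xh) {
              const int sh = xh + kj - r;
              if (sh < 0 || sh >= h) continue;
              const R_xlen_t src0 = choff + (R_xlen_t)d * (sh + (R_xlen_t)h * sw);
              const R_xlen_t dst0 = (R_xlen_t)d * (xh + (R_xlen_t)h * xw);
              const int i0 = std::max(0, r - ki), i1 = std::min(d, d + r - ki);
              for (int i = i0; i < i1; ++i) {
                x[src0 + i + ki - r] += cols(dst0 + i, col);
              }
            }
          }
        }
  }
  return x;
}

// 2x2 max pooling (h, w even); returns pooled values and argmax indices
// (1-based into the input array) for the backward pass.
// [[Rcpp::export(name = ".maxpool2_cpp")]]
List maxpool2_cpp(NumericVector x, int h, int w, int c) {
  const int ph = h / 2, pw = w / 2;
  NumericVector out((R_xlen_t)ph * pw * c);
  IntegerVector arg((R_xlen_t)ph * pw * c);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < pw; ++j)
      for (int i = 0; i < ph; ++i) {
        double best = -HUGE_VAL;
        R_xlen_t bidx = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            R_xlen_t idx = (2 * i + di) +
              (R_xlen_t)h * ((2 * j + dj) + (R_xlen_t)w * ch);
            if (x[idx] > best) { best = x[idx]; bidx = idx; }
          }
        R_xlen_t o = i + (R_xlen_t)ph * (j + (R_xlen_t)pw * ch);
        out[o] = best;
        arg[o] = (int)(bidx + 1);
      }
  return List::create(_["out"] = out, _["arg"] = arg);
}
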