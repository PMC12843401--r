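// Numerical kernels for the segmentation network.
// Array layout convention throughout the package: feature grids are R arrays
// dim = c(H, W, C) (column-major), matching arma::cube(H, W, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// im2col for one channel group. cols is (cin_g*kh*kw) x (Ho*Wo), row index
// ky + kx*kh + ci*kh*kw to match the memory order of a (kh,kw,cin_g,cout)
// weight array.
static void im2col_group(const arma::cube& x, int c0, int cin_g,
                         int kh, int kw, int stride, int pad,
                         arma::mat& cols) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  cols.zeros(cin_g * kh * kw, Ho * Wo);
  for (int ci = 0; ci < cin_g; ++ci) {
    const arma::mat& sl = x.slice(c0 + ci);
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int row = ky + kx * kh + ci * kh * kw;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            cols(row, oy + ox * Ho) = sl(iy, ix);
          }
        }
      }
    }
  }
}

static void col2im_group(const arma::mat& cols, arma::cube& dx, int c0,
                         int cin_g, int kh, int kw, int stride, int pad) {
  const int H = dx.n_rows, W = dx.n_cols;
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int ci = 0; ci < cin_g; ++ci) {
    arma::mat& sl = dx.slice(c0 + ci);
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int row = ky + kx * kh + ci * kh * kw;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            sl(iy, ix) += cols(row, oy + ox * Ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::vec& w,
                      const arma::vec& bias, bool has_bias,
                      int kh, int kw, int cin_g, int cout,
                      int stride, int pad, int groups) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const int cout_g = cout / groups;
  const int krows = cin_g * kh * kw;
  arma::cube y(Ho, Wo, cout);
  arma::mat cols;
  for (int g = 0; g < groups; ++g) {
    im2col_group(x, g * cin_g, cin_g, kh, kw, stride, pad, cols);
    // weight block for this group: columns g*cout_g .. in the (krows x cout) view
    arma::mat Wg(const_cast<double*>(w.memptr()) + (size_t)krows * g * cout_g,
                 krows, cout_g, false, true);
    arma::mat Yg = Wg.t() * cols;  // cout_g x (Ho*Wo)
    for (int co = 0; co < cout_g; ++co) {
      arma::rowvec r = Yg.row(co);
      arma::mat m(r.memptr(), Ho, Wo);  // column-major: (oy, ox) = r[oy + ox*Ho]
      y.slice(g * cout_g + co) = m;
      if (has_bias) y.slice(g * cout_g + co) += bias(g * cout_g + co);
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::cube& x, const arma::vec& w,
                   const arma::cube& dy, bool has_bias,
                   int kh, int kw, int cin_g, int cout,
                   int stride, int pad, int groups) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  const int cout_g = cout / groups;
  const int krows = cin_g * kh * kw;
  arma::cube dx(H, W, x.n_slices, arma::fill::zeros);
  arma::vec dw((size_t)krows * cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  arma::mat cols;
  for (int g = 0; g < groups; ++g) {
    im2col_group(x, g * cin_g, cin_g, kh, kw, stride, pad, cols);
    arma::mat dYg(cout_g, Ho * Wo);
    for (int co = 0; co < cout_g; ++co) {
      const arma::mat& sl = dy.slice(g * cout_g + co);
      dYg.row(co) = arma::rowvec(const_cast<double*>(sl.memptr()), Ho * Wo, false);
      if (has_bias) db(g * cout_g + co) = arma::accu(sl);
    }
    arma::mat Wg(const_cast<double*>(w.memptr()) + (size_t)krows * g * cout_g,
                 krows, cout_g, false, true);
    arma::mat dWg = cols * dYg.t();  // krows x cout_g
    std::copy(dWg.memptr(), dWg.memptr() + (size_t)krows * cout_g,
              dw.memptr() + (size_t)krows * g * cout_g);
    arma::mat dcols = Wg * dYg;      // krows x (Ho*Wo)
    col2im_group(dcols, dx, g * cin_g, cin_g, kh, kw, stride, pad);
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// Bilinear 2x upsampling, half-pixel centers (align_corners = FALSE).
// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  arma::cube y(Ho, Wo, C);
  std::vector<int> r0(Ho), r1(Ho);
  std::vector<double> wr(Ho);
  for (int o = 0; o < Ho; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    double f = std::floor(src);
    int i0 = (int)f;
    double t = src - f;
    int a = std::min(std::max(i0, 0), H - 1);
    int b = std::min(std::max(i0 + 1, 0), H - 1);
    r0[o] = a; r1[o] = b; wr[o] = t;
  }
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    arma::mat& out = y.slice(c);
    for (int ox = 0; ox < Wo; ++ox) {
      int c0 = r0[ox], c1 = r1[ox];
      double tx = wr[ox];
      for (int oy = 0; oy < Ho; ++oy) {
        int a0 = r0[oy], a1 = r1[oy];
        double ty = wr[oy];
        out(oy, ox) = (1 - ty) * (1 - tx) * sl(a0, c0) +
                      ty * (1 - tx) * sl(a1, c0) +
                      (1 - ty) * tx * sl(a0, c1) +
                      ty * tx * sl(a1, c1);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bw(const arma::cube& dy) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  const int H = Ho / 2, W = Wo / 2;
  arma::cube dx(H, W, C, arma::fill::zeros);
  std::vector<int> r0(Ho), r1(Ho);
  std::vector<double> wr(Ho);
  for (int o = 0; o < Ho; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    double f = std::floor(src);
    int i0 = (int)f;
    double t = src - f;
    r0[o] = std::min(std::max(i0, 0), H - 1);
    r1[o] = std::min(std::max(i0 + 1, 0), H - 1);
    wr[o] = t;
  }
  for (int c = 0; c < C; ++c) {
    const arma::mat& g = dy.slice(c);
    arma::mat& out = dx.slice(c);
    for (int ox = 0; ox < Wo; ++ox) {
      int c0 = r0[ox], c1 = r1[ox];
      double tx = wr[ox];
      for (int oy = 0; oy < Ho; ++oy) {
        int a0 = r0[oy], a1 = r1[oy];
        double ty = wr[oy];
        double v = g(oy, ox);
        out(a0, c0) += (1 - ty) * (1 - tx) * v;
        out(a1, c0) += ty * (1 - tx) * v;
        out(a0, c1) += (1 - ty) * tx * v;
        out(a1, c1) += ty * tx * v;
      }
    }
  }
  return dx;
}

// Geometric resampling for augmentation. mapr/mapc give, for each output
// pixel, the 0-based source (row, col); border handling is clamp-to-edge.
// mode 0 = bilinear, 1 = nearest.
// [[Rcpp::export]]
arma::cube cpp_warp(const arma::cube& x, const arma::mat& mapr,
                    const arma::mat& mapc, int mode) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = mapr.n_rows, Wo = mapr.n_cols;
  arma::cube y(Ho, Wo, C);
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      double sr = mapr(oy, ox), sc = mapc(oy, ox);
      if (mode == 1) {
        int ir = std::min(std::max((int)std::lround(sr), 0), H - 1);
        int ic = std::min(std::max((int)std::lround(sc), 0), W - 1);
        for (int c = 0; c < C; ++c) y(oy, ox, c) = x(ir, ic, c);
      } else {
        double fr = std::floor(sr), fc = std::floor(sc);
        double tr = sr - fr, tc = sc - fc;
        int r0 = std::min(std::max((int)fr, 0), H - 1);
        int r1 = std::min(std::max((int)fr + 1, 0), H - 1);
        int c0 = std::min(std::max((int)fc, 0), W - 1);
        int c1 = std::min(std::max((int)fc + 1, 0), W - 1);
        for (int c = 0; c < C; ++c) {
          y(oy, ox, c) = (1 - tr) * (1 - tc) * x(r0, c0, c) +
                         tr * (1 - tc) * x(r1, c0, c) +
                         (1 - tr) * tc * x(r0, c1, c) +
                         tr * tc * x(r1, c1, c);
        }
      }
    }
  }
  return y;
}

// For each point (row) in A, minimum Euclidean distance to any row of B.
// Points are already scaled by physical spacing.
// [[Rcpp::export]]
arma::vec cpp_min_dists(const arma::mat& A, const arma::mat& B) {
  const int n = A.n_rows, m = B.n_rows, d = A.n_cols;
  arma::vec out(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}
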