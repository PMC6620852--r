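// Low-level numerical kernels: convolution forward/backward (im2col + BLAS),
// 2x2 max-pooling, stride-2 transposed convolution (k=4, pad=1), 8-connected
// component labelling, and an exact squared Euclidean distance transform.
//
// Conventions
//   Feature maps: arma::cube (H, W, C) sharing R's column-major array layout.
//   Conv weights: mat (k*k*Cin, Cout); row index = a + k*b + k*k*ci where
//                 (a, b) is the kernel offset (row, col) and ci the input
//                 channel. Stride 1, zero padding (k-1)/2 (same-size output).
//   Deconv weights: mat (16*Cin, Cout); row index = ci + Cin*(a + 4*b).
//                 Kernel 4x4, stride 2, pad 1 -> output is exactly 2H x 2W.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static mat im2col(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  mat cols(k * k * C, (uword)H * W, fill::zeros);
  const uword nr = cols.n_rows;
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int b = 0; b < k; ++b) {
      const int dj = b - p;
      for (int a = 0; a < k; ++a) {
        const int di = a - p;
        const uword row = a + k * b + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          if (i1 <= i0) continue;
          const double* src = xs.colptr(sj) + (i0 + di);
          double* dst = cols.memptr() + ((uword)i0 + (uword)H * j) * nr + row;
          for (int t = 0; t < i1 - i0; ++t) { *dst = src[t]; dst += nr; }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& dcols, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  cube dx(H, W, C, fill::zeros);
  const uword nr = dcols.n_rows;
  for (int c = 0; c < C; ++c) {
    mat& xs = dx.slice(c);
    for (int b = 0; b < k; ++b) {
      const int dj = b - p;
      for (int a = 0; a < k; ++a) {
        const int di = a - p;
        const uword row = a + k * b + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          if (i1 <= i0) continue;
          double* dst = xs.colptr(sj) + (i0 + di);
          const double* src = dcols.memptr() + ((uword)i0 + (uword)H * j) * nr + row;
          for (int t = 0; t < i1 - i0; ++t) { dst[t] += *src; src += nr; }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat cols = im2col(x, k);
  mat y = cols.t() * w;               // (H*W, Cout)
  cube out(H, W, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* dst = out.slice(co).memptr();
    const double* src = y.colptr(co);
    const double bias = b(co);
    for (uword t = 0; t < (uword)H * W; ++t) dst[t] = src[t] + bias;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::cube& x, const arma::mat& w,
                        const arma::cube& dy, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = dy.n_slices;
  mat cols = im2col(x, k);
  // view dy as (H*W, Cout)
  mat dY(const_cast<double*>(dy.memptr()), (uword)H * W, Cout, false, true);
  mat dw = cols * dY;                 // (k*k*C, Cout)
  vec db = sum(dY, 0).t();
  mat dcols = w * dY.t();             // (k*k*C, H*W)
  cube dx = col2im(dcols, H, W, C, k);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_pool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  cube y(H2, W2, C);
  IntegerVector idx((uword)H2 * W2 * C);
  uword t = 0;
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        double best = -datum::inf; uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const uword li = (uword)(2 * i + di) + (uword)H * (2 * j + dj) + (uword)H * W * c;
            const double v = xs(2 * i + di, 2 * j + dj);
            if (v > best) { best = v; bi = li; }
          }
        }
        y(i, j, c) = best;
        idx[t] = (int)bi;  // 0-based linear index into x
        ++t;
      }
    }
  }
  // order of idx matches column-major order of y
  IntegerVector ord((uword)H2 * W2 * C);
  // re-fill in y's memory order (c outer, j, i inner == our loop order? our loop
  // order is c, j, i with i fastest -> matches column-major within slice, slices
  // outermost: exactly y's layout). idx already in y's order; loop above filled
  // idx sequentially in that order via t.
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_pool_bwd(const Rcpp::IntegerVector& idx, const arma::cube& dy,
                        int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  double* p = dx.memptr();
  const double* g = dy.memptr();
  const uword n = dy.n_elem;
  for (uword t = 0; t < n; ++t) p[idx[t]] += g[t];
  return dx;
}

// Transposed convolution, kernel 4, stride 2, pad 1: out (2H, 2W, Cout).
// out(2i + a - 1, 2j + b - 1, co) += x(i, j, ci) * w[ci + Cin*(a + 4b), co]
// [[Rcpp::export]]
arma::cube cpp_deconv_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols;
  const int Ho = 2 * H, Wo = 2 * W;
  cube out(Ho, Wo, Cout, fill::zeros);
  mat X(const_cast<double*>(x.memptr()), (uword)H * W, Cin, false, true);
  for (int bb = 0; bb < 4; ++bb) {
    for (int a = 0; a < 4; ++a) {
      const mat Wab = w.rows(Cin * (a + 4 * bb), Cin * (a + 4 * bb) + Cin - 1);
      mat M = X * Wab;                // (H*W, Cout)
      // valid i: 0 <= 2i+a-1 < Ho ; a=0 -> i>=1 ; a=3 -> 2i+2<=Ho-1 -> i<=H-2
      const int i0 = (a == 0) ? 1 : 0;
      const int i1 = (a == 3) ? H - 1 : H;
      const int j0 = (bb == 0) ? 1 : 0;
      const int j1 = (bb == 3) ? W - 1 : W;
      for (int co = 0; co < Cout; ++co) {
        for (int j = j0; j < j1; ++j) {
          double* dst = out.slice(co).colptr(2 * j + bb - 1);
          const double* src = M.colptr(co) + (uword)H * j;
          for (int i = i0; i < i1; ++i) dst[2 * i + a - 1] += src[i];
        }
      }
    }
  }
  for (int co = 0; co < Cout; ++co) out.slice(co) += b(co);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_deconv_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  mat X(const_cast<double*>(x.memptr()), (uword)H * W, Cin, false, true);
  mat dX((uword)H * W, Cin, fill::zeros);
  mat dw(16 * Cin, Cout, fill::zeros);
  vec db(Cout, fill::zeros);
  for (int co = 0; co < Cout; ++co) db(co) = accu(dy.slice(co));
  mat G((uword)H * W, Cout);
  for (int bb = 0; bb < 4; ++bb) {
    for (int a = 0; a < 4; ++a) {
      G.zeros();
      const int i0 = (a == 0) ? 1 : 0;
      const int i1 = (a == 3) ? H - 1 : H;
      const int j0 = (bb == 0) ? 1 : 0;
      const int j1 = (bb == 3) ? W - 1 : W;
      for (int co = 0; co < Cout; ++co) {
        for (int j = j0; j < j1; ++j) {
          const double* src = dy.slice(co).colptr(2 * j + bb - 1);
          double* dst = G.colptr(co) + (uword)H * j;
          for (int i = i0; i < i1; ++i) dst[i] = src[2 * i + a - 1];
        }
      }
      const mat Wab = w.rows(Cin * (a + 4 * bb), Cin * (a + 4 * bb) + Cin - 1);
      dX += G * Wab.t();
      dw.rows(Cin * (a + 4 * bb), Cin * (a + 4 * bb) + Cin - 1) = X.t() * G;
    }
  }
  cube dxc(H, W, Cin);
  std::memcpy(dxc.memptr(), dX.memptr(), sizeof(double) * dX.n_elem);
  return List::create(_["dx"] = dxc, _["dw"] = dw, _["db"] = db);
}

// 8-connected component labelling of a binary matrix; labels 1..n in
// first-encounter (column-major) order, background stays 0.
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_label8(const Rcpp::IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + H * qj);
            }
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -datum::inf;
  z[1] = datum::inf;
  bool any = std::isfinite(f[0]) || f[0] == 0.0;
  // lower envelope; handle +inf parabolas by skipping
  int first = -1;
  for (int q = 0; q < n; ++q) if (f[q] < datum::inf) { first = q; break; }
  if (first < 0) { for (int q = 0; q < n; ++q) d[q] = datum::inf; return; }
  k = 0; v[0] = first; z[0] = -datum::inf; z[1] = datum::inf;
  for (int q = first + 1; q < n; ++q) {
    if (!(f[q] < datum::inf)) continue;
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = datum::inf;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    const double dq = q - v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
  (void)any;
}

// Exact squared Euclidean distance (in pixels) from every pixel to the nearest
// nonzero ("feature") pixel. All-zero input -> all +Inf.
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_sqedt(const Rcpp::IntegerMatrix& feat) {
  const int H = feat.nrow(), W = feat.ncol();
  NumericMatrix out(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  // pass 1: along columns
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = feat(i, j) != 0 ? 0.0 : datum::inf;
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) out(i, j) = d[i];
  }
  // pass 2: along rows
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = out(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) out(i, j) = d[j];
  }
  return out;
}
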