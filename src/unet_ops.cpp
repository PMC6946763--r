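// Numerical kernels for the U-Net segmenter and skeleton thinning.
// Feature maps are H x W x C cubes; convolution is same-padding, stride 1,
// implemented as im2col + GEMM so OpenBLAS does the heavy lifting.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Column layout: row index = c * k * k + dy * k + dx, one column per output
// pixel in column-major (R array) pixel order. Weights are (Cout x Cin*k*k).
static mat im2col(const cube& x, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(C * k * k, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int r = c * k * k + dy * k + dx;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dy - pad;
            if (si < 0 || si >= H) continue;
            cols(r, j * H + i) = x(si, sj, c);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k, const int pad) {
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int r = c * k * k + dy * k + dx;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dy - pad;
            if (si < 0 || si >= H) continue;
            x(si, sj, c) += cols(r, j * H + i);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".nq_conv_fwd")]]
arma::cube nq_conv_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols;
  mat out = w * im2col(x, k, pad);      // Cout x (H*W)
  out.each_col() += b;
  cube y(H, W, w.n_rows);
  for (unsigned c = 0; c < w.n_rows; ++c)
    y.slice(c) = reshape(out.row(c), H, W);
  return y;
}

// [[Rcpp::export(name = ".nq_conv_bwd")]]
Rcpp::List nq_conv_bwd(const arma::cube& x, const arma::mat& w,
                       const arma::cube& gout, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gout.n_slices;
  mat g(Cout, H * W);
  for (int c = 0; c < Cout; ++c)
    g.row(c) = vectorise(gout.slice(c)).t();
  mat cols = im2col(x, k, pad);
  mat dw = g * cols.t();
  vec db = sum(g, 1);
  cube dx = col2im(w.t() * g, H, W, C, k, pad);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling; idx records the flat (i,j,c) position of each maximum so
// the backward pass can scatter gradients.
// [[Rcpp::export(name = ".nq_pool_fwd")]]
Rcpp::List nq_pool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  umat idx(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf; int bi = 0, bj = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        y(i, j, c) = best;
        idx(j * Ho + i, c) = (uword)(c * H * W + bj * H + bi);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".nq_pool_bwd")]]
arma::cube nq_pool_bwd(const arma::umat& idx, const arma::cube& gout,
                       const int H, const int W) {
  const int C = gout.n_slices;
  cube dx(H, W, C, fill::zeros);
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dx(idx(j * Ho + i, c)) += gout(i, j, c);
  return dx;
}

// [[Rcpp::export(name = ".nq_upsample_fwd")]]
arma::cube nq_upsample_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;     y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".nq_upsample_bwd")]]
arma::cube nq_upsample_bwd(const arma::cube& gout) {
  const int H = gout.n_rows / 2, W = gout.n_cols / 2, C = gout.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = gout(2 * i, 2 * j, c) + gout(2 * i + 1, 2 * j, c) +
                      gout(2 * i, 2 * j + 1, c) + gout(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// ---- Zhang-Suen thinning ---------------------------------------------------

static inline int nb(const imat& m, int i, int j, int* p) {
  // p2..p9 clockwise from north, in a 1-padded matrix
  p[0] = m(i - 1, j);     p[1] = m(i - 1, j + 1);
  p[2] = m(i, j + 1);     p[3] = m(i + 1, j + 1);
  p[4] = m(i + 1, j);     p[5] = m(i + 1, j - 1);
  p[6] = m(i, j - 1);     p[7] = m(i - 1, j - 1);
  return p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
}

static inline int transitions(const int* p) {
  int a = 0;
  for (int t = 0; t < 8; ++t) a += (p[t] == 0 && p[(t + 1) % 8] == 1);
  return a;
}

// number of 8-connected components the foreground 8-neighbours of (i,j)
// form among themselves (full diagonal adjacency, not through (i,j))
static int neighbourhood_components(const imat& m, int i, int j) {
  int di[8], dj[8], n = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b) {
      if (a == 0 && b == 0) continue;
      if (m(i + a, j + b) == 1) { di[n] = a; dj[n] = b; ++n; }
    }
  if (n == 0) return 0;
  int comp[8];
  for (int a = 0; a < n; ++a) comp[a] = a;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      if (std::abs(di[a] - di[b]) <= 1 && std::abs(dj[a] - dj[b]) <= 1) {
        const int ca = comp[a], cb = comp[b];
        if (ca != cb)
          for (int t = 0; t < n; ++t) if (comp[t] == cb) comp[t] = ca;
      }
  int k = 0;
  for (int a = 0; a < n; ++a) if (comp[a] == a) ++k;
  return k;
}

// [[Rcpp::export(name = ".nq_thin")]]
arma::imat nq_thin(const arma::imat& input) {
  const int H = input.n_rows, W = input.n_cols;
  imat m(H + 2, W + 2, fill::zeros);
  m.submat(1, 1, H, W) = clamp(input, 0, 1);
  int p[8];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      std::vector<std::pair<int, int> > kill;
      for (int j = 1; j <= W; ++j)
        for (int i = 1; i <= H; ++i) {
          if (m(i, j) != 1) continue;
          const int B = nb(m, i, j, p);
          if (B < 2 || B > 6) continue;
          if (transitions(p) != 1) continue;
          // p[0]=N, p[2]=E, p[4]=S, p[6]=W
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      for (size_t t = 0; t < kill.size(); ++t)
        m(kill[t].first, kill[t].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  // cleanup to a minimal skeleton: sequentially delete redundant pixels --
  // non-endpoints whose foreground neighbours form a single 8-connected
  // set, so removal changes neither connectivity nor topology. This
  // dissolves residual 2x2 blocks and the staircase-corner pixels that
  // Zhang-Suen leaves, which would otherwise read as false degree-3 nodes.
  changed = true;
  while (changed) {
    changed = false;
    for (int j = 1; j <= W; ++j)
      for (int i = 1; i <= H; ++i) {
        if (m(i, j) != 1) continue;
        const int B = nb(m, i, j, p);
        if (B >= 2 && B <= 6 && neighbourhood_components(m, i, j) == 1) {
          m(i, j) = 0; changed = true;
        }
      }
  }
  return m.submat(1, 1, H, W);
}
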