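// Low-level numerical kernels: 3x3 "same" convolutions (im2col + GEMM) with
// their gradients, 2x2 max-pooling, nearest-neighbour upsampling, 4/8-connected
// component labelling, and a marker-seeded priority-flood watershed.
//
// Conventions shared with the R side:
//  * images are H x W matrices, feature stacks are H x W x C arrays
//    (column-major, identical to arma::cube layout);
//  * a 3x3 conv weight is a (9*Cin) x Cout matrix whose column index for input
//    channel c (0-based) and kernel offset (di, dj), di/dj in {-1,0,1}, is
//    c*9 + (di+1) + 3*(dj+1);
//  * zero padding at the image border.

#include <RcppArmadillo.h>
#include <queue>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col3(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(static_cast<size_t>(H) * W, 9 * static_cast<size_t>(C),
                arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (di + 1) + 3 * (dj + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            if (is < 0 || is >= H) continue;
            out(i + static_cast<size_t>(H) * j, col) = x(is, js, c);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv3_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  if (static_cast<int>(w.n_rows) != 9 * static_cast<int>(x.n_slices))
    stop("conv3_fwd: weight rows do not match 9 * input channels");
  arma::mat y = im2col3(x) * w;
  y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::cube& x, const arma::mat& w,
                   const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat gymat(const_cast<double*>(gy.memptr()),
                  static_cast<size_t>(H) * W, Cout, false, true);
  arma::mat cols = im2col3(x);
  arma::mat gw = cols.t() * gymat;
  arma::vec gb = arma::sum(gymat, 0).t();
  arma::mat gcols = gymat * w.t();  // (H*W) x (9*Cin)
  arma::cube gx(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (di + 1) + 3 * (dj + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            if (is < 0 || is >= H) continue;
            gx(is, js, c) += gcols(i + static_cast<size_t>(H) * j, col);
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool2: odd spatial dimensions");
  const int h = H / 2, wo = W / 2;
  arma::cube y(h, wo, C);
  IntegerVector idx(static_cast<R_xlen_t>(h) * wo * C);
  R_xlen_t q = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bi = 2 * i, bj = 2 * j;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        y(i, j, c) = best;
        idx[q++] = bi + H * bj + H * W * c;  // 0-based linear index into x
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const IntegerVector& idx, const arma::cube& gy,
                            int H, int W) {
  const int C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  const double* g = gy.memptr();
  for (R_xlen_t q = 0; q < idx.size(); ++q) gx.memptr()[idx[q]] += g[q];
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        y(i, j, c) = x(i / 2, j / 2, c);
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        gx(i / 2, j / 2, c) += gy(i, j, c);
  return gx;
}

// ---------------------------------------------------------------------------
// Connected components (BFS) with selectable connectivity.

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  const int ndir = (connectivity == 8) ? 8 : 4;
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  for (int j0 = 0; j0 < W; ++j0) {
    for (int i0 = 0; i0 < H; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      ++next;
      lab(i0, j0) = next;
      stack.clear();
      stack.push_back(i0 + H * j0);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int d = 0; d < ndir; ++d) {
          const int ni = pi + di[d], nj = pj + dj[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni + H * nj);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Marker-seeded watershed by priority flooding: pixels are claimed in order of
// decreasing dmap value (FIFO among ties), growing 8-connected from the seed
// labels and restricted to the foreground mask.

struct QItem {
  double p;
  long long t;
  int idx;
  int lab;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.p != b.p) return a.p < b.p;  // larger dmap first
    return a.t > b.t;                  // FIFO among ties
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_priority_flood(const NumericMatrix& dmap,
                                 const LogicalMatrix& fg,
                                 const IntegerMatrix& seeds) {
  const int H = dmap.nrow(), W = dmap.ncol();
  if (fg.nrow() != H || fg.ncol() != W || seeds.nrow() != H ||
      seeds.ncol() != W)
    stop("priority_flood: shape mismatch");
  IntegerMatrix lab(H, W);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long counter = 0;
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (seeds(i, j) > 0) lab(i, j) = seeds(i, j);
  // enqueue unlabelled foreground neighbours of every seed pixel
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (lab(i, j) == 0) continue;
      for (int d = 0; d < 8; ++d) {
        const int ni = i + di[d], nj = j + dj[d];
        if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
        if (fg(ni, nj) && lab(ni, nj) == 0)
          pq.push({dmap(ni, nj), counter++, ni + H * nj, lab(i, j)});
      }
    }
  }
  while (!pq.empty()) {
    const QItem it = pq.top();
    pq.pop();
    const int pi = it.idx % H, pj = it.idx / H;
    if (lab(pi, pj)) continue;
    lab(pi, pj) = it.lab;
    for (int d = 0; d < 8; ++d) {
      const int ni = pi + di[d], nj = pj + dj[d];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      if (fg(ni, nj) && lab(ni, nj) == 0)
        pq.push({dmap(ni, nj), counter++, ni + H * nj, it.lab});
    }
  }
  return lab;
}
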