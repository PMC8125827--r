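// Minimal CPU convolutional engine used by the network module.
// Tensors are dense cubes laid out H x W x C (matching R arrays dim c(H, W, C)).
// 3x3/1x1 convolutions run as im2col + GEMM; the 2x2 stride-2 transposed
// convolution and max-pooling are written directly. Every forward has a
// matching analytic backward; correctness is pinned by finite-difference
// tests on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col with zero padding pad = (k-1)/2, stride 1.
// Column index for output pixel (i, j) is j*H + i (column-major, as in R).
// Row index: ci*k*k + dj*k + di addresses input pixel (i-pad+di, j-pad+dj, ci).
static arma::mat im2col_same(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  arma::mat col(k * k * C, H * W, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = ci * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int jj = j - pad + dj;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i - pad + di;
            if (ii < 0 || ii >= H) continue;
            col(r, j * H + i) = x(ii, jj, ci);
          }
        }
      }
    }
  }
  return col;
}

static arma::cube col2im_same(const arma::mat& col, int H, int W, int C, int k) {
  const int pad = (k - 1) / 2;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = ci * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int jj = j - pad + dj;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i - pad + di;
            if (ii < 0 || ii >= H) continue;
            x(ii, jj, ci) += col(r, j * H + i);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, int k, bool relu) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  arma::mat col = im2col_same(x, k);
  arma::mat y = W.t() * col;            // Cout x (H*W)
  y.each_col() += b;
  if (relu) y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  arma::cube out(H, Wd, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.row(c), H, Wd);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const arma::mat& W, const arma::cube& out,
                const arma::cube& dout, int k, bool relu) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  arma::mat dy(Cout, H * Wd);
  for (int c = 0; c < Cout; ++c) {
    arma::mat g = dout.slice(c);
    if (relu) g %= arma::conv_to<arma::mat>::from(out.slice(c) > 0.0);
    dy.row(c) = arma::vectorise(g).t();
  }
  arma::mat col = im2col_same(x, k);
  arma::mat dW = col * dy.t();          // (k*k*Cin) x Cout
  arma::vec db = arma::sum(dy, 1);
  arma::cube dx = col2im_same(W * dy, H, Wd, Cin, k);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);           // linear index into x of the max
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) {
              best = v;
              bi = (arma::uword)c * H * W + (arma::uword)jj * H + ii;
            }
          }
        }
        out(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::ucube& idx, const arma::cube& dout,
                        int H, int W) {
  const int C = dout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const arma::uword n = idx.n_elem;
  for (arma::uword e = 0; e < n; ++e) dx(idx(e)) += dout(e);
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2 (doubles spatial size).
// M is (4*Cout) x Cin; row co*4 + dj*2 + di writes output pixel
// (2i+di, 2j+dj, co) from input pixel (i, j, :).
// [[Rcpp::export(name = ".deconv2_fwd")]]
arma::cube deconv2_fwd(const arma::cube& x, const arma::mat& M,
                       const arma::vec& b, bool relu) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = M.n_rows / 4;
  arma::mat X(Cin, H * W);
  for (int c = 0; c < Cin; ++c) X.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat Y = M * X;                  // (4*Cout) x (H*W)
  arma::cube out(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        const int r = co * 4 + dj * 2 + di;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            double v = Y(r, j * H + i) + b(co);
            if (relu && v < 0.0) v = 0.0;
            out(2 * i + di, 2 * j + dj, co) = v;
          }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".deconv2_bwd")]]
List deconv2_bwd(const arma::cube& x, const arma::mat& M, const arma::cube& out,
                 const arma::cube& dout, bool relu) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = M.n_rows / 4;
  arma::mat X(Cin, H * W);
  for (int c = 0; c < Cin; ++c) X.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat dY(4 * Cout, H * W);
  arma::vec db(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        const int r = co * 4 + dj * 2 + di;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            double g = dout(2 * i + di, 2 * j + dj, co);
            if (relu && out(2 * i + di, 2 * j + dj, co) <= 0.0) g = 0.0;
            dY(r, j * H + i) = g;
            db(co) += g;
          }
      }
    }
  }
  arma::mat dM = dY * X.t();
  arma::mat dXm = M.t() * dY;           // Cin x (H*W)
  arma::cube dx(H, W, Cin);
  for (int c = 0; c < Cin; ++c) dx.slice(c) = arma::reshape(dXm.row(c), H, W);
  return List::create(_["dx"] = dx, _["dW"] = dM, _["db"] = db);
}

// All-pairs minimum Euclidean distances between two point sets (n x 2 each):
// for every point in A, the distance to the nearest point in B. Used by the
// surface-distance metrics; kept simple and exact.
// [[Rcpp::export(name = ".min_dists")]]
arma::vec min_dists(const arma::mat& A, const arma::mat& B) {
  const arma::uword nA = A.n_rows, nB = B.n_rows;
  arma::vec out(nA);
  for (arma::uword i = 0; i < nA; ++i) {
    double best = arma::datum::inf;
    for (arma::uword j = 0; j < nB; ++j) {
      const double dr = A(i, 0) - B(j, 0), dc = A(i, 1) - B(j, 1);
      const double d2 = dr * dr + dc * dc;
      if (d2 < best) best = d2;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}
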