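// Convolution and batch-norm primitives for the autoencoder stack.
//
// Activation layout: one sample per column; within a column the element for
// (h, w, c) sits at row  h + H*w + H*W*c  (row index fastest, channel
// slowest), matching an R array of dim c(H, W, C) flattened by as.vector().
// All convolutions are 3x3 with padding 1; stride is 1 or 2.
//
// im2col uses a pixel-major patch matrix, (P*B) x (C*9) with the output
// pixel fastest, so both the fill loops and the GEMMs touch memory
// contiguously.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int H, int stride) {
  return (H + 2 - 3) / stride + 1;
}

// grow-only scratch buffers reused across calls (single-threaded R);
// avoids re-faulting hundreds of MB of fresh pages on every minibatch.
// Convolutions run in single precision internally: the patch matrices are
// the dominant memory traffic and the reduced precision is far below the
// optimization noise floor.
static arma::fmat scratch_view(int id, size_t r, size_t c) {
  static std::vector<std::vector<float>> bufs(8);
  std::vector<float>& buf = bufs.at(id);
  if (buf.size() < r * c) buf.resize(r * c);
  return arma::fmat(buf.data(), r, c, false, true);
}

// double <-> float conversions through reusable buffers
static arma::fmat to_f(int id, const arma::mat& X) {
  arma::fmat F = scratch_view(id, X.n_rows, X.n_cols);
  const double* src = X.memptr();
  float* dst = F.memptr();
  const size_t n = X.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return F;
}

static arma::mat to_d(const arma::fmat& F) {
  arma::mat X(F.n_rows, F.n_cols);
  const float* src = F.memptr();
  double* dst = X.memptr();
  const size_t n = F.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return X;
}

// patch matrix: (Ho*Wo*B) x (C*9); row = ho + Ho*wo + Ho*Wo*b,
// col = kh + 3*kw + 9*c
static void im2col_into(arma::fmat& col, const arma::fmat& X, int C, int H,
                        int W, int stride) {
  const int B = X.n_cols;
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const size_t P = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh) {
        float* cc = col.colptr(kh + 3 * kw + 9 * c);
        for (int b = 0; b < B; ++b) {
          const float* xc = X.colptr(b) + (size_t)c * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            float* dst = cc + P * b + (size_t)Ho * wo;
            const int w = wo * stride + kw - 1;
            if (w < 0 || w >= W) {         // padding column
              std::memset(dst, 0, Ho * sizeof(float));
              continue;
            }
            const float* src = xc + (size_t)w * H + (kh - 1);
            const int h0 = (kh - 1 < 0) ? 1 : 0;
            const int h1 = (Ho - 1) * stride + kh - 1 >= H ? Ho - 1 : Ho;
            if (h0 > 0) dst[0] = 0.0f;
            if (h1 < Ho) dst[Ho - 1] = 0.0f;
            if (stride == 1) {
              for (int ho = h0; ho < h1; ++ho) dst[ho] = src[ho];
            } else {
              for (int ho = h0; ho < h1; ++ho) dst[ho] = src[2 * ho];
            }
          }
        }
      }
}

// adjoint of im2col (scatter-add back to zero-initialized X)
static void col2im_into(arma::fmat& X, const arma::fmat& col, int C, int H,
                        int W, int stride, int B) {
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const size_t P = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh) {
        const float* cc = col.colptr(kh + 3 * kw + 9 * c);
        for (int b = 0; b < B; ++b) {
          float* xc = X.colptr(b) + (size_t)c * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride + kw - 1;
            if (w < 0 || w >= W) continue;
            const float* src = cc + P * b + (size_t)Ho * wo;
            float* dst = xc + (size_t)w * H + (kh - 1);
            const int h0 = (kh - 1 < 0) ? 1 : 0;
            const int h1 = (Ho - 1) * stride + kh - 1 >= H ? Ho - 1 : Ho;
            if (stride == 1) {
              for (int ho = h0; ho < h1; ++ho) dst[ho] += src[ho];
            } else {
              for (int ho = h0; ho < h1; ++ho) dst[2 * ho] += src[ho];
            }
          }
        }
      }
}

// (P*Cout x B) activation <-> (P*B x Cout) gemm layout (contiguous copies)
static void act2gemm_into(arma::fmat& G, const arma::fmat& Y, int Cout,
                          size_t P) {
  const int B = Y.n_cols;
  for (int c = 0; c < Cout; ++c) {
    float* g = G.colptr(c);
    for (int b = 0; b < B; ++b)
      std::memcpy(g + P * b, Y.colptr(b) + P * c, P * sizeof(float));
  }
}

static arma::mat gemm2act(const arma::fmat& G, int Cout, size_t P, int B) {
  arma::mat Y(P * Cout, B);
  for (int c = 0; c < Cout; ++c) {
    const float* g = G.colptr(c);
    for (int b = 0; b < B; ++b) {
      double* dst = Y.colptr(b) + P * c;
      const float* src = g + P * b;
      for (size_t p = 0; p < P; ++p) dst[p] = (double)src[p];
    }
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, const arma::mat& Wt,
                       const arma::vec& bias, int C, int H, int W,
                       int stride) {
  const int B = X.n_cols;
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const size_t P = (size_t)Ho * Wo;
  arma::fmat fX = to_f(4, X);
  arma::fmat fW = arma::conv_to<arma::fmat>::from(Wt);
  arma::fmat col = scratch_view(0, P * B, (size_t)C * 9);
  im2col_into(col, fX, C, H, W, stride);
  arma::fmat G = scratch_view(1, P * B, Wt.n_rows);
  G = col * fW.t();                         // P*B x Cout
  G.each_row() += arma::conv_to<arma::frowvec>::from(bias.t());
  return gemm2act(G, Wt.n_rows, P, B);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& X, const arma::mat& Wt, const arma::mat& dY,
                  int C, int H, int W, int stride) {
  const int B = X.n_cols;
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const size_t P = (size_t)Ho * Wo;
  const int Cout = Wt.n_rows;
  arma::fmat fX = to_f(4, X);
  arma::fmat fW = arma::conv_to<arma::fmat>::from(Wt);
  arma::fmat col = scratch_view(0, P * B, (size_t)C * 9);
  im2col_into(col, fX, C, H, W, stride);
  arma::fmat dG = scratch_view(1, P * B, Cout);
  arma::fmat fdY = to_f(5, dY);
  act2gemm_into(dG, fdY, Cout, P);          // P*B x Cout
  arma::mat dW = to_d(dG.t() * col);        // Cout x C*9
  arma::vec db = arma::conv_to<arma::vec>::from(arma::sum(dG, 0).t());
  arma::fmat dcol = scratch_view(2, P * B, (size_t)C * 9);
  dcol = dG * fW;                           // P*B x C*9
  arma::fmat fdX = scratch_view(4, (size_t)C * H * W, B);
  fdX.zeros();
  col2im_into(fdX, dcol, C, H, W, stride, B);
  return List::create(_["dX"] = to_d(fdX), _["dW"] = dW, _["db"] = db);
}

// Transposed conv, stride 2, doubling H and W.  Parameterized by the weight
// V (Cin x Cout*9) of the adjoint convolution (Cout, 2H, 2W) -> (Cin, H, W).
// [[Rcpp::export]]
arma::mat cpp_convt_fwd(const arma::mat& X, const arma::mat& V,
                        const arma::vec& bias, int Cin, int Cout, int H,
                        int W) {
  const int B = X.n_cols;
  const int Hb = 2 * H, Wb = 2 * W;
  const size_t P = (size_t)H * W, Pb = (size_t)Hb * Wb;
  arma::fmat fX = to_f(4, X);
  arma::fmat fV = arma::conv_to<arma::fmat>::from(V);
  arma::fmat G = scratch_view(1, P * B, Cin);
  act2gemm_into(G, fX, Cin, P);             // P*B x Cin
  arma::fmat dcol = scratch_view(2, P * B, (size_t)Cout * 9);
  dcol = G * fV;                            // P*B x Cout*9
  arma::fmat fY = scratch_view(5, (size_t)Cout * Hb * Wb, B);
  fY.zeros();
  col2im_into(fY, dcol, Cout, Hb, Wb, 2, B);
  arma::mat Y = to_d(fY);
  for (int b = 0; b < B; ++b) {
    double* yb = Y.colptr(b);
    for (int c = 0; c < Cout; ++c) {
      double* yc = yb + Pb * c;
      const double bc = bias(c);
      for (size_t p = 0; p < Pb; ++p) yc[p] += bc;
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_convt_bwd(const arma::mat& X, const arma::mat& V, const arma::mat& dY,
                   int Cin, int Cout, int H, int W) {
  const int B = X.n_cols;
  const int Hb = 2 * H, Wb = 2 * W;
  const size_t P = (size_t)H * W, Pb = (size_t)Hb * Wb;
  arma::fmat fdY = to_f(5, dY);
  arma::fmat fV = arma::conv_to<arma::fmat>::from(V);
  arma::fmat colb = scratch_view(0, P * B, (size_t)Cout * 9);
  im2col_into(colb, fdY, Cout, Hb, Wb, 2);  // P*B x Cout*9
  arma::fmat G = scratch_view(1, P * B, Cin);
  G = colb * fV.t();                        // P*B x Cin
  arma::mat dX = gemm2act(G, Cin, P, B);
  arma::fmat fX = to_f(4, X);
  arma::fmat Xg = scratch_view(3, P * B, Cin);
  act2gemm_into(Xg, fX, Cin, P);            // P*B x Cin
  arma::mat dV = to_d(Xg.t() * colb);       // Cin x Cout*9
  arma::vec db(Cout, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* yb = dY.colptr(b);
    for (int c = 0; c < Cout; ++c) {
      const double* yc = yb + Pb * c;
      double s = 0.0;
      for (size_t p = 0; p < Pb; ++p) s += yc[p];
      db(c) += s;
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dV, _["db"] = db);
}

// per-channel mean and (biased) variance over batch and space
// [[Rcpp::export]]
List cpp_channel_stats(const arma::mat& X, int P) {
  const int B = X.n_cols, C = X.n_rows / P;
  arma::vec mu(C, arma::fill::zeros), v(C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* xb = X.colptr(b);
    for (int c = 0; c < C; ++c) {
      const double* xc = xb + (size_t)P * c;
      double s = 0, s2 = 0;
      for (int p = 0; p < P; ++p) { s += xc[p]; s2 += xc[p] * xc[p]; }
      mu(c) += s; v(c) += s2;
    }
  }
  const double n = (double)P * B;
  mu /= n; v = v / n - mu % mu;
  return List::create(_["mean"] = mu, _["var"] = v);
}

// normalize with given per-channel stats: out = xhat*gamma + beta
// [[Rcpp::export]]
List cpp_bn_apply(const arma::mat& X, const arma::vec& mu,
                  const arma::vec& invstd, const arma::vec& gamma,
                  const arma::vec& beta, int P) {
  const int B = X.n_cols, C = X.n_rows / P;
  arma::mat xhat(X.n_rows, B), out(X.n_rows, B);
  for (int b = 0; b < B; ++b) {
    const double* xb = X.colptr(b);
    double* hb = xhat.colptr(b);
    double* ob = out.colptr(b);
    for (int c = 0; c < C; ++c) {
      const double m = mu(c), is = invstd(c), g = gamma(c), be = beta(c);
      const double* xc = xb + (size_t)P * c;
      double* hc = hb + (size_t)P * c;
      double* oc = ob + (size_t)P * c;
      for (int p = 0; p < P; ++p) {
        const double h = (xc[p] - m) * is;
        hc[p] = h; oc[p] = h * g + be;
      }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// batch-norm backward (train mode uses batch statistics)
// [[Rcpp::export]]
List cpp_bn_bwd(const arma::mat& dY, const arma::mat& xhat,
                const arma::vec& invstd, const arma::vec& gamma, int P,
                bool train) {
  const int B = dY.n_cols, C = dY.n_rows / P;
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* db_ = dY.colptr(b);
    const double* hb = xhat.colptr(b);
    for (int c = 0; c < C; ++c) {
      const double* dc = db_ + (size_t)P * c;
      const double* hc = hb + (size_t)P * c;
      double s1 = 0, s2 = 0;
      for (int p = 0; p < P; ++p) { s1 += dc[p]; s2 += dc[p] * hc[p]; }
      dbeta(c) += s1; dgamma(c) += s2;
    }
  }
  arma::mat dX(dY.n_rows, B);
  const double n = (double)P * B;
  for (int b = 0; b < B; ++b) {
    const double* dyb = dY.colptr(b);
    const double* hb = xhat.colptr(b);
    double* dxb = dX.colptr(b);
    for (int c = 0; c < C; ++c) {
      const double g = gamma(c), is = invstd(c);
      const double m1 = train ? dbeta(c) / n : 0.0;
      const double m2 = train ? dgamma(c) / n : 0.0;
      const double* dc = dyb + (size_t)P * c;
      const double* hc = hb + (size_t)P * c;
      double* dxc = dxb + (size_t)P * c;
      for (int p = 0; p < P; ++p)
        dxc[p] = g * is * (dc[p] - m1 - hc[p] * m2);
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Aperture rasterization: rows are fine leaf-index pixels, cols are fine
// position pixels.  pair_of_row is 1-based; a pixel is open iff the column
// center lies strictly inside (left, right) of its row's leaf pair.
// [[Rcpp::export]]
arma::mat cpp_rasterize(const arma::vec& left, const arma::vec& right,
                        const arma::ivec& pair_of_row,
                        const arma::vec& centers) {
  const int NL = pair_of_row.n_elem, NP = centers.n_elem;
  arma::mat A(NL, NP, arma::fill::zeros);
  for (int j = 0; j < NP; ++j) {
    const double x = centers(j);
    double* aj = A.colptr(j);
    for (int i = 0; i < NL; ++i) {
      const int p = pair_of_row(i) - 1;
      if (x > left(p) && x < right(p)) aj[i] = 1.0;
    }
  }
  return A;
}

// [[Rcpp::export]]
arma::mat cpp_block_mean(const arma::mat& M, int fr, int fc) {
  const int nr = M.n_rows / fr, nc = M.n_cols / fc;
  arma::mat out(nr, nc, arma::fill::zeros);
  for (int j = 0; j < (int)M.n_cols; ++j) {
    const int jo = j / fc;
    double* oj = out.colptr(jo);
    const double* mj = M.colptr(j);
    for (int i = 0; i < (int)M.n_rows; ++i) oj[i / fr] += mj[i];
  }
  out /= (double)(fr * fc);
  return out;
}

// pointwise (1x1) convolution over channels
// [[Rcpp::export]]
arma::mat cpp_conv1_fwd(const arma::mat& X, const arma::mat& Wt,
                        const arma::vec& bias, int C, int P) {
  const int B = X.n_cols;
  arma::fmat fX = to_f(4, X);
  arma::fmat fW = arma::conv_to<arma::fmat>::from(Wt);
  arma::fmat G = scratch_view(1, (size_t)P * B, C);
  act2gemm_into(G, fX, C, P);
  arma::fmat O = scratch_view(2, (size_t)P * B, Wt.n_rows);
  O = G * fW.t();
  O.each_row() += arma::conv_to<arma::frowvec>::from(bias.t());
  return gemm2act(O, Wt.n_rows, P, B);
}

// [[Rcpp::export]]
List cpp_conv1_bwd(const arma::mat& X, const arma::mat& Wt,
                   const arma::mat& dY, int C, int P) {
  const int B = X.n_cols;
  const int Cout = Wt.n_rows;
  arma::fmat fX = to_f(4, X);
  arma::fmat fdY = to_f(5, dY);
  arma::fmat fW = arma::conv_to<arma::fmat>::from(Wt);
  arma::fmat G = scratch_view(1, (size_t)P * B, C);
  act2gemm_into(G, fX, C, P);
  arma::fmat dG = scratch_view(2, (size_t)P * B, Cout);
  act2gemm_into(dG, fdY, Cout, P);
  arma::mat dW = to_d(dG.t() * G);
  arma::vec db = arma::conv_to<arma::vec>::from(arma::sum(dG, 0).t());
  arma::fmat dXg = scratch_view(3, (size_t)P * B, C);
  dXg = dG * fW;
  arma::mat dX = gemm2act(dXg, C, P, B);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// fused ReLU: forward clamps; backward gates by the cached output
// [[Rcpp::export]]
arma::mat cpp_relu_fwd(const arma::mat& X) {
  arma::mat Y(X.n_rows, X.n_cols);
  const double* x = X.memptr();
  double* y = Y.memptr();
  const size_t n = X.n_elem;
  for (size_t i = 0; i < n; ++i) y[i] = x[i] > 0.0 ? x[i] : 0.0;
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_relu_bwd(const arma::mat& dY, const arma::mat& out) {
  arma::mat dX(dY.n_rows, dY.n_cols);
  const double* d = dY.memptr();
  const double* o = out.memptr();
  double* r = dX.memptr();
  const size_t n = dY.n_elem;
  for (size_t i = 0; i < n; ++i) r[i] = o[i] > 0.0 ? d[i] : 0.0;
  return dX;
}
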