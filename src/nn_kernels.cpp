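// Hot-path kernels for the CNN-LSTM classifiers.
//
// Batches are dense cubes laid out (N, T, C): batch x time x feature
// channels, matching the R arrays bit for bit. Convolutions use 'same'
// zero padding with an odd kernel and are lowered to one GEMM via
// im2col; the im2col matrix is rebuilt in the backward pass instead of
// being cached across the R boundary. All computation is single-
// threaded BLAS, so results are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a (N, T, Cin) cube, kernel k, same padding.
// Column order: tap-major, channel-minor (col = d*Cin + c), matching
// the (k*Cin, F) weight layout on the R side.
static mat im2col_same(const cube& X, int k) {
  const int N = X.n_rows, T = X.n_cols, Cin = X.n_slices;
  const int P = (k - 1) / 2;
  mat Xcol(N * T, k * Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int d = 0; d < k; ++d) {
      const int col = d * Cin + c;
      for (int t = 0; t < T; ++t) {
        const int src = t + d - P;
        if (src < 0 || src >= T) continue;
        Xcol.col(col).subvec(t * N, t * N + N - 1) = X.slice(c).col(src);
      }
    }
  }
  return Xcol;
}

// [[Rcpp::export(name = ".cpp_conv1d_fwd")]]
Rcpp::List cpp_conv1d_fwd(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b) {
  const int N = X.n_rows, T = X.n_cols;
  const int F = W.n_cols;
  mat Ym = im2col_same(X, W.n_rows / X.n_slices) * W;
  Ym.each_row() += b.t();
  cube Y(N, T, F);
  for (int f = 0; f < F; ++f) {
    Y.slice(f) = reshape(Ym.col(f), N, T);
  }
  return Rcpp::List::create(Rcpp::Named("out") = Y);
}

// [[Rcpp::export(name = ".cpp_conv1d_bwd")]]
Rcpp::List cpp_conv1d_bwd(const arma::cube& X, const arma::mat& W,
                          const arma::cube& dY, bool need_dx) {
  const int N = X.n_rows, T = X.n_cols, Cin = X.n_slices;
  const int F = W.n_cols;
  const int k = W.n_rows / Cin;
  const int P = (k - 1) / 2;
  mat dYm(N * T, F);
  for (int f = 0; f < F; ++f) dYm.col(f) = vectorise(dY.slice(f));
  mat Xcol = im2col_same(X, k);
  mat dW = Xcol.t() * dYm;
  vec db = sum(dYm, 0).t();
  cube dX;
  if (need_dx) {
    dX.zeros(N, T, Cin);
    mat dXcol = dYm * W.t();
    for (int c = 0; c < Cin; ++c) {
      for (int d = 0; d < k; ++d) {
        const int col = d * Cin + c;
        for (int t = 0; t < T; ++t) {
          const int src = t + d - P;
          if (src < 0 || src >= T) continue;
          dX.slice(c).col(src) += dXcol.col(col).subvec(t * N, t * N + N - 1);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Fused conv -> relu -> maxpool(2) block. Returns the pooled output,
// the pre-pool relu mask and the pool routing mask (ties -> earlier
// sample). Skips pooling when T < 2.
// [[Rcpp::export(name = ".cpp_conv_block_fwd")]]
Rcpp::List cpp_conv_block_fwd(const arma::cube& X, const arma::mat& W,
                              const arma::vec& b) {
  const int N = X.n_rows, T = X.n_cols;
  const int F = W.n_cols;
  mat Ym = im2col_same(X, W.n_rows / X.n_slices) * W;
  Ym.each_row() += b.t();
  umat relu_mask = Ym > 0.0;
  Ym.elem(find(relu_mask == 0)).zeros();
  const int T2 = T / 2;
  if (T2 < 1) {
    cube Y(N, T, F);
    for (int f = 0; f < F; ++f) Y.slice(f) = reshape(Ym.col(f), N, T);
    return Rcpp::List::create(Rcpp::Named("out") = Y,
                              Rcpp::Named("relu_mask") = relu_mask,
                              Rcpp::Named("pooled") = false);
  }
  cube Yp(N, T2, F);
  umat pool_mask(N * T2, F);
  for (int f = 0; f < F; ++f) {
    const double* col = Ym.colptr(f);
    double* outp = Yp.slice_memptr(f);
    uword* mp = pool_mask.colptr(f);
    for (int t = 0; t < T2; ++t) {
      const double* a = col + (2 * t) * N;
      const double* bb = col + (2 * t + 1) * N;
      for (int n = 0; n < N; ++n) {
        const bool first = a[n] >= bb[n];
        outp[t * N + n] = first ? a[n] : bb[n];
        mp[t * N + n] = first ? 1 : 0;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = Yp,
                            Rcpp::Named("relu_mask") = relu_mask,
                            Rcpp::Named("pool_mask") = pool_mask,
                            Rcpp::Named("pooled") = true);
}

// [[Rcpp::export(name = ".cpp_conv_block_bwd")]]
Rcpp::List cpp_conv_block_bwd(const arma::cube& X, const arma::mat& W,
                              const arma::umat& relu_mask,
                              const arma::umat& pool_mask, bool pooled,
                              const arma::cube& dY, bool need_dx) {
  const int N = X.n_rows, T = X.n_cols, Cin = X.n_slices;
  const int F = W.n_cols;
  const int k = W.n_rows / Cin;
  const int P = (k - 1) / 2;
  // un-pool (route gradients along the recorded argmax) and un-relu
  mat dYm(N * T, F, fill::zeros);
  if (pooled) {
    const int T2 = dY.n_cols;
    for (int f = 0; f < F; ++f) {
      const double* dyp = dY.slice_memptr(f);
      const uword* mp = pool_mask.colptr(f);
      double* dst = dYm.colptr(f);
      for (int t = 0; t < T2; ++t) {
        for (int n = 0; n < N; ++n) {
          const double g = dyp[t * N + n];
          if (mp[t * N + n]) dst[(2 * t) * N + n] = g;
          else dst[(2 * t + 1) * N + n] = g;
        }
      }
    }
  } else {
    for (int f = 0; f < F; ++f) dYm.col(f) = vectorise(dY.slice(f));
  }
  dYm.elem(find(relu_mask == 0)).zeros();
  mat Xcol = im2col_same(X, k);
  mat dW = Xcol.t() * dYm;
  vec db = sum(dYm, 0).t();
  cube dX;
  if (need_dx) {
    dX.zeros(N, T, Cin);
    mat dXcol = dYm * W.t();
    for (int c = 0; c < Cin; ++c) {
      for (int d = 0; d < k; ++d) {
        const int col = d * Cin + c;
        for (int t = 0; t < T; ++t) {
          const int src = t + d - P;
          if (src < 0 || src >= T) continue;
          dX.slice(c).col(src) += dXcol.col(col).subvec(t * N, t * N + N - 1);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".cpp_pool2_fwd")]]
Rcpp::List cpp_pool2_fwd(const arma::cube& X) {
  const int N = X.n_rows, T = X.n_cols, C = X.n_slices;
  const int T2 = T / 2;
  cube out(N, T2, C), mask(N, T2, C);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < T2; ++t) {
      const vec a = X.slice(c).col(2 * t);
      const vec b = X.slice(c).col(2 * t + 1);
      const uvec m = (a >= b);            // ties -> earlier sample
      mask.slice(c).col(t) = conv_to<vec>::from(m);
      out.slice(c).col(t) = a % conv_to<vec>::from(m) +
                            b % (1.0 - conv_to<vec>::from(m));
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("mask") = mask);
}

// [[Rcpp::export(name = ".cpp_pool2_bwd")]]
arma::cube cpp_pool2_bwd(const arma::cube& mask, int Tin,
                         const arma::cube& dY) {
  const int N = dY.n_rows, T2 = dY.n_cols, C = dY.n_slices;
  cube dX(N, Tin, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < T2; ++t) {
      dX.slice(c).col(2 * t) = dY.slice(c).col(t) % mask.slice(c).col(t);
      dX.slice(c).col(2 * t + 1) =
        dY.slice(c).col(t) % (1.0 - mask.slice(c).col(t));
    }
  }
  return dX;
}

static mat cube_to_seqmat(const cube& X) {
  mat Xm(X.n_rows * X.n_cols, X.n_slices);
  for (unsigned d = 0; d < X.n_slices; ++d) Xm.col(d) = vectorise(X.slice(d));
  return Xm;
}

// LSTM over the full sequence; returns the last hidden state plus the
// gate/cell caches needed for backpropagation. Gate order: i, f, g, o.
// [[Rcpp::export(name = ".cpp_lstm_fwd")]]
Rcpp::List cpp_lstm_fwd(const arma::cube& X, const arma::mat& Wx,
                        const arma::mat& Wh, const arma::vec& b) {
  const int N = X.n_rows, T = X.n_cols;
  const int H = Wh.n_rows;
  mat pre = cube_to_seqmat(X) * Wx;
  pre.each_row() += b.t();
  mat h(N, H, fill::zeros), cs(N, H, fill::zeros);
  cube G(N, 4 * H, T), CC(N, H, T), TC(N, H, T);
  for (int t = 0; t < T; ++t) {
    mat Z = pre.rows(t * N, t * N + N - 1) + h * Wh;
    mat i = 1.0 / (1.0 + exp(-Z.cols(0, H - 1)));
    mat f = 1.0 / (1.0 + exp(-Z.cols(H, 2 * H - 1)));
    mat g = tanh(Z.cols(2 * H, 3 * H - 1));
    mat o = 1.0 / (1.0 + exp(-Z.cols(3 * H, 4 * H - 1)));
    cs = f % cs + i % g;
    mat tc = tanh(cs);
    h = o % tc;
    G.slice(t) = join_rows(join_rows(i, f), join_rows(g, o));
    CC.slice(t) = cs;
    TC.slice(t) = tc;
  }
  return Rcpp::List::create(Rcpp::Named("h") = h, Rcpp::Named("G") = G,
                            Rcpp::Named("C") = CC, Rcpp::Named("TC") = TC);
}

// [[Rcpp::export(name = ".cpp_lstm_bwd")]]
Rcpp::List cpp_lstm_bwd(const arma::cube& X, const arma::mat& Wx,
                        const arma::mat& Wh, const arma::cube& G,
                        const arma::cube& CC, const arma::cube& TC,
                        const arma::mat& dh_last) {
  const int N = X.n_rows, T = X.n_cols, D = X.n_slices;
  const int H = Wh.n_rows;
  mat Xm = cube_to_seqmat(X);
  mat dWx(D, 4 * H, fill::zeros), dWh(H, 4 * H, fill::zeros);
  vec db(4 * H, fill::zeros);
  mat dXm(N * T, D);
  mat dh = dh_last, dc(N, H, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const mat i = G.slice(t).cols(0, H - 1);
    const mat f = G.slice(t).cols(H, 2 * H - 1);
    const mat g = G.slice(t).cols(2 * H, 3 * H - 1);
    const mat o = G.slice(t).cols(3 * H, 4 * H - 1);
    const mat tc = TC.slice(t);
    const mat cprev = (t > 0) ? CC.slice(t - 1) : mat(N, H, fill::zeros);
    mat dO = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    mat dZ = join_rows(
        join_rows((dc % g) % i % (1.0 - i), (dc % cprev) % f % (1.0 - f)),
        join_rows((dc % i) % (1.0 - g % g), dO % o % (1.0 - o)));
    const mat xt = Xm.rows(t * N, t * N + N - 1);
    const mat hprev = (t > 0)
      ? mat(G.slice(t - 1).cols(3 * H, 4 * H - 1) % TC.slice(t - 1))
      : mat(N, H, fill::zeros);
    dWx += xt.t() * dZ;
    dWh += hprev.t() * dZ;
    db += sum(dZ, 0).t();
    dXm.rows(t * N, t * N + N - 1) = dZ * Wx.t();
    dh = dZ * Wh.t();
    dc = dc % f;
  }
  cube dX(N, T, D);
  for (int d = 0; d < D; ++d) dX.slice(d) = reshape(dXm.col(d), N, T);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("db") = db);
}
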