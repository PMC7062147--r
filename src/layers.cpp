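// Minimal neural-network kernels for the LRCN: 1-D convolution (with fused
// ReLU), temporal max-pooling and LSTM, forward and backward. Batched
// activations are stored as cubes of dimension (batch, time, channel),
// matching R arrays c(B, T, C) in memory, so reshaping between R and
// Armadillo is copy-free in layout. GEMMs run in single precision, the
// standard training dtype for networks of this kind; parameters and the
// optimizer state stay in double on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Workspace buffers are reused across calls (R is single-threaded) to avoid
// repeated large allocations inside training loops.
static fcube ws_pad, ws_dpad;
static fmat ws_cols, ws_out, ws_dout, ws_dcols;

// im2col for a (B, Tp, Cin) padded cube in float, into `out`:
// (B*Tout) x (K*Cin), column j = k + K*c holds X[b, t+k, c] for position t.
static void im2col_time(const fcube& Xp, int K, int Tout, fmat& out) {
  const int B = Xp.n_rows, Cin = Xp.n_slices;
  out.set_size(B * Tout, K * Cin);
  for (int c = 0; c < Cin; ++c) {
    for (int k = 0; k < K; ++k) {
      const float* src = Xp.slice(c).colptr(k);
      std::memcpy(out.colptr(k + K * c), src, sizeof(float) * B * Tout);
    }
  }
}

static void pad_time(const cube& X, int pad_l, int pad_r, fcube& Xp) {
  Xp.set_size(X.n_rows, X.n_cols + pad_l + pad_r, X.n_slices);
  if (pad_l > 0 || pad_r > 0) Xp.zeros();
  const double* src = X.memptr();
  for (uword c = 0; c < X.n_slices; ++c) {
    float* dst = Xp.slice(c).colptr(pad_l);
    const double* s = src + c * X.n_rows * X.n_cols;
    for (uword i = 0; i < X.n_rows * X.n_cols; ++i) dst[i] = (float)s[i];
  }
}

// X: (B, T, Cin); W: (K, Cin, Cout) flattened column-major so that row index
// k + K*c of the (K*Cin) x Cout weight matrix matches im2col. padding:
// "same" (K odd, stride 1) or "valid". Optionally applies ReLU in place.
// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::cube& W,
                      const arma::vec& b, const std::string& padding,
                      bool relu = false) {
  const int B = X.n_rows, T = X.n_cols;
  const int K = W.n_rows, Cin = W.n_cols, Cout = W.n_slices;
  if ((int)X.n_slices != Cin) Rcpp::stop("conv1d: channel mismatch");
  const int pad = (padding == "same") ? (K - 1) / 2 : 0;
  const int Tout = (padding == "same") ? T : T - K + 1;
  if (Tout < 1) Rcpp::stop("conv1d: input shorter than kernel");
  pad_time(X, pad, pad, ws_pad);
  im2col_time(ws_pad, K, Tout, ws_cols);
  fmat Wm = conv_to<fmat>::from(
      mat(const_cast<double*>(W.memptr()), K * Cin, Cout, false, true));
  ws_out = ws_cols * Wm;
  frowvec bf = conv_to<frowvec>::from(b.t());
  ws_out.each_row() += bf;
  if (relu) ws_out.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  cube Y(B, Tout, Cout);
  std::copy(ws_out.begin(), ws_out.end(), Y.begin());
  return Y;
}

// Backward pass. When Ypost is non-empty it is the post-ReLU forward output
// and dY is masked by Ypost > 0 first. dX is skipped when need_dx is false
// (input-layer convolutions).
// [[Rcpp::export(name = ".conv1d_bwd")]]
Rcpp::List conv1d_bwd(const arma::cube& X, const arma::cube& W,
                      const arma::cube& dY, const arma::cube& Ypost,
                      const std::string& padding, bool need_dx = true) {
  const int B = X.n_rows, T = X.n_cols;
  const int K = W.n_rows, Cin = W.n_cols, Cout = W.n_slices;
  const int pad = (padding == "same") ? (K - 1) / 2 : 0;
  const int Tout = dY.n_cols;
  pad_time(X, pad, pad, ws_pad);
  im2col_time(ws_pad, K, Tout, ws_cols);
  ws_dout.set_size(B * Tout, Cout);
  std::copy(dY.begin(), dY.end(), ws_dout.begin());
  if (Ypost.n_elem > 0) {
    const double* yp = Ypost.memptr();
    float* dp = ws_dout.memptr();
    for (uword i = 0; i < ws_dout.n_elem; ++i) {
      if (yp[i] <= 0.0) dp[i] = 0.0f;
    }
  }
  fmat dWm = ws_cols.t() * ws_dout;  // (K*Cin) x Cout
  vec db = conv_to<vec>::from(sum(ws_dout, 0).t());
  cube dW(K, Cin, Cout);
  std::copy(dWm.begin(), dWm.end(), dW.begin());
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
      Rcpp::Named("dX") = R_NilValue);
  if (need_dx) {
    fmat Wm = conv_to<fmat>::from(
        mat(const_cast<double*>(W.memptr()), K * Cin, Cout, false, true));
    ws_dcols = ws_dout * Wm.t();  // col2im accumulate
    ws_dpad.set_size(B, T + 2 * pad, Cin);
    ws_dpad.zeros();
    for (int c = 0; c < Cin; ++c) {
      for (int k = 0; k < K; ++k) {
        fmat blk(ws_dcols.colptr(k + K * c), B, Tout, false, true);
        ws_dpad.slice(c).cols(k, k + Tout - 1) += blk;
      }
    }
    cube dX(B, T, Cin);
    for (int c = 0; c < Cin; ++c) {
      dX.slice(c) = conv_to<mat>::from(ws_dpad.slice(c).cols(pad, pad + T - 1));
    }
    out["dX"] = dX;
  }
  return out;
}

// Temporal max-pooling, pool size p, T divisible by p. Ties go to the
// earliest position. Returns pooled cube and 1-based linear argmax indices.
// [[Rcpp::export(name = ".maxpool_fwd")]]
Rcpp::List maxpool_fwd(const arma::cube& X, int p) {
  const int B = X.n_rows, T = X.n_cols, C = X.n_slices;
  if (T % p != 0) Rcpp::stop("maxpool: length not divisible by pool size");
  const int Tout = T / p;
  cube Y(B, Tout, C);
  Rcpp::IntegerVector amax(B * Tout * C);
  const double* x = X.memptr();
  double* y = Y.memptr();
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < Tout; ++t) {
      for (int b = 0; b < B; ++b) {
        int base = b + B * (t * p) + B * T * c;
        double best = x[base];
        int besti = base;
        for (int j = 1; j < p; ++j) {
          int idx = base + B * j;
          if (x[idx] > best) { best = x[idx]; besti = idx; }
        }
        int o = b + B * t + B * Tout * c;
        y[o] = best;
        amax[o] = besti + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
arma::cube maxpool_bwd(const arma::cube& dY, const Rcpp::IntegerVector& amax,
                       int B, int T, int C) {
  cube dX(B, T, C, fill::zeros);
  double* dx = dX.memptr();
  const double* dy = dY.memptr();
  for (int i = 0; i < (int)amax.size(); ++i) dx[amax[i] - 1] += dy[i];
  return dX;
}

static inline fmat sigm(const fmat& z) { return 1.0f / (1.0f + exp(-z)); }

static fcube to_f(const cube& X) {
  fcube out(X.n_rows, X.n_cols, X.n_slices);
  std::copy(X.begin(), X.end(), out.begin());
  return out;
}

static fmat slice_t(const fcube& A, int t) {
  const int B = A.n_rows, n = A.n_slices;
  fmat out(B, n);
  for (int j = 0; j < n; ++j) out.col(j) = A.slice(j).col(t);
  return out;
}

static void set_slice_t(fcube& A, int t, const fmat& v) {
  for (uword j = 0; j < A.n_slices; ++j) A.slice(j).col(t) = v.col(j);
}

// LSTM forward over a (B, T, D) cube. Wx: D x 4H, Wh: H x 4H, b: 4H.
// Gate column order: input, forget, output, candidate. Initial state zero.
// Returns hidden states h (B, T, Hd), cell states c, activated gates g.
// [[Rcpp::export(name = ".lstm_fwd")]]
Rcpp::List lstm_fwd(const arma::cube& X, const arma::mat& Wx,
                    const arma::mat& Wh, const arma::vec& b) {
  const int B = X.n_rows, T = X.n_cols, D = X.n_slices;
  const int Hd = Wh.n_rows;
  if ((int)Wx.n_rows != D || (int)Wx.n_cols != 4 * Hd)
    Rcpp::stop("lstm: weight shape mismatch");
  fcube Xf = to_f(X);
  fmat Wxf = conv_to<fmat>::from(Wx), Whf = conv_to<fmat>::from(Wh);
  frowvec bf = conv_to<frowvec>::from(b.t());
  fcube Hs(B, T, Hd), Cs(B, T, Hd), Gs(B, T, 4 * Hd);
  fmat h(B, Hd, fill::zeros), c(B, Hd, fill::zeros);
  for (int t = 0; t < T; ++t) {
    fmat Z = slice_t(Xf, t) * Wxf + h * Whf;
    Z.each_row() += bf;
    fmat gi = sigm(Z.cols(0, Hd - 1));
    fmat gf = sigm(Z.cols(Hd, 2 * Hd - 1));
    fmat go = sigm(Z.cols(2 * Hd, 3 * Hd - 1));
    fmat gg = tanh(Z.cols(3 * Hd, 4 * Hd - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    set_slice_t(Hs, t, h);
    set_slice_t(Cs, t, c);
    fmat G = join_rows(join_rows(gi, gf), join_rows(go, gg));
    set_slice_t(Gs, t, G);
  }
  cube Ho(B, T, Hd), Co(B, T, Hd), Go(B, T, 4 * Hd);
  std::copy(Hs.begin(), Hs.end(), Ho.begin());
  std::copy(Cs.begin(), Cs.end(), Co.begin());
  std::copy(Gs.begin(), Gs.end(), Go.begin());
  return Rcpp::List::create(Rcpp::Named("h") = Ho, Rcpp::Named("c") = Co,
                            Rcpp::Named("g") = Go);
}

// Backprop through time. dH carries the loss gradient w.r.t. every hidden
// output (zero rows except the last timestep when only h_T is consumed).
// [[Rcpp::export(name = ".lstm_bwd")]]
Rcpp::List lstm_bwd(const arma::cube& X, const arma::mat& Wx,
                    const arma::mat& Wh, const arma::vec& b,
                    const arma::cube& Hs, const arma::cube& Cs,
                    const arma::cube& Gs, const arma::cube& dH) {
  const int B = X.n_rows, T = X.n_cols, D = X.n_slices;
  const int Hd = Wh.n_rows;
  (void)b;
  fcube Xf = to_f(X), Hf = to_f(Hs), Cf = to_f(Cs), Gf = to_f(Gs),
        dHf = to_f(dH);
  fmat Wxf = conv_to<fmat>::from(Wx), Whf = conv_to<fmat>::from(Wh);
  fcube dX(B, T, D, fill::zeros);
  fmat dWx(D, 4 * Hd, fill::zeros), dWh(Hd, 4 * Hd, fill::zeros);
  frowvec db(4 * Hd, fill::zeros);
  fmat dh_next(B, Hd, fill::zeros), dc(B, Hd, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    fmat dh = slice_t(dHf, t) + dh_next;
    fmat gall = slice_t(Gf, t);
    fmat gi = gall.cols(0, Hd - 1), gf = gall.cols(Hd, 2 * Hd - 1),
         go = gall.cols(2 * Hd, 3 * Hd - 1), gg = gall.cols(3 * Hd, 4 * Hd - 1);
    fmat tc = tanh(slice_t(Cf, t));
    fmat dgo = dh % tc;
    dc += dh % go % (1.0f - tc % tc);
    fmat cprev = (t > 0) ? slice_t(Cf, t - 1) : fmat(B, Hd, fill::zeros);
    fmat dZ(B, 4 * Hd);
    dZ.cols(0, Hd - 1) = (dc % gg) % gi % (1.0f - gi);
    dZ.cols(Hd, 2 * Hd - 1) = (dc % cprev) % gf % (1.0f - gf);
    dZ.cols(2 * Hd, 3 * Hd - 1) = dgo % go % (1.0f - go);
    dZ.cols(3 * Hd, 4 * Hd - 1) = (dc % gi) % (1.0f - gg % gg);
    fmat hprev = (t > 0) ? slice_t(Hf, t - 1) : fmat(B, Hd, fill::zeros);
    dWx += slice_t(Xf, t).t() * dZ;
    dWh += hprev.t() * dZ;
    db += sum(dZ, 0);
    set_slice_t(dX, t, dZ * Wxf.t());
    dh_next = dZ * Whf.t();
    dc = dc % gf;
  }
  cube dXo(B, T, D);
  std::copy(dX.begin(), dX.end(), dXo.begin());
  return Rcpp::List::create(
      Rcpp::Named("dX") = dXo,
      Rcpp::Named("dWx") = conv_to<mat>::from(dWx),
      Rcpp::Named("dWh") = conv_to<mat>::from(dWh),
      Rcpp::Named("db") = conv_to<vec>::from(db.t()));
}
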