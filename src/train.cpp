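// Fused minibatch training loop for the angle stage (feature extractor +
// LSTM angle head, Adam). Keeping the whole step in C++ with buffers
// allocated once per call avoids the allocator/GC churn a per-batch R loop
// would cause. Compute is single precision; master weights and Adam moments
// stay double. Dropout uniforms come from R's RNG stream (seeded by the
// caller), epoch shuffles are precomputed in R, so runs are reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Par {
  std::string name;
  vec master;      // flattened double master weights
  vec m, v;        // Adam moments
  fvec w;          // float working copy
  fvec g;          // float gradient
};

void adam_update(std::vector<Par>& ps, int t, double lr, double b1, double b2,
                 double eps) {
  const double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
  for (auto& p : ps) {
    for (uword i = 0; i < p.master.n_elem; ++i) {
      const double g = (double)p.g[i];
      p.m[i] = b1 * p.m[i] + (1 - b1) * g;
      p.v[i] = b2 * p.v[i] + (1 - b2) * g * g;
      p.master[i] -= lr * (p.m[i] / bc1) / (std::sqrt(p.v[i] / bc2) + eps);
    }
    for (uword i = 0; i < p.master.n_elem; ++i) p.w[i] = (float)p.master[i];
  }
}

inline fmat pview(Par& p, int r, int c) { return fmat(p.w.memptr(), r, c, false, true); }

// temporal max-pool on a (B*T) x C matrix (row index b + B*t), pool size p;
// writes (B*Tout) x C output and the source row of each maximum
void pool_fwd(const fmat& A, int B, int T, int p, fmat& Y, Mat<int>& arg) {
  const int Tout = T / p, C = A.n_cols;
  Y.set_size(B * Tout, C);
  arg.set_size(B * Tout, C);
  for (int c = 0; c < C; ++c) {
    const float* a = A.colptr(c);
    float* y = Y.colptr(c);
    int* ar = arg.colptr(c);
    for (int t = 0; t < Tout; ++t) {
      for (int b = 0; b < B; ++b) {
        int r = b + B * t * p;
        float best = a[r];
        int bi = r;
        for (int j = 1; j < p; ++j) {
          int rr = r + B * j;
          if (a[rr] > best) { best = a[rr]; bi = rr; }
        }
        y[b + B * t] = best;
        ar[b + B * t] = bi;
      }
    }
  }
}

void pool_bwd(const fmat& dY, const Mat<int>& arg, int rows_in, fmat& dA) {
  dA.zeros(rows_in, dY.n_cols);
  for (uword c = 0; c < dY.n_cols; ++c) {
    float* d = dA.colptr(c);
    const float* dy = dY.colptr(c);
    const int* ar = arg.colptr(c);
    for (uword i = 0; i < dY.n_rows; ++i) d[ar[i]] += dy[i];
  }
}

void draw_mask(fmat& M, int r, int c, double rate) {
  M.set_size(r, c);
  const float keep = 1.0f / (float)(1.0 - rate);
  for (uword i = 0; i < M.n_elem; ++i) {
    M[i] = (unif_rand() >= rate) ? keep : 0.0f;
  }
}

struct LstmCache {
  fmat H, C, G;  // B x (Hd*T), B x (Hd*T), B x (4*Hd*T)
};

// forward one LSTM layer; xt(t) must return a B x D float matrix view
template <typename XT>
void lstm_fwd_steps(int B, int T, int Hd, const fmat& Wx, const fmat& Wh,
                    const frowvec& b, XT xt, LstmCache& cc, fmat& Z) {
  cc.H.set_size(B, Hd * T);
  cc.C.set_size(B, Hd * T);
  cc.G.set_size(B, 4 * Hd * T);
  fmat h(B, Hd, fill::zeros), c(B, Hd, fill::zeros);
  for (int t = 0; t < T; ++t) {
    Z = xt(t) * Wx;
    if (t > 0) Z += cc.H.cols((t - 1) * Hd, t * Hd - 1) * Wh;
    Z.each_row() += b;
    fmat gi = 1.0f / (1.0f + exp(-Z.cols(0, Hd - 1)));
    fmat gf = 1.0f / (1.0f + exp(-Z.cols(Hd, 2 * Hd - 1)));
    fmat go = 1.0f / (1.0f + exp(-Z.cols(2 * Hd, 3 * Hd - 1)));
    fmat gg = tanh(Z.cols(3 * Hd, 4 * Hd - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    cc.H.cols(t * Hd, (t + 1) * Hd - 1) = h;
    cc.C.cols(t * Hd, (t + 1) * Hd - 1) = c;
    cc.G.cols(4 * t * Hd, 4 * t * Hd + Hd - 1) = gi;
    cc.G.cols(4 * t * Hd + Hd, 4 * t * Hd + 2 * Hd - 1) = gf;
    cc.G.cols(4 * t * Hd + 2 * Hd, 4 * t * Hd + 3 * Hd - 1) = go;
    cc.G.cols(4 * t * Hd + 3 * Hd, 4 * t * Hd + 4 * Hd - 1) = gg;
  }
}

// backward one LSTM layer. dH(t) is the upstream gradient on h_t; dxt(t)
// receives the gradient w.r.t. the layer input at t.
template <typename XT, typename DH, typename DX>
void lstm_bwd_steps(int B, int T, int Hd, const fmat& Wx, const fmat& Wh,
                    const LstmCache& cc, XT xt, DH dH, DX dxt,
                    fmat& dWx, fmat& dWh, frowvec& db) {
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(4 * Hd);
  fmat dh_next(B, Hd, fill::zeros), dc(B, Hd, fill::zeros), dZ(B, 4 * Hd);
  for (int t = T - 1; t >= 0; --t) {
    fmat dh = dH(t) + dh_next;
    const fmat gi = cc.G.cols(4 * t * Hd, 4 * t * Hd + Hd - 1);
    const fmat gf = cc.G.cols(4 * t * Hd + Hd, 4 * t * Hd + 2 * Hd - 1);
    const fmat go = cc.G.cols(4 * t * Hd + 2 * Hd, 4 * t * Hd + 3 * Hd - 1);
    const fmat gg = cc.G.cols(4 * t * Hd + 3 * Hd, 4 * t * Hd + 4 * Hd - 1);
    fmat tc = tanh(cc.C.cols(t * Hd, (t + 1) * Hd - 1));
    dc += dh % go % (1.0f - tc % tc);
    fmat cprev = (t > 0) ? fmat(cc.C.cols((t - 1) * Hd, t * Hd - 1))
                         : fmat(B, Hd, fill::zeros);
    dZ.cols(0, Hd - 1) = (dc % gg) % gi % (1.0f - gi);
    dZ.cols(Hd, 2 * Hd - 1) = (dc % cprev) % gf % (1.0f - gf);
    dZ.cols(2 * Hd, 3 * Hd - 1) = (dh % tc) % go % (1.0f - go);
    dZ.cols(3 * Hd, 4 * Hd - 1) = (dc % gi) % (1.0f - gg % gg);
    dWx += xt(t).t() * dZ;
    if (t > 0) dWh += cc.H.cols((t - 1) * Hd, t * Hd - 1).t() * dZ;
    db += sum(dZ, 0);
    dxt(t, dZ * Wx.t());
    dh_next = dZ * Wh.t();
    dc = dc % gf;
  }
}

}  // namespace

// params: named list of the fe.* and ah.* weights (R layouts as in build_lrcn)
// X: n x W x C cube of normalized windows; Y: n x W scaled angle targets;
// perms: n x epochs matrix of 1-based shuffle indices.
// [[Rcpp::export(name = ".lrcn_train_angle")]]
Rcpp::List lrcn_train_angle(Rcpp::List params, const arma::cube& X,
                            const arma::mat& Y, const arma::imat& perms,
                            int batch_size, double lr, double dropout,
                            const std::string& padding, int pool_sz, int K,
                            int Fm, int H1, int H2, const std::string& loss_kind,
                            double beta1 = 0.9, double beta2 = 0.999,
                            double adam_eps = 1e-8) {
  Rcpp::RNGScope rng;  // dropout uniforms from R's seeded stream
  const int n = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int epochs = perms.n_cols;
  const bool same = (padding == "same");
  const int pad = same ? (K - 1) / 2 : 0;
  const int Tc1 = same ? W : W - K + 1;       // stage-1 conv output length
  const int t1 = Tc1 / pool_sz;
  const int Tc2 = same ? t1 : t1 - K + 1;     // stage-2 conv output length
  const int t2 = Tc2 / pool_sz;
  const int CF = C * Fm;
  const bool mse = (loss_kind == "mse");

  // parameter order: br1.W..brC.W, br1.b.., conv2.W, conv2.b,
  // lstm1.{Wx,Wh,b}, lstm2.{Wx,Wh,b}, dense.{W,b}
  std::vector<std::string> names;
  for (int c = 1; c <= C; ++c) names.push_back("fe.br" + std::to_string(c) + ".W");
  for (int c = 1; c <= C; ++c) names.push_back("fe.br" + std::to_string(c) + ".b");
  const char* rest[] = {"fe.conv2.W", "fe.conv2.b", "ah.lstm1.Wx", "ah.lstm1.Wh",
                        "ah.lstm1.b", "ah.lstm2.Wx", "ah.lstm2.Wh", "ah.lstm2.b",
                        "ah.dense.W", "ah.dense.b"};
  for (auto s : rest) names.push_back(s);
  std::vector<Par> ps(names.size());
  for (size_t i = 0; i < names.size(); ++i) {
    Rcpp::NumericVector rv = params[names[i]];
    ps[i].name = names[i];
    ps[i].master = vec(rv.begin(), rv.size());
    ps[i].m.zeros(rv.size());
    ps[i].v.zeros(rv.size());
    ps[i].w = conv_to<fvec>::from(ps[i].master);
    ps[i].g.set_size(rv.size());
  }
  auto P = [&](const std::string& nm) -> Par& {
    for (auto& p : ps) if (p.name == nm) return p;
    Rcpp::stop("missing parameter " + nm);
    return ps[0];
  };

  vec losses(epochs, fill::zeros);
  int adam_t = 0;

  // buffers (sized for the largest batch; resized automatically on the
  // smaller final batch)
  fcube Xp;             // B x (W + 2*pad) x C padded input
  fmat cols1, act1, pool1, mask1, concat, cols2p;
  fmat act2, feat, mask2, dfeat, dact2, dcols2, dconcat, dact1, dpool1;
  fcube dpad2;
  Mat<int> arg1, arg2;
  LstmCache L1, L2;
  fmat Zws, pred, dPred, hT, dhT, dH1seq;
  fmat dWx1, dWh1, dWx2, dWh2;
  frowvec dbl1, dbl2;
  fcube pooled_pad;

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    int nb = 0;
    for (int at = 0; at < n; at += batch_size) {
      const int B = std::min(batch_size, n - at);
      // ---- gather batch into padded float input
      Xp.set_size(B, W + 2 * pad, C);
      if (pad > 0) Xp.zeros();
      fmat Yb(B, W);
      for (int b = 0; b < B; ++b) {
        const int src = perms(at + b, ep) - 1;
        for (int c = 0; c < C; ++c) {
          for (int t = 0; t < W; ++t) {
            Xp(b, t + pad, c) = (float)X(src, t, c);
          }
        }
        for (int t = 0; t < W; ++t) Yb(b, t) = (float)Y(src, t);
      }
      // ---- stage 1: C parallel convs, fused ReLU
      cols1.set_size(B * Tc1, K * C);
      for (int c = 0; c < C; ++c) {
        for (int k = 0; k < K; ++k) {
          std::memcpy(cols1.colptr(k + K * c), Xp.slice(c).colptr(k),
                      sizeof(float) * B * Tc1);
        }
      }
      act1.set_size(B * Tc1, CF);
      for (int c = 0; c < C; ++c) {
        fmat Wc = pview(P("fe.br" + std::to_string(c + 1) + ".W"), K, Fm);
        fmat out = cols1.cols(K * c, K * c + K - 1) * Wc;
        const fvec& bb = P("fe.br" + std::to_string(c + 1) + ".b").w;
        out.each_row() += bb.t();
        out.transform([](float v) { return v > 0.0f ? v : 0.0f; });
        act1.cols(c * Fm, (c + 1) * Fm - 1) = out;
      }
      pool_fwd(act1, B, Tc1, pool_sz, pool1, arg1);
      if (dropout > 0) {
        draw_mask(mask1, B * t1, CF, dropout);
        pool1 %= mask1;
      }
      // ---- stage 2 conv over the concatenated maps
      pooled_pad.set_size(B, t1 + 2 * pad, CF);
      if (pad > 0) pooled_pad.zeros();
      for (int c = 0; c < CF; ++c) {
        std::memcpy(pooled_pad.slice(c).colptr(pad), pool1.colptr(c),
                    sizeof(float) * B * t1);
      }
      cols2p.set_size(B * Tc2, K * CF);
      for (int c = 0; c < CF; ++c) {
        for (int k = 0; k < K; ++k) {
          std::memcpy(cols2p.colptr(k + K * c), pooled_pad.slice(c).colptr(k),
                      sizeof(float) * B * Tc2);
        }
      }
      act2 = cols2p * pview(P("fe.conv2.W"), K * CF, Fm);
      act2.each_row() += P("fe.conv2.b").w.t();
      act2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      pool_fwd(act2, B, Tc2, pool_sz, feat, arg2);
      if (dropout > 0) {
        draw_mask(mask2, B * t2, Fm, dropout);
        feat %= mask2;
      }
      // ---- LSTM stack + dense
      fmat Wx1 = pview(P("ah.lstm1.Wx"), Fm, 4 * H1);
      fmat Wh1 = pview(P("ah.lstm1.Wh"), H1, 4 * H1);
      frowvec b1f = P("ah.lstm1.b").w.t();
      lstm_fwd_steps(B, t2, H1, Wx1, Wh1, b1f,
                     [&](int t) { return feat.rows(t * B, t * B + B - 1); },
                     L1, Zws);
      fmat Wx2 = pview(P("ah.lstm2.Wx"), H1, 4 * H2);
      fmat Wh2 = pview(P("ah.lstm2.Wh"), H2, 4 * H2);
      frowvec b2f = P("ah.lstm2.b").w.t();
      lstm_fwd_steps(B, t2, H2, Wx2, Wh2, b2f,
                     [&](int t) { return L1.H.cols(t * H1, (t + 1) * H1 - 1); },
                     L2, Zws);
      hT = L2.H.cols((t2 - 1) * H2, t2 * H2 - 1);
      pred = hT * pview(P("ah.dense.W"), H2, W);
      pred.each_row() += P("ah.dense.b").w.t();
      // ---- loss
      fmat e = pred - Yb;
      double bl;
      if (mse) {
        bl = accu(conv_to<mat>::from(e % e)) / e.n_elem;
        dPred = e * (float)(2.0 / e.n_elem);
      } else {
        bl = accu(conv_to<mat>::from(abs(e))) / e.n_elem;
        dPred = sign(e) * (float)(1.0 / e.n_elem);
      }
      if (!std::isfinite(bl)) {
        return Rcpp::List::create(Rcpp::Named("error") = true,
                                  Rcpp::Named("epoch") = ep + 1,
                                  Rcpp::Named("batch") = at + 1);
      }
      ep_loss += bl;
      ++nb;
      // ---- backward: dense
      fmat dWd = hT.t() * dPred;
      frowvec dbd = sum(dPred, 0);
      dhT = dPred * pview(P("ah.dense.W"), H2, W).t();
      // lstm2 (upstream gradient only at the last step)
      dH1seq.zeros(B, H1 * t2);
      lstm_bwd_steps(B, t2, H2, Wx2, Wh2, L2,
                     [&](int t) { return L1.H.cols(t * H1, (t + 1) * H1 - 1); },
                     [&](int t) -> fmat {
                       return (t == t2 - 1) ? dhT : fmat(dhT.n_rows, H2, fill::zeros);
                     },
                     [&](int t, const fmat& dx) {
                       dH1seq.cols(t * H1, (t + 1) * H1 - 1) = dx;
                     },
                     dWx2, dWh2, dbl2);
      // lstm1 (upstream gradient on every step)
      dfeat.set_size(B * t2, Fm);
      lstm_bwd_steps(B, t2, H1, Wx1, Wh1, L1,
                     [&](int t) { return feat.rows(t * B, t * B + B - 1); },
                     [&](int t) { return dH1seq.cols(t * H1, (t + 1) * H1 - 1); },
                     [&](int t, const fmat& dx) {
                       dfeat.rows(t * B, t * B + B - 1) = dx;
                     },
                     dWx1, dWh1, dbl1);
      // ---- backward: stage 2
      if (dropout > 0) dfeat %= mask2;
      pool_bwd(dfeat, arg2, B * Tc2, dact2);
      for (uword i = 0; i < dact2.n_elem; ++i) {
        if (act2[i] <= 0.0f) dact2[i] = 0.0f;
      }
      fmat dW2 = cols2p.t() * dact2;
      frowvec db2 = sum(dact2, 0);
      dcols2 = dact2 * pview(P("fe.conv2.W"), K * CF, Fm).t();
      dpad2.zeros(B, t1 + 2 * pad, CF);
      for (int c = 0; c < CF; ++c) {
        for (int k = 0; k < K; ++k) {
          fmat blk(dcols2.colptr(k + K * c), B, Tc2, false, true);
          dpad2.slice(c).cols(k, k + Tc2 - 1) += blk;
        }
      }
      dconcat.set_size(B * t1, CF);
      for (int c = 0; c < CF; ++c) {
        std::memcpy(dconcat.colptr(c), dpad2.slice(c).colptr(pad),
                    sizeof(float) * B * t1);
      }
      // ---- backward: stage 1 branches
      if (dropout > 0) dconcat %= mask1;
      pool_bwd(dconcat, arg1, B * Tc1, dact1);
      for (uword i = 0; i < dact1.n_elem; ++i) {
        if (act1[i] <= 0.0f) dact1[i] = 0.0f;
      }
      for (int c = 0; c < C; ++c) {
        fmat sub = dact1.cols(c * Fm, (c + 1) * Fm - 1);
        fmat dWc = cols1.cols(K * c, K * c + K - 1).t() * sub;
        Par& pw = P("fe.br" + std::to_string(c + 1) + ".W");
        std::copy(dWc.begin(), dWc.end(), pw.g.begin());
        frowvec dbc = sum(sub, 0);
        Par& pb = P("fe.br" + std::to_string(c + 1) + ".b");
        std::copy(dbc.begin(), dbc.end(), pb.g.begin());
      }
      std::copy(dW2.begin(), dW2.end(), P("fe.conv2.W").g.begin());
      std::copy(db2.begin(), db2.end(), P("fe.conv2.b").g.begin());
      std::copy(dWx1.begin(), dWx1.end(), P("ah.lstm1.Wx").g.begin());
      std::copy(dWh1.begin(), dWh1.end(), P("ah.lstm1.Wh").g.begin());
      std::copy(dbl1.begin(), dbl1.end(), P("ah.lstm1.b").g.begin());
      std::copy(dWx2.begin(), dWx2.end(), P("ah.lstm2.Wx").g.begin());
      std::copy(dWh2.begin(), dWh2.end(), P("ah.lstm2.Wh").g.begin());
      std::copy(dbl2.begin(), dbl2.end(), P("ah.lstm2.b").g.begin());
      std::copy(dWd.begin(), dWd.end(), P("ah.dense.W").g.begin());
      std::copy(dbd.begin(), dbd.end(), P("ah.dense.b").g.begin());
      adam_update(ps, ++adam_t, lr, beta1, beta2, adam_eps);
    }
    losses[ep] = ep_loss / nb;
    if (ep % 5 == 4) Rcpp::checkUserInterrupt();
  }

  Rcpp::List out_params = Rcpp::clone(params);
  for (auto& p : ps) {
    Rcpp::NumericVector rv = out_params[p.name];
    std::copy(p.master.begin(), p.master.end(), rv.begin());
  }
  return Rcpp::List::create(Rcpp::Named("error") = false,
                            Rcpp::Named("params") = out_params,
                            Rcpp::Named("losses") = losses);
}
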