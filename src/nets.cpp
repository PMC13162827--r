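// Recurrent forecasting engines: GRU / LSTM / dilated-causal TCN backbones,
// optional efficient channel attention (ECA) on the input window, a linear
// regression head, and an Adam training loop with chronological-validation
// early stopping. All randomness (parameter init, batch shuffling) comes
// from one std::mt19937 seed, so training is bit-reproducible on one device.
//
// Sample layout: a window is an L x C matrix (L time steps, C channels);
// batches hold X_t as C x B matrices per step. The backbone's final hidden
// state is the sequence representation; the head maps it to one scalar.

#include <RcppArmadillo.h>
#include <random>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
typedef std::map<std::string, mat> Params;

struct Cfg {
  std::string type;  // "gru", "lstm", "tcn"
  bool eca, bias;
  int hidden, k, ksize;
  std::vector<int> dil;
};

static Cfg parse_cfg(const Rcpp::List& cfg) {
  Cfg c;
  c.type = Rcpp::as<std::string>(cfg["type"]);
  c.eca = Rcpp::as<bool>(cfg["eca"]);
  c.bias = Rcpp::as<bool>(cfg["bias"]);
  c.hidden = Rcpp::as<int>(cfg["hidden"]);
  c.k = Rcpp::as<int>(cfg["k"]);
  c.ksize = cfg.containsElementNamed("ksize") ? Rcpp::as<int>(cfg["ksize"]) : 3;
  if (cfg.containsElementNamed("dilations"))
    c.dil = Rcpp::as<std::vector<int>>(cfg["dilations"]);
  else
    c.dil = {1, 2, 4, 8, 16};
  return c;
}

static Params from_list(const Rcpp::List& lst) {
  Params p;
  Rcpp::CharacterVector nm = lst.names();
  for (int i = 0; i < lst.size(); i++)
    p[Rcpp::as<std::string>(nm[i])] = Rcpp::as<mat>(lst[i]);
  return p;
}

static Rcpp::List to_list(const Params& p) {
  Rcpp::List out;
  for (auto& kv : p) out[kv.first] = kv.second;
  return out;
}

static mat rand_mat(int r, int cc, double scale, std::mt19937& gen) {
  std::uniform_real_distribution<double> U(-scale, scale);
  mat m(r, cc);
  for (uword j = 0; j < m.n_cols; j++)
    for (uword i = 0; i < m.n_rows; i++) m(i, j) = U(gen);
  return m;
}

static Params init_params(const Cfg& c, int C, std::mt19937& gen) {
  Params p;
  int H = c.hidden;
  double si = 1.0 / std::sqrt((double)H);
  if (c.type == "gru") {
    const char* g[] = {"z", "r", "h"};
    for (auto* s : g) {
      p[std::string("W") + s] = rand_mat(H, C, si, gen);
      p[std::string("U") + s] = rand_mat(H, H, si, gen);
      p[std::string("b") + s] = zeros<mat>(H, 1);
    }
  } else if (c.type == "lstm") {
    const char* g[] = {"i", "f", "o", "g"};
    for (auto* s : g) {
      p[std::string("W") + s] = rand_mat(H, C, si, gen);
      p[std::string("U") + s] = rand_mat(H, H, si, gen);
      p[std::string("b") + s] = zeros<mat>(H, 1);
    }
  } else if (c.type == "tcn") {
    int cin = C;
    for (size_t l = 0; l < c.dil.size(); l++) {
      double sf = 1.0 / std::sqrt((double)(cin * c.ksize));
      p["K" + std::to_string(l + 1)] = rand_mat(H, cin * c.ksize, sf, gen);
      p["c" + std::to_string(l + 1)] = zeros<mat>(H, 1);
      cin = H;
    }
  } else {
    Rcpp::stop("unknown backbone type '%s'", c.type.c_str());
  }
  if (c.eca) p["alpha"] = rand_mat(c.k, 1, 1.0 / std::sqrt((double)c.k), gen);
  p["Wy"] = rand_mat(1, H, si, gen);
  p["by"] = zeros<mat>(1, 1);
  return p;
}

// gather batch: Xt[t] is C x B; d is the per-channel temporal mean (C x B)
static void gather(const cube& X, const std::vector<int>& idx,
                   std::vector<mat>& Xt, mat& d) {
  int L = X.n_rows, C = X.n_cols, B = idx.size();
  Xt.assign(L, mat(C, B));
  for (int b = 0; b < B; b++) {
    const mat& s = X.slice(idx[b]);  // L x C
    for (int t = 0; t < L; t++)
      for (int ch = 0; ch < C; ch++) Xt[t](ch, b) = s(t, ch);
  }
  d = zeros<mat>(C, B);
  for (int t = 0; t < L; t++) d += Xt[t];
  d /= (double)L;
}

static mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// zero-padded shared 1-D convolution along the channel axis
static mat eca_conv(const mat& d, const vec& alpha) {
  int C = d.n_rows, k = alpha.n_elem, p = (k - 1) / 2;
  mat s = zeros<mat>(C, d.n_cols);
  for (int i = 0; i < C; i++)
    for (int j = 0; j < k; j++) {
      int m = i + j - p;
      if (m >= 0 && m < C) s.row(i) += alpha(j) * d.row(m);
    }
  return s;
}

struct Cache {
  std::vector<mat> Xt, Xw;            // raw and attention-weighted inputs
  mat d, w;                           // ECA descriptor and weights
  std::vector<mat> Z, R, Hc, H;       // GRU gates
  std::vector<mat> I, F, O, G, Cc, Th;// LSTM gates, cell, tanh(cell)
  std::vector<std::vector<mat>> A;    // TCN activations per layer per step
  mat h;                              // final representation (H x B)
  rowvec yhat;
};

static void forward_batch(const cube& X, const std::vector<int>& idx,
                          const Params& P, const Cfg& c, Cache& K) {
  int L = X.n_rows, B = idx.size();
  gather(X, idx, K.Xt, K.d);
  if (c.eca) {
    K.w = sigm(eca_conv(K.d, P.at("alpha").col(0)));
    K.Xw.assign(L, mat());
    for (int t = 0; t < L; t++) K.Xw[t] = K.Xt[t] % K.w;
  } else {
    K.Xw = K.Xt;
  }
  int H = c.hidden;
  if (c.type == "gru") {
    K.Z.assign(L, mat()); K.R.assign(L, mat()); K.Hc.assign(L, mat()); K.H.assign(L, mat());
    mat h = zeros<mat>(H, B);
    const mat &Wz = P.at("Wz"), &Uz = P.at("Uz"), &Wr = P.at("Wr"), &Ur = P.at("Ur"),
              &Wh = P.at("Wh"), &Uh = P.at("Uh");
    // input contributions of all steps in three large matmuls
    int C = K.Xw[0].n_rows;
    mat Xs(C, (size_t)B * L);
    for (int t = 0; t < L; t++) Xs.cols((size_t)t * B, (size_t)t * B + B - 1) = K.Xw[t];
    mat PZ = Wz * Xs, PR = Wr * Xs, PH = Wh * Xs;
    PZ.each_col() += P.at("bz").col(0);
    PR.each_col() += P.at("br").col(0);
    PH.each_col() += P.at("bh").col(0);
    for (int t = 0; t < L; t++) {
      span cs((size_t)t * B, (size_t)t * B + B - 1);
      mat z = sigm(PZ.cols(cs) + Uz * h);
      mat r = sigm(PR.cols(cs) + Ur * h);
      mat hc = tanh(PH.cols(cs) + Uh * (r % h));
      h = (1.0 - z) % h + z % hc;
      K.Z[t] = z; K.R[t] = r; K.Hc[t] = hc; K.H[t] = h;
    }
    K.h = h;
  } else if (c.type == "lstm") {
    K.I.assign(L, mat()); K.F.assign(L, mat()); K.O.assign(L, mat());
    K.G.assign(L, mat()); K.Cc.assign(L, mat()); K.Th.assign(L, mat()); K.H.assign(L, mat());
    mat h = zeros<mat>(H, B), cc = zeros<mat>(H, B);
    for (int t = 0; t < L; t++) {
      mat i = sigm(P.at("Wi") * K.Xw[t] + P.at("Ui") * h + repmat(P.at("bi"), 1, B));
      mat f = sigm(P.at("Wf") * K.Xw[t] + P.at("Uf") * h + repmat(P.at("bf"), 1, B));
      mat o = sigm(P.at("Wo") * K.Xw[t] + P.at("Uo") * h + repmat(P.at("bo"), 1, B));
      mat g = tanh(P.at("Wg") * K.Xw[t] + P.at("Ug") * h + repmat(P.at("bg"), 1, B));
      cc = f % cc + i % g;
      mat th = tanh(cc);
      h = o % th;
      K.I[t] = i; K.F[t] = f; K.O[t] = o; K.G[t] = g; K.Cc[t] = cc; K.Th[t] = th; K.H[t] = h;
    }
    K.h = h;
  } else {  // tcn
    int nl = c.dil.size(), ks = c.ksize;
    K.A.assign(nl + 1, std::vector<mat>());
    K.A[0] = K.Xw;
    for (int l = 0; l < nl; l++) {
      const mat& Kl = P.at("K" + std::to_string(l + 1));
      const mat& bl = P.at("c" + std::to_string(l + 1));
      int cin = K.A[l][0].n_rows, dl = c.dil[l];
      K.A[l + 1].assign(L, mat());
      for (int t = 0; t < L; t++) {
        mat pre = repmat(bl, 1, B);
        for (int j = 0; j < ks; j++) {
          int tt = t - j * dl;
          if (tt >= 0) pre += Kl.cols(j * cin, (j + 1) * cin - 1) * K.A[l][tt];
        }
        pre.elem(find(pre < 0.0)).zeros();  // ReLU
        K.A[l + 1][t] = pre;
      }
    }
    K.h = K.A[nl][L - 1];
  }
  K.yhat = P.at("Wy") * K.h + as_scalar(P.at("by"));
}

// backward pass; fills G with gradients, returns the batch MSE
static double backward_batch(const cube& X, const std::vector<int>& idx,
                             const rowvec& y, const Params& P, const Cfg& c,
                             Params& Gr) {
  Cache K;
  forward_batch(X, idx, P, c, K);
  int L = X.n_rows, B = idx.size(), H = c.hidden;
  for (auto& kv : P) Gr[kv.first] = zeros<mat>(kv.second.n_rows, kv.second.n_cols);
  rowvec diff = K.yhat - y;
  double loss = as_scalar(diff * diff.t()) / B;
  rowvec dy = 2.0 * diff / B;

  Gr["Wy"] = dy * K.h.t();
  Gr["by"](0, 0) = accu(dy);
  mat dh = P.at("Wy").t() * dy;   // H x B
  std::vector<mat> dXw(L, zeros<mat>(K.Xw[0].n_rows, B));

  if (c.type == "gru") {
    const mat &Wz = P.at("Wz"), &Uz = P.at("Uz"), &Wr = P.at("Wr"), &Ur = P.at("Ur"),
              &Wh = P.at("Wh"), &Uh = P.at("Uh");
    int C = K.Xw[0].n_rows;
    // collect per-step pre-activation gradients; weight/input gradients are
    // formed afterwards in three large matmuls
    mat Xs(C, (size_t)B * L), DZ(H, (size_t)B * L), DR(H, (size_t)B * L),
        DHc(H, (size_t)B * L);
    for (int t = 0; t < L; t++) Xs.cols((size_t)t * B, (size_t)t * B + B - 1) = K.Xw[t];
    for (int t = L - 1; t >= 0; t--) {
      span cs((size_t)t * B, (size_t)t * B + B - 1);
      mat hp = (t == 0) ? zeros<mat>(H, B) : K.H[t - 1];
      mat dz = dh % (K.Hc[t] - hp);
      mat dhc = dh % K.Z[t];
      mat dhp = dh % (1.0 - K.Z[t]);
      mat dhc_pre = dhc % (1.0 - K.Hc[t] % K.Hc[t]);
      Gr["Uh"] += dhc_pre * (K.R[t] % hp).t();
      mat tmp = Uh.t() * dhc_pre;
      mat dr = tmp % hp;
      dhp += tmp % K.R[t];
      mat dz_pre = dz % K.Z[t] % (1.0 - K.Z[t]);
      mat dr_pre = dr % K.R[t] % (1.0 - K.R[t]);
      Gr["Uz"] += dz_pre * hp.t();
      Gr["Ur"] += dr_pre * hp.t();
      dhp += Uz.t() * dz_pre + Ur.t() * dr_pre;
      DZ.cols(cs) = dz_pre; DR.cols(cs) = dr_pre; DHc.cols(cs) = dhc_pre;
      dh = dhp;
    }
    Gr["Wz"] = DZ * Xs.t(); Gr["Wr"] = DR * Xs.t(); Gr["Wh"] = DHc * Xs.t();
    Gr["bz"] = sum(DZ, 1); Gr["br"] = sum(DR, 1); Gr["bh"] = sum(DHc, 1);
    if (c.eca) {
      mat DX = Wz.t() * DZ + Wr.t() * DR + Wh.t() * DHc;
      for (int t = 0; t < L; t++)
        dXw[t] = DX.cols((size_t)t * B, (size_t)t * B + B - 1);
    }
  } else if (c.type == "lstm") {
    mat dc = zeros<mat>(H, B);
    for (int t = L - 1; t >= 0; t--) {
      mat hp = (t == 0) ? zeros<mat>(H, B) : K.H[t - 1];
      mat cp = (t == 0) ? zeros<mat>(H, B) : K.Cc[t - 1];
      mat dtc = dh % K.O[t] % (1.0 - K.Th[t] % K.Th[t]) + dc;
      mat do_ = dh % K.Th[t];
      mat di = dtc % K.G[t];
      mat dg = dtc % K.I[t];
      mat df = dtc % cp;
      dc = dtc % K.F[t];
      mat di_p = di % K.I[t] % (1.0 - K.I[t]);
      mat df_p = df % K.F[t] % (1.0 - K.F[t]);
      mat do_p = do_ % K.O[t] % (1.0 - K.O[t]);
      mat dg_p = dg % (1.0 - K.G[t] % K.G[t]);
      Gr["Wi"] += di_p * K.Xw[t].t(); Gr["Ui"] += di_p * hp.t(); Gr["bi"] += sum(di_p, 1);
      Gr["Wf"] += df_p * K.Xw[t].t(); Gr["Uf"] += df_p * hp.t(); Gr["bf"] += sum(df_p, 1);
      Gr["Wo"] += do_p * K.Xw[t].t(); Gr["Uo"] += do_p * hp.t(); Gr["bo"] += sum(do_p, 1);
      Gr["Wg"] += dg_p * K.Xw[t].t(); Gr["Ug"] += dg_p * hp.t(); Gr["bg"] += sum(dg_p, 1);
      dXw[t] = P.at("Wi").t() * di_p + P.at("Wf").t() * df_p +
               P.at("Wo").t() * do_p + P.at("Wg").t() * dg_p;
      dh = P.at("Ui").t() * di_p + P.at("Uf").t() * df_p +
           P.at("Uo").t() * do_p + P.at("Ug").t() * dg_p;
    }
  } else {  // tcn
    int nl = c.dil.size(), ks = c.ksize;
    std::vector<std::vector<mat>> dA(nl + 1);
    for (int l = 0; l <= nl; l++)
      dA[l].assign(L, zeros<mat>(K.A[l][0].n_rows, B));
    dA[nl][L - 1] = dh;
    for (int l = nl - 1; l >= 0; l--) {
      const mat& Kl = P.at("K" + std::to_string(l + 1));
      mat& gK = Gr["K" + std::to_string(l + 1)];
      mat& gb = Gr["c" + std::to_string(l + 1)];
      int cin = K.A[l][0].n_rows, dl = c.dil[l];
      for (int t = 0; t < L; t++) {
        mat dpre = dA[l + 1][t] % conv_to<mat>::from(K.A[l + 1][t] > 0.0);
        if (accu(abs(dpre)) == 0.0) continue;
        gb += sum(dpre, 1);
        for (int j = 0; j < ks; j++) {
          int tt = t - j * dl;
          if (tt < 0) continue;
          gK.cols(j * cin, (j + 1) * cin - 1) += dpre * K.A[l][tt].t();
          dA[l][tt] += Kl.cols(j * cin, (j + 1) * cin - 1).t() * dpre;
        }
      }
    }
    dXw = dA[0];
  }

  if (c.eca) {
    int C = K.d.n_rows, k = c.k, p = (k - 1) / 2;
    mat dw = zeros<mat>(C, B);
    for (int t = 0; t < L; t++) dw += dXw[t] % K.Xt[t];
    mat ds = dw % K.w % (1.0 - K.w);
    vec galpha = zeros<vec>(k);
    for (int i = 0; i < C; i++)
      for (int j = 0; j < k; j++) {
        int m = i + j - p;
        if (m >= 0 && m < C) galpha(j) += accu(ds.row(i) % K.d.row(m));
      }
    Gr["alpha"] = galpha;
  }
  if (!c.bias) {
    for (auto& kv : Gr)
      if (kv.first[0] == 'b' || kv.first[0] == 'c')
        if (kv.first != "by") kv.second.zeros();  // head bias always trained
  }
  return loss;
}

static rowvec predict_all(const cube& X, const Params& P, const Cfg& c,
                          int chunk = 512) {
  int N = X.n_slices;
  rowvec out(N);
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    std::vector<int> idx;
    for (int i = s; i < e; i++) idx.push_back(i);
    Cache K;
    forward_batch(X, idx, P, c, K);
    out.subvec(s, e - 1) = K.yhat;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_init_params(Rcpp::List cfg, int C, int seed) {
  Cfg c = parse_cfg(cfg);
  std::mt19937 gen(seed);
  return to_list(init_params(c, C, gen));
}

// [[Rcpp::export]]
arma::rowvec cpp_forward(arma::cube X, Rcpp::List params, Rcpp::List cfg) {
  return predict_all(X, from_list(params), parse_cfg(cfg));
}

// [[Rcpp::export]]
arma::mat cpp_hidden(arma::cube X, Rcpp::List params, Rcpp::List cfg) {
  Cfg c = parse_cfg(cfg);
  Params P = from_list(params);
  std::vector<int> idx;
  for (uword i = 0; i < X.n_slices; i++) idx.push_back(i);
  Cache K;
  forward_batch(X, idx, P, c, K);
  return K.h;
}

// [[Rcpp::export]]
arma::vec cpp_eca_weights(arma::mat window, arma::vec alpha) {
  // window: L x C; returns the C attention weights
  mat d = mean(window, 0).t();  // C x 1
  return vec(sigm(eca_conv(d, alpha)));
}

// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(arma::cube X, arma::vec y, Rcpp::List params,
                         Rcpp::List cfg) {
  Cfg c = parse_cfg(cfg);
  Params P = from_list(params), Gr;
  std::vector<int> idx;
  for (uword i = 0; i < X.n_slices; i++) idx.push_back(i);
  double loss = backward_batch(X, idx, y.t(), P, c, Gr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = to_list(Gr));
}

// [[Rcpp::export]]
Rcpp::List cpp_train(arma::cube Xtr, arma::vec ytr, arma::cube Xval,
                     arma::vec yval, Rcpp::List cfg, double lr, int batch,
                     int epochs, int patience, int seed) {
  Cfg c = parse_cfg(cfg);
  std::mt19937 gen(seed);
  Params P = init_params(c, Xtr.n_cols, gen);
  Params M, V;
  for (auto& kv : P) {
    M[kv.first] = zeros<mat>(kv.second.n_rows, kv.second.n_cols);
    V[kv.first] = zeros<mat>(kv.second.n_rows, kv.second.n_cols);
  }
  int N = Xtr.n_slices;
  bool has_val = Xval.n_slices > 0;
  std::vector<int> order(N);
  for (int i = 0; i < N; i++) order[i] = i;
  std::vector<double> tr_hist, val_hist;
  double best_val = datum::inf;
  Params best = P;
  int best_epoch = 0, wait = 0, step = 0, epoch = 0;
  const double b1 = 0.9, b2 = 0.999, epsad = 1e-8;
  rowvec ytr_r = ytr.t(), yval_r = yval.t();

  for (epoch = 1; epoch <= epochs; epoch++) {
    std::shuffle(order.begin(), order.end(), gen);
    double ep_loss = 0.0;
    int nb = 0;
    for (int s = 0; s < N; s += batch) {
      int e = std::min(N, s + batch);
      std::vector<int> idx(order.begin() + s, order.begin() + e);
      rowvec yb(idx.size());
      for (size_t i = 0; i < idx.size(); i++) yb(i) = ytr_r(idx[i]);
      Params Gr;
      ep_loss += backward_batch(Xtr, idx, yb, P, c, Gr);
      nb++;
      step++;
      double corr = lr * std::sqrt(1.0 - std::pow(b2, step)) /
                    (1.0 - std::pow(b1, step));
      for (auto& kv : P) {
        mat& g = Gr[kv.first];
        mat& m = M[kv.first];
        mat& v = V[kv.first];
        m = b1 * m + (1.0 - b1) * g;
        v = b2 * v + (1.0 - b2) * (g % g);
        kv.second -= corr * m / (sqrt(v) + epsad);
      }
    }
    tr_hist.push_back(ep_loss / nb);
    if (has_val) {
      rowvec pv = predict_all(Xval, P, c);
      double vl = as_scalar((pv - yval_r) * (pv - yval_r).t()) / Xval.n_slices;
      val_hist.push_back(vl);
      if (vl < best_val - 1e-12) {
        best_val = vl; best = P; best_epoch = epoch; wait = 0;
      } else if (++wait >= patience) break;
    } else {
      best = P; best_epoch = epoch;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = to_list(best),
      Rcpp::Named("train_loss") = tr_hist,
      Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("epochs_run") = std::min(epoch, epochs));
}
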