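// Recurrent (LSTM) sequence autoencoder over one-hot node-id sequences.
// Encoder LSTM: |V|-dim one-hot input -> H-dim hidden state per step (the
// per-step hidden states are the low-dimension codes). Decoder LSTM consumes
// the codes step by step; a linear layer projects its hidden states back to
// |V|. Trained with mean-squared error against the one-hot input, by Adam.
//
// Gate column layout in all 4H-wide weight blocks: [input | forget | cell | output].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;

namespace {

struct AEW {
  mat Wxe, Whe, be;  // encoder: V x 4H, H x 4H, 1 x 4H
  mat Wxd, Whd, bd;  // decoder: H x 4H, H x 4H, 1 x 4H
  mat Wo, bo;        // projection: H x V, 1 x V
};

AEW weights_from_list(const List& w) {
  AEW W;
  W.Wxe = as<mat>(w["Wxe"]); W.Whe = as<mat>(w["Whe"]); W.be = as<mat>(w["be"]);
  W.Wxd = as<mat>(w["Wxd"]); W.Whd = as<mat>(w["Whd"]); W.bd = as<mat>(w["bd"]);
  W.Wo = as<mat>(w["Wo"]);   W.bo = as<mat>(w["bo"]);
  return W;
}

List weights_to_list(const AEW& W) {
  return List::create(_["Wxe"] = W.Wxe, _["Whe"] = W.Whe, _["be"] = W.be,
                      _["Wxd"] = W.Wxd, _["Whd"] = W.Whd, _["bd"] = W.bd,
                      _["Wo"] = W.Wo, _["bo"] = W.bo);
}

void zero_like(const AEW& W, AEW& G) {
  G.Wxe = arma::zeros<mat>(W.Wxe.n_rows, W.Wxe.n_cols);
  G.Whe = arma::zeros<mat>(W.Whe.n_rows, W.Whe.n_cols);
  G.be  = arma::zeros<mat>(W.be.n_rows, W.be.n_cols);
  G.Wxd = arma::zeros<mat>(W.Wxd.n_rows, W.Wxd.n_cols);
  G.Whd = arma::zeros<mat>(W.Whd.n_rows, W.Whd.n_cols);
  G.bd  = arma::zeros<mat>(W.bd.n_rows, W.bd.n_cols);
  G.Wo  = arma::zeros<mat>(W.Wo.n_rows, W.Wo.n_cols);
  G.bo  = arma::zeros<mat>(W.bo.n_rows, W.bo.n_cols);
}

mat runif_mat(int r, int c, double k) {
  mat m(r, c);
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = (2.0 * unif_rand() - 1.0) * k;
  return m;
}

mat rnorm_mat(int r, int c) {
  mat m(r, c);
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = norm_rand();
  return m;
}

AEW init_weights(int vocab, int H) {
  // One-hot inputs turn the encoder input matrix into an embedding table: a
  // node's entire input signature is one row of Wxe. Rows are initialised at
  // unit scale (standard normal, the usual embedding init) so distinct nodes
  // start with distinct signatures; recurrent/projection weights use the
  // usual uniform(-1/sqrt(H), 1/sqrt(H)) LSTM scaling.
  const double k = 1.0 / std::sqrt((double)H);
  AEW W;
  W.Wxe = rnorm_mat(vocab, 4 * H); W.Whe = runif_mat(H, 4 * H, k);
  W.be = runif_mat(1, 4 * H, k);
  W.Wxd = runif_mat(H, 4 * H, k); W.Whd = runif_mat(H, 4 * H, k);
  W.bd = runif_mat(1, 4 * H, k);
  W.Wo = runif_mat(H, vocab, k); W.bo = runif_mat(1, vocab, k);
  return W;
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct StepCache {
  mat gi, gf, gg, go, tc, cprev, hprev, h;
};

void lstm_step(const mat& xWx, const mat& h, const mat& c, const mat& Wh,
               const mat& b, StepCache& s) {
  const int H = (int)Wh.n_rows;
  mat a = xWx + h * Wh;
  a.each_row() += b;
  s.gi = sigmoid(a.cols(0, H - 1));
  s.gf = sigmoid(a.cols(H, 2 * H - 1));
  s.gg = arma::tanh(a.cols(2 * H, 3 * H - 1));
  s.go = sigmoid(a.cols(3 * H, 4 * H - 1));
  s.cprev = c;
  s.hprev = h;
  mat cnew = s.gf % c + s.gi % s.gg;
  s.tc = arma::tanh(cnew);
  s.h = s.go % s.tc;
}

// backward through one LSTM step; dh/dc are gradients w.r.t. this step's
// outputs (h, c); on return they hold gradients w.r.t. the previous step's.
// da_out receives the pre-activation gradient (B x 4H).
void lstm_step_back(const StepCache& s, mat& dh, mat& dc, const mat& Wh, mat& da_out) {
  mat do_ = dh % s.tc;
  dc += dh % s.go % (1.0 - s.tc % s.tc);
  mat di = dc % s.gg;
  mat dg = dc % s.gi;
  mat df = dc % s.cprev;
  mat dcprev = dc % s.gf;
  mat dai = di % s.gi % (1.0 - s.gi);
  mat daf = df % s.gf % (1.0 - s.gf);
  mat dag = dg % (1.0 - s.gg % s.gg);
  mat dao = do_ % s.go % (1.0 - s.go);
  da_out = arma::join_rows(arma::join_rows(dai, daf), arma::join_rows(dag, dao));
  dh = da_out * Wh.t();
  dc = dcprev;
}

// Forward (and optionally backward) pass over one padded batch.
// idx: B x L node indices, -1 padding; lens: true lengths.
double ae_batch(const AEW& W, const arma::imat& idx, const arma::ivec& lens,
                AEW* G) {
  const int B = (int)idx.n_rows, L = (int)idx.n_cols;
  const int H = (int)W.Whe.n_rows, V = (int)W.Wxe.n_rows;
  long M = 0;
  for (int b = 0; b < B; ++b) M += lens(b);
  if (M == 0) return 0.0;
  const double denom = (double)M * (double)V;

  std::vector<StepCache> enc(L), dec(L);
  std::vector<mat> r(L), diff(L);
  mat h = arma::zeros<mat>(B, H), c = arma::zeros<mat>(B, H);
  for (int t = 0; t < L; ++t) {
    mat xWx = arma::zeros<mat>(B, 4 * H);
    for (int b = 0; b < B; ++b)
      if (idx(b, t) >= 0) xWx.row(b) = W.Wxe.row(idx(b, t));
    lstm_step(xWx, h, c, W.Whe, W.be, enc[t]);
    h = enc[t].h;
    c = enc[t].gf % enc[t].cprev + enc[t].gi % enc[t].gg;
    r[t] = h;
  }
  h.zeros(); c.zeros();
  double loss = 0.0;
  for (int t = 0; t < L; ++t) {
    lstm_step(r[t] * W.Wxd, h, c, W.Whd, W.bd, dec[t]);
    h = dec[t].h;
    c = dec[t].gf % dec[t].cprev + dec[t].gi % dec[t].gg;
    mat y = h * W.Wo;
    y.each_row() += W.bo;
    for (int b = 0; b < B; ++b) {
      if (lens(b) > t) {
        y(b, idx(b, t)) -= 1.0;  // subtract one-hot target
      } else {
        y.row(b).zeros();        // padded steps carry no loss
      }
    }
    loss += arma::accu(y % y);
    if (G) diff[t] = y;
  }
  loss /= denom;
  if (!G) return loss;

  // ---- backward ----
  std::vector<mat> dr(L);
  mat dh = arma::zeros<mat>(B, H), dc = arma::zeros<mat>(B, H), da;
  for (int t = L - 1; t >= 0; --t) {
    mat dy = (2.0 / denom) * diff[t];
    G->Wo += dec[t].h.t() * dy;
    G->bo += arma::sum(dy, 0);
    dh += dy * W.Wo.t();
    lstm_step_back(dec[t], dh, dc, W.Whd, da);
    G->Wxd += r[t].t() * da;
    G->Whd += dec[t].hprev.t() * da;
    G->bd += arma::sum(da, 0);
    dr[t] = da * W.Wxd.t();
    // dh already holds gradient w.r.t. previous decoder hidden state
  }
  dh.zeros(); dc.zeros();
  for (int t = L - 1; t >= 0; --t) {
    dh += dr[t];
    lstm_step_back(enc[t], dh, dc, W.Whe, da);
    for (int b = 0; b < B; ++b)
      if (idx(b, t) >= 0) G->Wxe.row(idx(b, t)) += da.row(b);
    G->Whe += enc[t].hprev.t() * da;
    G->be += arma::sum(da, 0);
  }
  return loss;
}

struct Adam {
  AEW m, v;
  long t;
  double b1, b2, eps;
  Adam(const AEW& W) : t(0), b1(0.9), b2(0.999), eps(1e-8) {
    zero_like(W, m);
    zero_like(W, v);
  }
  void upd1(mat& p, const mat& g, mat& mm, mat& vv, double lr) {
    mm = b1 * mm + (1.0 - b1) * g;
    vv = b2 * vv + (1.0 - b2) * (g % g);
    const double bc1 = 1.0 - std::pow(b1, (double)t);
    const double bc2 = 1.0 - std::pow(b2, (double)t);
    p -= lr * (mm / bc1) / (arma::sqrt(vv / bc2) + eps);
  }
  void step(AEW& W, const AEW& G, double lr) {
    ++t;
    upd1(W.Wxe, G.Wxe, m.Wxe, v.Wxe, lr);
    upd1(W.Whe, G.Whe, m.Whe, v.Whe, lr);
    upd1(W.be, G.be, m.be, v.be, lr);
    upd1(W.Wxd, G.Wxd, m.Wxd, v.Wxd, lr);
    upd1(W.Whd, G.Whd, m.Whd, v.Whd, lr);
    upd1(W.bd, G.bd, m.bd, v.bd, lr);
    upd1(W.Wo, G.Wo, m.Wo, v.Wo, lr);
    upd1(W.bo, G.bo, m.bo, v.bo, lr);
  }
};

arma::imat idx_from_R(const IntegerMatrix& seq_idx) {
  arma::imat idx(seq_idx.nrow(), seq_idx.ncol());
  for (int i = 0; i < seq_idx.nrow(); ++i)
    for (int j = 0; j < seq_idx.ncol(); ++j)
      idx(i, j) = (seq_idx(i, j) == NA_INTEGER) ? -1 : seq_idx(i, j) - 1;
  return idx;
}

}  // namespace

// [[Rcpp::export(name = "cpp_ae_init")]]
List cpp_ae_init(int vocab, int code_dim) {
  return weights_to_list(init_weights(vocab, code_dim));
}

// [[Rcpp::export(name = "cpp_ae_loss")]]
double cpp_ae_loss(IntegerMatrix seq_idx, IntegerVector lens, List weights) {
  AEW W = weights_from_list(weights);
  arma::imat idx = idx_from_R(seq_idx);
  arma::ivec lv = as<arma::ivec>(lens);
  return ae_batch(W, idx, lv, (AEW*)0);
}

// [[Rcpp::export(name = "cpp_ae_grad")]]
List cpp_ae_grad(IntegerMatrix seq_idx, IntegerVector lens, List weights) {
  AEW W = weights_from_list(weights);
  arma::imat idx = idx_from_R(seq_idx);
  arma::ivec lv = as<arma::ivec>(lens);
  AEW G;
  zero_like(W, G);
  const double loss = ae_batch(W, idx, lv, &G);
  List out = weights_to_list(G);
  out["loss"] = loss;
  return out;
}

// [[Rcpp::export(name = "cpp_ae_train")]]
List cpp_ae_train(IntegerMatrix seq_idx, IntegerVector lens, int vocab,
                  int code_dim, int epochs, int batch_size, double lr,
                  Nullable<List> init) {
  arma::imat idx = idx_from_R(seq_idx);
  arma::ivec lv = as<arma::ivec>(lens);
  const int n = (int)idx.n_rows, L = (int)idx.n_cols;
  if (n < 1) stop("empty training set");
  AEW W = init.isNotNull() ? weights_from_list(List(init)) : init_weights(vocab, code_dim);
  Adam opt(W);
  NumericVector losses(epochs);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    double epoch_loss = 0.0;
    long epoch_steps = 0;
    for (int start = 0; start < n; start += batch_size) {
      Rcpp::checkUserInterrupt();
      const int stop_ = std::min(n, start + batch_size);
      const int B = stop_ - start;
      arma::imat bidx(B, L);
      arma::ivec blens(B);
      for (int b = 0; b < B; ++b) {
        bidx.row(b) = idx.row(ord[start + b]);
        blens(b) = lv(ord[start + b]);
      }
      AEW G;
      zero_like(W, G);
      const double l = ae_batch(W, bidx, blens, &G);
      opt.step(W, G, lr);
      long M = 0;
      for (int b = 0; b < B; ++b) M += blens(b);
      epoch_loss += l * (double)M;
      epoch_steps += M;
    }
    losses[ep] = epoch_steps > 0 ? epoch_loss / (double)epoch_steps : 0.0;
  }
  return List::create(_["weights"] = weights_to_list(W), _["loss"] = losses);
}

// Encoder-only forward pass; returns per-sequence code slabs flattened
// row-major as (step, code) -> column (step-1)*code_dim + code, zero-padded to
// l_max steps.
// [[Rcpp::export(name = "cpp_ae_encode")]]
NumericMatrix cpp_ae_encode(IntegerMatrix seq_idx, IntegerVector lens,
                            List weights, int lmax) {
  AEW W = weights_from_list(weights);
  const int H = (int)W.Whe.n_rows;
  arma::imat idx = idx_from_R(seq_idx);
  const int n = (int)idx.n_rows, L = (int)idx.n_cols;
  if (L > lmax) stop("sequences longer than l_max");
  NumericMatrix out(n, lmax * H);
  const int chunk = 4096;
  for (int start = 0; start < n; start += chunk) {
    const int stop_ = std::min(n, start + chunk);
    const int B = stop_ - start;
    mat h = arma::zeros<mat>(B, H), c = arma::zeros<mat>(B, H);
    StepCache s;
    for (int t = 0; t < L; ++t) {
      mat xWx = arma::zeros<mat>(B, 4 * H);
      for (int b = 0; b < B; ++b)
        if (idx(start + b, t) >= 0) xWx.row(b) = W.Wxe.row(idx(start + b, t));
      lstm_step(xWx, h, c, W.Whe, W.be, s);
      h = s.h;
      c = s.gf % s.cprev + s.gi % s.gg;
      for (int b = 0; b < B; ++b) {
        if (lens[start + b] > t) {
          for (int d = 0; d < H; ++d) out(start + b, t * H + d) = h(b, d);
        }
      }
    }
  }
  return out;
}

// Full forward pass; fraction of valid steps whose reconstruction argmax
// recovers the input node.
// [[Rcpp::export(name = "cpp_ae_reconstruct_acc")]]
double cpp_ae_reconstruct_acc(IntegerMatrix seq_idx, IntegerVector lens,
                              List weights) {
  AEW W = weights_from_list(weights);
  const int H = (int)W.Whe.n_rows;
  arma::imat idx = idx_from_R(seq_idx);
  const int n = (int)idx.n_rows, L = (int)idx.n_cols;
  long correct = 0, total = 0;
  const int chunk = 2048;
  for (int start = 0; start < n; start += chunk) {
    const int stop_ = std::min(n, start + chunk);
    const int B = stop_ - start;
    std::vector<mat> r(L);
    mat h = arma::zeros<mat>(B, H), c = arma::zeros<mat>(B, H);
    StepCache s;
    for (int t = 0; t < L; ++t) {
      mat xWx = arma::zeros<mat>(B, 4 * H);
      for (int b = 0; b < B; ++b)
        if (idx(start + b, t) >= 0) xWx.row(b) = W.Wxe.row(idx(start + b, t));
      lstm_step(xWx, h, c, W.Whe, W.be, s);
      h = s.h;
      c = s.gf % s.cprev + s.gi % s.gg;
      r[t] = h;
    }
    h.zeros(); c.zeros();
    for (int t = 0; t < L; ++t) {
      lstm_step(r[t] * W.Wxd, h, c, W.Whd, W.bd, s);
      h = s.h;
      c = s.gf % s.cprev + s.gi % s.gg;
      mat y = h * W.Wo;
      y.each_row() += W.bo;
      for (int b = 0; b < B; ++b) {
        if (lens[start + b] > t) {
          ++total;
          if ((int)y.row(b).index_max() == idx(start + b, t)) ++correct;
        }
      }
    }
  }
  return total > 0 ? (double)correct / (double)total : NA_REAL;
}

// Fill the flattened classifier design matrix from encoded unique sequences.
// placements columns: record, group, slot, seq (all 1-based). Column order of
// the output: (((group-1)*eta + slot-1)*lmax + step-1)*code_dim + code.
// [[Rcpp::export(name = "cpp_pack_representation")]]
NumericMatrix cpp_pack_representation(IntegerMatrix placements, NumericMatrix enc,
                                      int n_records, int K, int eta, int lmax,
                                      int code_dim) {
  const int slab = lmax * code_dim;
  if (enc.ncol() != slab) stop("encoded slab width mismatch");
  NumericMatrix X(n_records, K * eta * slab);
  for (int i = 0; i < placements.nrow(); ++i) {
    const int rec = placements(i, 0) - 1;
    const int g = placements(i, 1) - 1;
    const int s = placements(i, 2) - 1;
    const int id = placements(i, 3) - 1;
    if (rec < 0 || rec >= n_records || g < 0 || g >= K || s < 0 || s >= eta)
      stop("placement index out of range");
    const int off = (g * eta + s) * slab;
    for (int j = 0; j < slab; ++j) X(rec, off + j) = enc(id, j);
  }
  return X;
}
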