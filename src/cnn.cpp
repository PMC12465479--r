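// 2D-CNN engine for hotspot coordinate regression.
//
// Layout conventions:
//  - A trial is an H x W image (H = EEG channels, W = time or PSD bins)
//    with one input channel. Batched feature maps are (H*W*B) x C float
//    matrices: sample b owns row block [b*H*W, (b+1)*H*W), and within a
//    block the spatial index is p = c + r*W (time-major, so im2col and
//    col2im move long contiguous runs).
//  - Convolutions are stride-1 with shape-preserving zero padding, one
//    GEMM per batch over an im2col buffer of shape (H*W*B) x (C*kh*kw).
//  - Max pooling is 2x2, stride 2, ceil semantics with zero padding.
//  - All hidden activations are ReLU; the final dense layer is linear.
// The training loop (ADAM, MSE, patience-based early stopping with
// best-weight restore) runs entirely in C++; the caller supplies the
// weight initialization and per-epoch shuffling orders so that all
// randomness goes through R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::IntegerMatrix;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::stop;

enum LayerType { CONV = 0, POOL = 1, FLATTEN = 2, DENSE = 3 };

struct Layer {
  int type;
  int in_ch, out_ch, kh, kw;
  int in_h, in_w, out_h, out_w;
  int in_len, out_len;
  int act;   // dense only: 1 relu, 0 linear
  int widx;  // index into weight vectors, -1 if none
};

static std::vector<Layer> parse_layers(const List& layers) {
  std::vector<Layer> out;
  int widx = 0;
  for (int i = 0; i < layers.size(); ++i) {
    List li = layers[i];
    Layer L;
    L.type = Rcpp::as<int>(li["type"]);
    L.in_ch = L.out_ch = L.kh = L.kw = 0;
    L.in_h = L.in_w = L.out_h = L.out_w = 0;
    L.in_len = L.out_len = 0;
    L.act = 1;
    L.widx = -1;
    if (L.type == CONV) {
      L.in_ch = Rcpp::as<int>(li["in_ch"]);
      L.out_ch = Rcpp::as<int>(li["out_ch"]);
      L.kh = Rcpp::as<int>(li["kh"]);
      L.kw = Rcpp::as<int>(li["kw"]);
      L.in_h = L.out_h = Rcpp::as<int>(li["in_h"]);
      L.in_w = L.out_w = Rcpp::as<int>(li["in_w"]);
      L.widx = widx++;
    } else if (L.type == POOL) {
      L.in_ch = L.out_ch = Rcpp::as<int>(li["in_ch"]);
      L.in_h = Rcpp::as<int>(li["in_h"]);
      L.in_w = Rcpp::as<int>(li["in_w"]);
      L.out_h = (L.in_h + 1) / 2;
      L.out_w = (L.in_w + 1) / 2;
    } else if (L.type == FLATTEN) {
      L.in_ch = Rcpp::as<int>(li["in_ch"]);
      L.in_h = Rcpp::as<int>(li["in_h"]);
      L.in_w = Rcpp::as<int>(li["in_w"]);
      L.out_len = L.in_ch * L.in_h * L.in_w;
    } else if (L.type == DENSE) {
      L.in_len = Rcpp::as<int>(li["in_len"]);
      L.out_len = Rcpp::as<int>(li["out_len"]);
      L.act = Rcpp::as<int>(li["act"]);
      L.widx = widx++;
    } else stop("unknown layer type");
    out.push_back(L);
  }
  return out;
}

static void parse_weights(const List& weights, const std::vector<Layer>& spec,
                          std::vector<fmat>& Ws, std::vector<fvec>& bs) {
  Ws.clear(); bs.clear();
  for (size_t i = 0; i < spec.size(); ++i) {
    if (spec[i].widx < 0) continue;
    List wi = weights[i];
    NumericMatrix W = wi["W"];
    NumericVector b = wi["b"];
    fmat Wf(W.nrow(), W.ncol());
    for (int c = 0; c < W.ncol(); ++c)
      for (int r = 0; r < W.nrow(); ++r)
        Wf(r, c) = (float)W(r, c);
    fvec bf(b.size());
    for (int k = 0; k < b.size(); ++k) bf(k) = (float)b[k];
    Ws.push_back(Wf);
    bs.push_back(bf);
  }
}

// im2col for sample block b0 of `A` ((HWB) x in_ch) into `cols`
// ((HWB) x in_ch*kh*kw). Column kk = ch + in_ch*(dr + kh*dc) holds, for
// each output position p = c + r*W, the input value at (r+dr-ph, c+dc-pw)
// or zero. For fixed (ch, dr, dc) the source offset is constant along c,
// so inner copies are contiguous runs of length up to W.
static void im2col(const fmat& A, int b0, int H, int W, int in_ch,
                   int kh, int kw, fmat& cols) {
  const int ph = kh / 2, pw = kw / 2, hw = H * W;
  for (int dc = 0; dc < kw; ++dc) {
    const int c0 = std::max(0, pw - dc), c1 = std::min(W, W + pw - dc);
    for (int dr = 0; dr < kh; ++dr) {
      const int r0 = std::max(0, ph - dr), r1 = std::min(H, H + ph - dr);
      const int shift = (dc - pw) + (dr - ph) * W;
      for (int ch = 0; ch < in_ch; ++ch) {
        const int kk = ch + in_ch * (dr + kh * dc);
        float* dst = cols.colptr(kk) + b0;
        const float* src = A.colptr(ch) + b0;
        for (int r = 0; r < H; ++r) {
          float* d = dst + r * W;
          if (r < r0 || r >= r1) { std::memset(d, 0, W * sizeof(float)); continue; }
          if (c0 > 0) std::memset(d, 0, c0 * sizeof(float));
          std::memcpy(d + c0, src + r * W + c0 + shift,
                      (c1 - c0) * sizeof(float));
          if (c1 < W) std::memset(d + c1, 0, (W - c1) * sizeof(float));
        }
      }
    }
  }
}

// Accumulating inverse of im2col.
static void col2im(const fmat& cols, int b0, int H, int W, int in_ch,
                   int kh, int kw, fmat& dA) {
  const int ph = kh / 2, pw = kw / 2;
  for (int dc = 0; dc < kw; ++dc) {
    const int c0 = std::max(0, pw - dc), c1 = std::min(W, W + pw - dc);
    for (int dr = 0; dr < kh; ++dr) {
      const int r0 = std::max(0, ph - dr), r1 = std::min(H, H + ph - dr);
      const int shift = (dc - pw) + (dr - ph) * W;
      for (int ch = 0; ch < in_ch; ++ch) {
        const int kk = ch + in_ch * (dr + kh * dc);
        const float* src = cols.colptr(kk) + b0;
        float* dst = dA.colptr(ch) + b0;
        for (int r = r0; r < r1; ++r) {
          const float* s = src + r * W + c0;
          float* d = dst + r * W + c0 + shift;
          const int len = c1 - c0;
          for (int j = 0; j < len; ++j) d[j] += s[j];
        }
      }
    }
  }
}

struct Workspace {
  std::vector<fmat> acts;    // output of each layer (batched)
  std::vector<fmat> cols;    // im2col buffers for conv layers
  std::vector<fmat> dacts;   // gradient w.r.t. each layer's input
  std::vector<fmat> dcols;   // scratch for conv input gradients
  std::vector<Mat<int>> poolidx;
  fmat input;
  int B = -1;
};

// Workspaces are cached per batch size so no large buffer is reallocated
// after the first epoch.
struct WorkspaceCache {
  std::map<int, Workspace> by_B;
  Workspace& get(const std::vector<Layer>& spec, int B, bool grad) {
    Workspace& ws = by_B[B];
    if (ws.B == B) return ws;
    ws.B = B;
    ws.acts.assign(spec.size(), fmat());
    ws.cols.assign(spec.size(), fmat());
    ws.dacts.assign(spec.size(), fmat());
    ws.dcols.assign(spec.size(), fmat());
    ws.poolidx.assign(spec.size(), Mat<int>());
    for (size_t i = 0; i < spec.size(); ++i) {
      const Layer& L = spec[i];
      if (L.type == CONV) {
        ws.acts[i].set_size(L.out_h * L.out_w * B, L.out_ch);
        ws.cols[i].set_size(L.in_h * L.in_w * B, L.in_ch * L.kh * L.kw);
        if (grad && i > 0) {
          ws.dacts[i].set_size(L.in_h * L.in_w * B, L.in_ch);
          ws.dcols[i].set_size(L.in_h * L.in_w * B, L.in_ch * L.kh * L.kw);
        }
      } else if (L.type == POOL) {
        ws.acts[i].set_size(L.out_h * L.out_w * B, L.out_ch);
        ws.poolidx[i].set_size(L.out_h * L.out_w * B, L.out_ch);
        if (grad) ws.dacts[i].set_size(L.in_h * L.in_w * B, L.in_ch);
      } else if (L.type == FLATTEN) {
        ws.acts[i].set_size(L.out_len, B);
        if (grad) ws.dacts[i].set_size(L.in_h * L.in_w * B, L.in_ch);
      } else {
        ws.acts[i].set_size(L.out_len, B);
        if (grad) ws.dacts[i].set_size(L.in_len, B);
      }
    }
    ws.input.set_size((uword)spec[0].in_h * spec[0].in_w * B, 1);
    return ws;
  }
};

static inline void relu_inplace(fmat& x) {
  float* p = x.memptr();
  const uword n = x.n_elem;
  for (uword i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

// Forward pass over a batch already in ws.input ((HWB) x 1).
static const fmat& forward(const std::vector<Layer>& spec,
                           const std::vector<fmat>& Ws,
                           const std::vector<fvec>& bs,
                           Workspace& ws, int B) {
  const fmat* cur = &ws.input;
  for (size_t i = 0; i < spec.size(); ++i) {
    const Layer& L = spec[i];
    fmat& out = ws.acts[i];
    if (L.type == CONV) {
      const int hw = L.in_h * L.in_w;
      for (int b = 0; b < B; ++b)
        im2col(*cur, b * hw, L.in_h, L.in_w, L.in_ch, L.kh, L.kw, ws.cols[i]);
      out = ws.cols[i] * Ws[L.widx].t();
      out.each_row() += bs[L.widx].t();
      relu_inplace(out);
    } else if (L.type == POOL) {
      const int hw = L.in_h * L.in_w, ohw = L.out_h * L.out_w;
      const int H = L.in_h, W = L.in_w, OW = L.out_w, OH = L.out_h;
      for (int ch = 0; ch < L.in_ch; ++ch) {
        const float* src = cur->colptr(ch);
        float* dst = out.colptr(ch);
        int* idst = ws.poolidx[i].colptr(ch);
        for (int b = 0; b < B; ++b) {
          const int so = b * hw, oo = b * ohw;
          for (int orr = 0; orr < OH; ++orr) {
            for (int oc = 0; oc < OW; ++oc) {
              float m = 0.0f; int mi = -1;
              for (int dr = 0; dr < 2; ++dr) {
                const int sr = 2 * orr + dr;
                if (sr >= H) continue;
                for (int dc = 0; dc < 2; ++dc) {
                  const int sc = 2 * oc + dc;
                  if (sc >= W) continue;
                  const int sp = so + sc + sr * W;
                  if (src[sp] > m) { m = src[sp]; mi = sp; }
                }
              }
              dst[oo + oc + orr * OW] = m;
              idst[oo + oc + orr * OW] = mi;
            }
          }
        }
      }
    } else if (L.type == FLATTEN) {
      const int hw = L.in_h * L.in_w;
      for (int b = 0; b < B; ++b)
        out.col(b) = vectorise(cur->rows(b * hw, (b + 1) * hw - 1));
    } else {  // DENSE
      out = Ws[L.widx] * (*cur);
      out.each_col() += bs[L.widx];
      if (L.act == 1) relu_inplace(out);
    }
    cur = &out;
  }
  return *cur;
}

static inline void relu_mask(fmat& delta, const fmat& act) {
  float* d = delta.memptr();
  const float* a = act.memptr();
  const uword n = delta.n_elem;
  for (uword i = 0; i < n; ++i) if (a[i] <= 0.0f) d[i] = 0.0f;
}

// Backward pass; fills gWs/gbs. `delta0` is dLoss/dOutput of the last
// layer; per-layer input gradients live in preallocated ws.dacts buffers.
static void backward(const std::vector<Layer>& spec,
                     const std::vector<fmat>& Ws, Workspace& ws, int B,
                     fmat delta0, std::vector<fmat>& gWs,
                     std::vector<fvec>& gbs) {
  fmat* delta = &delta0;
  for (int i = (int)spec.size() - 1; i >= 0; --i) {
    const Layer& L = spec[i];
    const fmat& out = ws.acts[i];
    const fmat& in = (i == 0) ? ws.input : ws.acts[i - 1];
    if (L.type == DENSE) {
      if (L.act == 1) relu_mask(*delta, out);
      gWs[L.widx] = (*delta) * in.t();
      gbs[L.widx] = sum(*delta, 1);
      if (i > 0) {
        ws.dacts[i] = Ws[L.widx].t() * (*delta);
        delta = &ws.dacts[i];
      }
    } else if (L.type == FLATTEN) {
      const int hw = L.in_h * L.in_w;
      fmat& d = ws.dacts[i];
      for (int b = 0; b < B; ++b) {
        const float* s = delta->colptr(b);
        for (int ch = 0; ch < L.in_ch; ++ch)
          std::memcpy(d.colptr(ch) + b * hw, s + ch * hw,
                      hw * sizeof(float));
      }
      delta = &d;
    } else if (L.type == POOL) {
      const int hw = L.in_h * L.in_w, ohw = L.out_h * L.out_w;
      fmat& d = ws.dacts[i];
      d.zeros();
      for (int ch = 0; ch < L.in_ch; ++ch) {
        const float* sd = delta->colptr(ch);
        const int* idx = ws.poolidx[i].colptr(ch);
        float* dd = d.colptr(ch);
        const int n = ohw * B;
        for (int op = 0; op < n; ++op)
          if (idx[op] >= 0) dd[idx[op]] += sd[op];
      }
      delta = &d;
    } else {  // CONV (ReLU)
      relu_mask(*delta, out);
      gWs[L.widx] = delta->t() * ws.cols[i];
      gbs[L.widx] = sum(*delta, 0).t();
      if (i > 0) {
        ws.dcols[i] = (*delta) * Ws[L.widx];
        const int hw = L.in_h * L.in_w;
        fmat& d = ws.dacts[i];
        d.zeros();
        for (int b = 0; b < B; ++b)
          col2im(ws.dcols[i], b * hw, L.in_h, L.in_w, L.in_ch, L.kh, L.kw, d);
        delta = &d;
      }
    }
  }
}

// Copy samples `idx` (0-based) of the (N, H, W) array into ws.input,
// time-major within each sample block.
static void fill_input(const double* x, int N, int H, int W,
                       const std::vector<int>& idx, Workspace& ws) {
  const int hw = H * W;
  if (ws.input.n_elem != (uword)hw * idx.size())
    ws.input.set_size((uword)hw * idx.size(), 1);
  float* dst0 = ws.input.memptr();
  for (size_t b = 0; b < idx.size(); ++b) {
    float* dst = dst0 + b * hw;
    const double* src = x + idx[b];
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c)
        dst[c + r * W] = (float)src[(R_xlen_t)N * (r + H * c)];
  }
}

static double mse_loss(const fmat& pred, const fmat& y) {
  return accu(square(pred - y)) / (double)pred.n_elem;
}

static List export_weights(const std::vector<Layer>& spec,
                           const std::vector<fmat>& Ws,
                           const std::vector<fvec>& bs) {
  List out(spec.size());
  for (size_t i = 0; i < spec.size(); ++i) {
    if (spec[i].widx < 0) { out[i] = R_NilValue; continue; }
    const fmat& W = Ws[spec[i].widx];
    const fvec& b = bs[spec[i].widx];
    NumericMatrix Wr(W.n_rows, W.n_cols);
    for (uword c = 0; c < W.n_cols; ++c)
      for (uword r = 0; r < W.n_rows; ++r) Wr(r, c) = W(r, c);
    NumericVector br(b.n_elem);
    for (uword k = 0; k < b.n_elem; ++k) br[k] = b(k);
    out[i] = List::create(Rcpp::Named("W") = Wr, Rcpp::Named("b") = br);
  }
  return out;
}

static fmat targets_for(const NumericMatrix& y, const std::vector<int>& idx) {
  fmat out(y.ncol(), idx.size());
  for (size_t b = 0; b < idx.size(); ++b)
    for (int k = 0; k < y.ncol(); ++k) out(k, b) = (float)y(idx[b], k);
  return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(List layers, List weights0, NumericVector x_train,
                   NumericMatrix y_train, NumericVector x_val,
                   NumericMatrix y_val, IntegerMatrix orders, double lr,
                   int batch_size, int max_epochs, int patience) {
  std::vector<Layer> spec = parse_layers(layers);
  std::vector<fmat> Ws; std::vector<fvec> bs;
  parse_weights(weights0, spec, Ws, bs);

  Rcpp::IntegerVector xd = x_train.attr("dim");
  const int N = xd[0], H = xd[1], W = xd[2];
  Rcpp::IntegerVector xvd = x_val.attr("dim");
  const int Nv = xvd[0];
  if (xvd[1] != H || xvd[2] != W) stop("validation shape mismatch");

  std::vector<fmat> mW(Ws.size()), vW(Ws.size()), gWs(Ws.size());
  std::vector<fvec> mb(bs.size()), vb(bs.size()), gbs(bs.size());
  for (size_t k = 0; k < Ws.size(); ++k) {
    mW[k].zeros(Ws[k].n_rows, Ws[k].n_cols);
    vW[k].zeros(Ws[k].n_rows, Ws[k].n_cols);
    mb[k].zeros(bs[k].n_elem);
    vb[k].zeros(bs[k].n_elem);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long tstep = 0;

  WorkspaceCache wcache, wvcache;
  std::vector<double> hist_train, hist_val;
  double best_val = std::numeric_limits<double>::infinity();
  std::vector<fmat> bestW = Ws;
  std::vector<fvec> bestb = bs;
  int best_epoch = 0, wait = 0, stopped_epoch = max_epochs;

  auto eval_val = [&]() {
    double sse = 0.0; long nel = 0;
    const int chunk = batch_size > 16 ? batch_size : 16;
    for (int s = 0; s < Nv; s += chunk) {
      std::vector<int> idx;
      for (int j = s; j < std::min(Nv, s + chunk); ++j) idx.push_back(j);
      Workspace& wsv = wvcache.get(spec, (int)idx.size(), false);
      fill_input(x_val.begin(), Nv, H, W, idx, wsv);
      const fmat& pred = forward(spec, Ws, bs, wsv, (int)idx.size());
      fmat yb = targets_for(y_val, idx);
      sse += accu(square(pred - yb));
      nel += pred.n_elem;
    }
    return sse / (double)nel;
  };

  int epoch = 0;
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    double tr_loss = 0.0;
    int n_batches = 0;
    for (int s = 0; s < N; s += batch_size) {
      std::vector<int> idx;
      for (int j = s; j < std::min(N, s + batch_size); ++j)
        idx.push_back(orders(epoch - 1, j) - 1);
      const int B = (int)idx.size();
      Workspace& ws = wcache.get(spec, B, true);
      fill_input(x_train.begin(), N, H, W, idx, ws);
      const fmat& pred = forward(spec, Ws, bs, ws, B);
      fmat yb = targets_for(y_train, idx);
      const double loss = mse_loss(pred, yb);
      if (!std::isfinite(loss))
        stop("non-finite training loss at epoch %d; check that inputs are standardized",
             epoch);
      tr_loss += loss; ++n_batches;

      fmat delta = (pred - yb) * (2.0f / (float)pred.n_elem);
      backward(spec, Ws, ws, B, delta, gWs, gbs);

      ++tstep;
      const float c1 = 1.0f - std::pow(b1, (float)tstep);
      const float c2 = 1.0f - std::pow(b2, (float)tstep);
      auto adam_step = [&](float* w, float* m, float* v, const float* g,
                           uword n) {
        const float flr = (float)lr;
        for (uword j = 0; j < n; ++j) {
          m[j] = b1 * m[j] + (1.0f - b1) * g[j];
          v[j] = b2 * v[j] + (1.0f - b2) * g[j] * g[j];
          w[j] -= flr * (m[j] / c1) / (std::sqrt(v[j] / c2) + eps);
        }
      };
      for (size_t k = 0; k < Ws.size(); ++k) {
        adam_step(Ws[k].memptr(), mW[k].memptr(), vW[k].memptr(),
                  gWs[k].memptr(), Ws[k].n_elem);
        adam_step(bs[k].memptr(), mb[k].memptr(), vb[k].memptr(),
                  gbs[k].memptr(), bs[k].n_elem);
      }
    }
    hist_train.push_back(tr_loss / n_batches);
    const double vl = eval_val();
    hist_val.push_back(vl);
    if (vl < best_val) {
      best_val = vl; best_epoch = epoch; wait = 0;
      bestW = Ws; bestb = bs;
    } else if (++wait >= patience) {
      stopped_epoch = epoch;
      break;
    }
    if (epoch % 10 == 0) Rcpp::checkUserInterrupt();
  }
  if (epoch > max_epochs) stopped_epoch = max_epochs;

  return List::create(
    Rcpp::Named("weights") = export_weights(spec, bestW, bestb),
    Rcpp::Named("train_loss") = hist_train,
    Rcpp::Named("val_loss") = hist_val,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_loss") = best_val,
    Rcpp::Named("stopped_epoch") = stopped_epoch);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(List layers, List weights, NumericVector x) {
  std::vector<Layer> spec = parse_layers(layers);
  std::vector<fmat> Ws; std::vector<fvec> bs;
  parse_weights(weights, spec, Ws, bs);
  Rcpp::IntegerVector xd = x.attr("dim");
  const int N = xd[0], H = xd[1], W = xd[2];
  const int out_len = spec.back().out_len;
  NumericMatrix out(N, out_len);
  WorkspaceCache wcache;
  const int chunk = 32;
  for (int s = 0; s < N; s += chunk) {
    std::vector<int> idx;
    for (int j = s; j < std::min(N, s + chunk); ++j) idx.push_back(j);
    Workspace& ws = wcache.get(spec, (int)idx.size(), false);
    fill_input(x.begin(), N, H, W, idx, ws);
    const fmat& pred = forward(spec, Ws, bs, ws, (int)idx.size());
    for (size_t b = 0; b < idx.size(); ++b)
      for (int k = 0; k < out_len; ++k) out(idx[b], k) = pred(k, b);
  }
  return out;
}
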