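// Minimal CNN engine for 2-class patch classification.
//
// Internal layout: spatial activations are stored channels-fastest, as
// (C x HW*B) matrices whose column (b*HW + x*h + y) holds all channels of
// pixel (x, y) of sample b. With this layout im2col is a sequence of
// C-sized memcpy blocks, the conv GEMM output (K x P*B) is already in
// layout, and flatten is a free reinterpretation to (C*HW x B). Dense
// activations are (features x B).
//
//  * convolutions are 3x3 (valid or zero-padded 'same'), ReLU;
//  * max pools are 2x2 stride 2 (odd trailing rows/cols dropped);
//  * dense layers are ReLU, the output layer is softmax over 2 classes.
//
// All randomness (init, shuffling, dropout, augmentation) comes from one
// mt19937 stream with hand-rolled draws, so results are reproducible
// across platforms for a fixed seed.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

enum LayerType { CONV_VALID = 0, CONV_SAME = 1, POOL = 2, FLATTEN = 3,
                 DENSE = 4, DENSE_SOFTMAX = 5, DROPOUT = 6 };

struct LayerDef {
  int type;
  int in_h, in_w, in_c;
  int out_h, out_w, out_c;
  int units;
  bool trainable;
  int in_feat() const { return in_h * in_w * in_c; }
  int out_feat() const { return out_h * out_w * out_c; }
};

static std::vector<LayerDef> parse_defs(const IntegerMatrix& L) {
  std::vector<LayerDef> defs(L.nrow());
  for (int i = 0; i < L.nrow(); ++i) {
    defs[i].type = L(i, 0);
    defs[i].in_h = L(i, 1); defs[i].in_w = L(i, 2); defs[i].in_c = L(i, 3);
    defs[i].out_h = L(i, 4); defs[i].out_w = L(i, 5); defs[i].out_c = L(i, 6);
    defs[i].units = L(i, 7);
    defs[i].trainable = L(i, 8) != 0;
  }
  return defs;
}

// ---------------------------------------------------------------- RNG ----
// mt19937 raw output is standardized; distributions are hand-rolled so the
// stream is identical on every platform.
struct Rng {
  std::mt19937 eng;
  explicit Rng(uint32_t seed) : eng(seed) {}
  double unif() { return (eng() + 0.5) * (1.0 / 4294967296.0); }
  double gauss() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int below(int n) { return static_cast<int>(eng() % static_cast<uint32_t>(n)); }
  void shuffle(std::vector<int>& v) {
    for (int i = static_cast<int>(v.size()) - 1; i > 0; --i)
      std::swap(v[i], v[below(i + 1)]);
  }
};

static inline void relu_mask_inplace(fmat& delta, const fmat& act) {
  const float* a = act.memptr();
  float* d = delta.memptr();
  const arma::uword n = delta.n_elem;
  for (arma::uword k = 0; k < n; ++k)
    if (a[k] <= 0.0f) d[k] = 0.0f;
}

// ---------------------------------------------------------- im2col ------
// cols rows are ordered (kx*3 + ky)*C + c; one memcpy of C floats per
// kernel tap per output position.
static void im2col_batch(const fmat& in, const LayerDef& d, int B,
                         fmat& cols) {
  const bool same = d.type == CONV_SAME;
  const int off = same ? -1 : 0;
  const int h = d.in_h, w = d.in_w, C = d.in_c;
  const int oh = d.out_h, ow = d.out_w;
  const size_t HW = static_cast<size_t>(h) * w;
  const size_t P = static_cast<size_t>(oh) * ow;
  for (int b = 0; b < B; ++b) {
    const float* base = in.colptr(b * HW);
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        float* dst = cols.colptr(b * P + static_cast<size_t>(ox) * oh + oy);
        for (int kx = 0; kx < 3; ++kx) {
          const int ix = ox + kx + off;
          for (int ky = 0; ky < 3; ++ky) {
            const int iy = oy + ky + off;
            float* d9 = dst + (kx * 3 + ky) * C;
            if (ix < 0 || ix >= w || iy < 0 || iy >= h)
              std::memset(d9, 0, sizeof(float) * C);
            else
              std::memcpy(d9, base + (static_cast<size_t>(ix) * h + iy) * C,
                          sizeof(float) * C);
          }
        }
      }
    }
  }
}

static void col2im_batch(const fmat& dcols, const LayerDef& d, int B,
                         fmat& dx) {
  const bool same = d.type == CONV_SAME;
  const int off = same ? -1 : 0;
  const int h = d.in_h, w = d.in_w, C = d.in_c;
  const int oh = d.out_h, ow = d.out_w;
  const size_t HW = static_cast<size_t>(h) * w;
  const size_t P = static_cast<size_t>(oh) * ow;
  dx.zeros(C, HW * B);
  for (int b = 0; b < B; ++b) {
    float* base = dx.colptr(b * HW);
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const float* src = dcols.colptr(b * P + static_cast<size_t>(ox) * oh + oy);
        for (int kx = 0; kx < 3; ++kx) {
          const int ix = ox + kx + off;
          if (ix < 0 || ix >= w) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int iy = oy + ky + off;
            if (iy < 0 || iy >= h) continue;
            float* dst = base + (static_cast<size_t>(ix) * h + iy) * C;
            const float* s9 = src + (kx * 3 + ky) * C;
            for (int c = 0; c < C; ++c) dst[c] += s9[c];
          }
        }
      }
    }
  }
}

// ------------------------------------------------------------ forward ---
struct BatchCache {
  std::vector<fmat> act;    // layer outputs (spatial or flat layout)
  std::vector<fmat> cols;   // im2col matrices for conv layers
  std::vector<std::vector<unsigned char>> pidx;  // pool argmax (0..3)
  std::vector<fmat> mask;   // dropout masks
};

static void forward(const std::vector<LayerDef>& defs,
                    const std::vector<fmat>& W, const std::vector<fvec>& b,
                    const fmat& input, int B, bool training, double drop_rate,
                    Rng* rng, BatchCache& C, bool keep_cache) {
  const int n_layers = static_cast<int>(defs.size());
  C.act.assign(n_layers, fmat());
  C.cols.assign(n_layers, fmat());
  C.pidx.assign(n_layers, std::vector<unsigned char>());
  C.mask.assign(n_layers, fmat());
  const fmat* x = &input;
  for (int i = 0; i < n_layers; ++i) {
    const LayerDef& d = defs[i];
    if (d.type == CONV_VALID || d.type == CONV_SAME) {
      const size_t P = static_cast<size_t>(d.out_h) * d.out_w;
      fmat cols(9 * d.in_c, P * B);
      im2col_batch(*x, d, B, cols);
      fmat out = W[i] * cols;            // K x P*B, already in layout
      out.each_col() += b[i];
      float* o = out.memptr();
      for (arma::uword k = 0; k < out.n_elem; ++k)
        if (o[k] < 0.0f) o[k] = 0.0f;
      if (keep_cache) C.cols[i] = std::move(cols);
      C.act[i] = std::move(out);
    } else if (d.type == POOL) {
      const int h = d.in_h, C_ch = d.in_c;
      const size_t HWi = static_cast<size_t>(d.in_h) * d.in_w;
      const size_t HWo = static_cast<size_t>(d.out_h) * d.out_w;
      fmat out(C_ch, HWo * B);
      std::vector<unsigned char> idx;
      if (keep_cache) idx.resize(static_cast<size_t>(C_ch) * HWo * B);
      for (int b2 = 0; b2 < B; ++b2) {
        const float* in0 = x->colptr(b2 * HWi);
        for (int ox = 0; ox < d.out_w; ++ox) {
          for (int oy = 0; oy < d.out_h; ++oy) {
            const size_t s00 = (static_cast<size_t>(2 * ox) * h + 2 * oy) * C_ch;
            const float* p0 = in0 + s00;            // (2ox, 2oy)
            const float* p1 = p0 + C_ch;            // (2ox, 2oy+1)
            const float* p2 = p0 + static_cast<size_t>(h) * C_ch;  // (2ox+1, 2oy)
            const float* p3 = p2 + C_ch;
            const size_t oc = b2 * HWo + static_cast<size_t>(ox) * d.out_h + oy;
            float* po = out.colptr(oc);
            unsigned char* pi = keep_cache ? idx.data() + oc * C_ch : nullptr;
            for (int c = 0; c < C_ch; ++c) {
              float best = p0[c]; unsigned char wi = 0;
              if (p1[c] > best) { best = p1[c]; wi = 1; }
              if (p2[c] > best) { best = p2[c]; wi = 2; }
              if (p3[c] > best) { best = p3[c]; wi = 3; }
              po[c] = best;
              if (pi) pi[c] = wi;
            }
          }
        }
      }
      C.act[i] = std::move(out);
      if (keep_cache) C.pidx[i] = std::move(idx);
    } else if (d.type == FLATTEN) {
      // memory of each sample is already contiguous: reinterpret
      C.act[i] = fmat(const_cast<float*>(x->memptr()), d.out_feat(), B,
                      true, true);
    } else if (d.type == DENSE || d.type == DENSE_SOFTMAX) {
      fmat out = W[i] * (*x);
      out.each_col() += b[i];
      if (d.type == DENSE) {
        float* o = out.memptr();
        for (arma::uword k = 0; k < out.n_elem; ++k)
          if (o[k] < 0.0f) o[k] = 0.0f;
      } else {
        for (int bi = 0; bi < B; ++bi) {
          fvec c = out.col(bi);
          c -= c.max();
          c = arma::exp(c);
          out.col(bi) = c / arma::accu(c);
        }
      }
      C.act[i] = std::move(out);
    } else if (d.type == DROPOUT) {
      if (training && drop_rate > 0.0) {
        fmat mask(x->n_rows, x->n_cols);
        const float scale = 1.0f / (1.0f - static_cast<float>(drop_rate));
        for (arma::uword k = 0; k < mask.n_elem; ++k)
          mask(k) = rng->unif() >= drop_rate ? scale : 0.0f;
        C.act[i] = (*x) % mask;
        if (keep_cache) C.mask[i] = std::move(mask);
      } else {
        C.act[i] = *x;
      }
    } else {
      stop("unknown layer type %d", d.type);
    }
    x = &C.act[i];
  }
}

// input activation feeding layer i (only needed for dense layers, whose
// input is always flat; the shape chain guarantees a preceding layer)
static const fmat& C_act_in(const std::vector<LayerDef>& defs,
                            const BatchCache& C, int i) {
  (void)defs;
  return C.act[i - 1];
}

// ----------------------------------------------------------- backward ---
// Assumes forward() ran with keep_cache = true. `first_grad` is the lowest
// layer index whose parameters need gradients; backprop stops below it.
static void backward(const std::vector<LayerDef>& defs,
                     const std::vector<fmat>& W,
                     const IntegerVector& y,
                     const std::vector<int>& batch_idx,
                     const BatchCache& C, int first_grad,
                     std::vector<fmat>& dW, std::vector<fvec>& db) {
  const int n_layers = static_cast<int>(defs.size());
  const int B = static_cast<int>(batch_idx.size());
  dW.assign(n_layers, fmat());
  db.assign(n_layers, fvec());

  // softmax + cross-entropy gradient
  fmat delta = C.act[n_layers - 1];
  for (int bi = 0; bi < B; ++bi)
    delta(y[batch_idx[bi]], bi) -= 1.0f;
  delta /= static_cast<float>(B);

  for (int i = n_layers - 1; i >= first_grad; --i) {
    const LayerDef& d = defs[i];
    const bool need_dx = i > first_grad;
    if (d.type == DENSE || d.type == DENSE_SOFTMAX) {
      if (d.type == DENSE) relu_mask_inplace(delta, C.act[i]);
      if (d.trainable) {
        dW[i] = delta * C_act_in(defs, C, i).t();
        db[i] = arma::sum(delta, 1);
      }
      if (need_dx) delta = W[i].t() * delta;
    } else if (d.type == DROPOUT) {
      if (C.mask[i].n_elem > 0) delta %= C.mask[i];
    } else if (d.type == FLATTEN) {
      // reinterpret (feat x B) back to the spatial (C x HW*B) layout
      delta = fmat(delta.memptr(), d.in_c,
                   static_cast<size_t>(d.in_h) * d.in_w * B, true, true);
    } else if (d.type == POOL) {
      const int h = d.in_h, C_ch = d.in_c;
      const size_t HWi = static_cast<size_t>(d.in_h) * d.in_w;
      const size_t HWo = static_cast<size_t>(d.out_h) * d.out_w;
      fmat dx(C_ch, HWi * B, arma::fill::zeros);
      const std::vector<unsigned char>& idx = C.pidx[i];
      for (int b2 = 0; b2 < B; ++b2) {
        float* out0 = dx.colptr(b2 * HWi);
        for (int ox = 0; ox < d.out_w; ++ox) {
          for (int oy = 0; oy < d.out_h; ++oy) {
            const size_t oc = b2 * HWo + static_cast<size_t>(ox) * d.out_h + oy;
            const float* dl = delta.colptr(oc);
            const unsigned char* pi = idx.data() + oc * C_ch;
            const size_t s00 = (static_cast<size_t>(2 * ox) * h + 2 * oy) * C_ch;
            for (int c = 0; c < C_ch; ++c) {
              size_t off = s00 + c;
              switch (pi[c]) {
                case 1: off += C_ch; break;
                case 2: off += static_cast<size_t>(h) * C_ch; break;
                case 3: off += static_cast<size_t>(h) * C_ch + C_ch; break;
                default: break;
              }
              out0[off] += dl[c];
            }
          }
        }
      }
      delta = std::move(dx);
    } else {  // conv
      relu_mask_inplace(delta, C.act[i]);
      if (d.trainable) {
        dW[i] = delta * C.cols[i].t();
        db[i] = arma::sum(delta, 1);
      }
      if (need_dx) {
        fmat dcols = W[i].t() * delta;  // 9*in_c x P*B
        fmat dx;
        col2im_batch(dcols, d, B, dx);
        delta = std::move(dx);
      }
    }
  }
}

// ------------------------------------------------- weights conversion ---
static void weights_from_r(const List& weights, const std::vector<LayerDef>& defs,
                           std::vector<fmat>& W, std::vector<fvec>& b) {
  const int n = static_cast<int>(defs.size());
  W.assign(n, fmat());
  b.assign(n, fvec());
  for (int i = 0; i < n; ++i) {
    if (Rf_isNull(weights[i])) continue;
    List wi = weights[i];
    NumericMatrix Wm = wi["W"];
    NumericVector bv = wi["b"];
    W[i] = arma::conv_to<fmat>::from(
      arma::mat(Wm.begin(), Wm.nrow(), Wm.ncol(), false));
    b[i] = arma::conv_to<fvec>::from(
      arma::vec(bv.begin(), bv.size(), false));
  }
}

static List weights_to_r(const std::vector<LayerDef>& defs,
                         const std::vector<fmat>& W,
                         const std::vector<fvec>& b) {
  const int n = static_cast<int>(defs.size());
  List out(n);
  for (int i = 0; i < n; ++i) {
    if (W[i].n_elem == 0) { out[i] = R_NilValue; continue; }
    NumericMatrix Wm(W[i].n_rows, W[i].n_cols);
    std::copy(W[i].begin(), W[i].end(), Wm.begin());
    NumericVector bv(b[i].n_elem);
    std::copy(b[i].begin(), b[i].end(), bv.begin());
    out[i] = List::create(Named("W") = Wm, Named("b") = bv);
  }
  return out;
}

// ----------------------------------------------------- input assembly ---
// X holds one column per sample; rows are either h*w (grayscale, replicated
// to in_c channels here) or h*w*in_c channel blocks. Output is the spatial
// (C x hw*B) layout. Augmentation applies one random dihedral transform per
// sample, identically to every channel.
static void assemble_input(const fmat& X, const std::vector<int>& idx,
                           const LayerDef& d0, bool augment, Rng* rng,
                           fmat& out) {
  const int h = d0.in_h, w = d0.in_w, C = d0.in_c;
  const size_t hw = static_cast<size_t>(h) * w;
  const bool gray = X.n_rows == hw;
  const int B = static_cast<int>(idx.size());
  out.set_size(C, hw * B);
  fmat T;
  for (int bi = 0; bi < B; ++bi) {
    int rot = 0; bool hf = false, vf = false;
    if (augment) {
      rot = rng->below(4);
      hf = rng->unif() < 0.5;
      vf = rng->unif() < 0.5;
    }
    float* ob = out.colptr(static_cast<size_t>(bi) * hw);
    const int n_src = gray ? 1 : C;
    for (int ch = 0; ch < n_src; ++ch) {
      fmat M(const_cast<float*>(X.colptr(idx[bi])) + ch * hw, h, w,
             false, true);
      T = M;
      for (int k = 0; k < rot; ++k) T = arma::flipud(T).t();  // 90 deg cw
      if (hf) T = arma::fliplr(T);
      if (vf) T = arma::flipud(T);
      const float* tp = T.memptr();
      if (gray) {
        for (size_t s = 0; s < hw; ++s) {
          float* oc = ob + s * C;
          for (int c = 0; c < C; ++c) oc[c] = tp[s];
        }
      } else {
        for (size_t s = 0; s < hw; ++s) ob[s * C + ch] = tp[s];
      }
    }
  }
}

static int first_trainable(const std::vector<LayerDef>& defs) {
  for (size_t i = 0; i < defs.size(); ++i)
    if (defs[i].trainable &&
        (defs[i].type == CONV_VALID || defs[i].type == CONV_SAME ||
         defs[i].type == DENSE || defs[i].type == DENSE_SOFTMAX))
      return static_cast<int>(i);
  return static_cast<int>(defs.size());
}

// ------------------------------------------------------------ exports ---

// [[Rcpp::export]]
List cnn_init_cpp(IntegerMatrix layer_defs, int seed) {
  std::vector<LayerDef> defs = parse_defs(layer_defs);
  Rng rng(static_cast<uint32_t>(seed));
  const int n = static_cast<int>(defs.size());
  std::vector<fmat> W(n);
  std::vector<fvec> b(n);
  for (int i = 0; i < n; ++i) {
    const LayerDef& d = defs[i];
    int rows = 0, cols = 0;
    double sd = 0.0;
    if (d.type == CONV_VALID || d.type == CONV_SAME) {
      rows = d.out_c; cols = 9 * d.in_c;
      sd = std::sqrt(2.0 / cols);                       // He (ReLU)
    } else if (d.type == DENSE || d.type == DENSE_SOFTMAX) {
      rows = d.units; cols = d.in_feat();
      sd = d.type == DENSE ? std::sqrt(2.0 / cols) : std::sqrt(1.0 / cols);
    } else {
      continue;
    }
    W[i].set_size(rows, cols);
    for (arma::uword k = 0; k < W[i].n_elem; ++k)
      W[i](k) = static_cast<float>(sd * rng.gauss());
    b[i].zeros(rows);
  }
  return weights_to_r(defs, W, b);
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, IntegerMatrix layer_defs, NumericMatrix X,
                   IntegerVector y, List hyper) {
  std::vector<LayerDef> defs = parse_defs(layer_defs);
  std::vector<fmat> W;
  std::vector<fvec> b;
  weights_from_r(weights, defs, W, b);

  const double lr = as<double>(hyper["learning_rate"]);
  const double beta1 = as<double>(hyper["beta1"]);
  const double beta2 = as<double>(hyper["beta2"]);
  const int batch = as<int>(hyper["batch_size"]);
  const int epochs = as<int>(hyper["epochs"]);
  const double drop = as<double>(hyper["dropout_rate"]);
  const bool augment = as<bool>(hyper["augment"]);
  Rng rng(static_cast<uint32_t>(as<int>(hyper["seed"])));

  const int N = X.ncol();
  fmat Xf = arma::conv_to<fmat>::from(
    arma::mat(X.begin(), X.nrow(), N, false));

  const int n_layers = static_cast<int>(defs.size());
  const int fg = first_trainable(defs);
  std::vector<fmat> mW(n_layers), vW(n_layers);
  std::vector<fvec> mb(n_layers), vb(n_layers);
  for (int i = 0; i < n_layers; ++i) {
    if (W[i].n_elem == 0 || !defs[i].trainable) continue;
    mW[i].zeros(W[i].n_rows, W[i].n_cols);
    vW[i].zeros(W[i].n_rows, W[i].n_cols);
    mb[i].zeros(b[i].n_elem);
    vb[i].zeros(b[i].n_elem);
  }

  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;
  NumericVector loss_hist(epochs), acc_hist(epochs);
  long step = 0;
  BatchCache C;
  fmat input;
  std::vector<fmat> dW;
  std::vector<fvec> db;

  for (int ep = 0; ep < epochs; ++ep) {
    rng.shuffle(perm);
    double loss_sum = 0.0;
    int correct = 0;
    for (int start = 0; start < N; start += batch) {
      const int stop_i = std::min(start + batch, N);
      std::vector<int> idx(perm.begin() + start, perm.begin() + stop_i);
      const int B = static_cast<int>(idx.size());
      assemble_input(Xf, idx, defs[0], augment, &rng, input);
      forward(defs, W, b, input, B, true, drop, &rng, C, true);
      const fmat& probs = C.act[n_layers - 1];
      for (int bi = 0; bi < B; ++bi) {
        const float p = std::max(probs(y[idx[bi]], bi), 1e-12f);
        loss_sum += -std::log(static_cast<double>(p));
        const int pred = probs(1, bi) > probs(0, bi) ? 1 : 0;
        if (pred == y[idx[bi]]) ++correct;
      }
      backward(defs, W, y, idx, C, fg, dW, db);
      ++step;
      const float fb1 = static_cast<float>(beta1);
      const float fb2 = static_cast<float>(beta2);
      const float flr = static_cast<float>(lr);
      const float bc1 =
        static_cast<float>(1.0 - std::pow(beta1, static_cast<double>(step)));
      const float bc2 =
        static_cast<float>(1.0 - std::pow(beta2, static_cast<double>(step)));
      for (int i = fg; i < n_layers; ++i) {
        if (dW[i].n_elem == 0) continue;
        mW[i] = fb1 * mW[i] + (1.0f - fb1) * dW[i];
        vW[i] = fb2 * vW[i] + (1.0f - fb2) * arma::square(dW[i]);
        W[i] -= flr * (mW[i] / bc1) / (arma::sqrt(vW[i] / bc2) + 1e-8f);
        mb[i] = fb1 * mb[i] + (1.0f - fb1) * db[i];
        vb[i] = fb2 * vb[i] + (1.0f - fb2) * arma::square(db[i]);
        b[i] -= flr * (mb[i] / bc1) / (arma::sqrt(vb[i] / bc2) + 1e-8f);
      }
    }
    loss_hist[ep] = loss_sum / N;
    acc_hist[ep] = static_cast<double>(correct) / N;
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("weights") = weights_to_r(defs, W, b),
                      Named("loss") = loss_hist,
                      Named("accuracy") = acc_hist);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(List weights, IntegerMatrix layer_defs,
                              NumericMatrix X, int batch = 64) {
  std::vector<LayerDef> defs = parse_defs(layer_defs);
  std::vector<fmat> W;
  std::vector<fvec> b;
  weights_from_r(weights, defs, W, b);
  const int N = X.ncol();
  fmat Xf = arma::conv_to<fmat>::from(
    arma::mat(X.begin(), X.nrow(), N, false));
  const int n_layers = static_cast<int>(defs.size());
  NumericMatrix out(N, defs[n_layers - 1].units);
  BatchCache C;
  fmat input;
  for (int start = 0; start < N; start += batch) {
    const int stop_i = std::min(start + batch, N);
    std::vector<int> idx;
    for (int i = start; i < stop_i; ++i) idx.push_back(i);
    assemble_input(Xf, idx, defs[0], false, nullptr, input);
    forward(defs, W, b, input, static_cast<int>(idx.size()), false, 0.0,
            nullptr, C, false);
    const fmat& probs = C.act[n_layers - 1];
    for (size_t bi = 0; bi < idx.size(); ++bi)
      for (int k = 0; k < static_cast<int>(probs.n_rows); ++k)
        out(idx[bi], k) = probs(k, bi);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Gradients of the mean cross-entropy at the current weights (no dropout,
// no augmentation); used for finite-difference verification in the tests.
// [[Rcpp::export]]
List cnn_gradients_cpp(List weights, IntegerMatrix layer_defs,
                       NumericMatrix X, IntegerVector y) {
  std::vector<LayerDef> defs = parse_defs(layer_defs);
  std::vector<fmat> W;
  std::vector<fvec> b;
  weights_from_r(weights, defs, W, b);
  const int N = X.ncol();
  fmat Xf = arma::conv_to<fmat>::from(
    arma::mat(X.begin(), X.nrow(), N, false));
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  fmat input;
  assemble_input(Xf, idx, defs[0], false, nullptr, input);
  BatchCache C;
  forward(defs, W, b, input, N, false, 0.0, nullptr, C, true);
  const int n_layers = static_cast<int>(defs.size());
  const fmat& probs = C.act[n_layers - 1];
  double loss = 0.0;
  for (int bi = 0; bi < N; ++bi)
    loss += -std::log(std::max(static_cast<double>(probs(y[bi], bi)), 1e-12));
  loss /= N;
  std::vector<fmat> dW;
  std::vector<fvec> db;
  backward(defs, W, y, idx, C, first_trainable(defs), dW, db);
  List grads(n_layers);
  for (int i = 0; i < n_layers; ++i) {
    if (dW[i].n_elem == 0) { grads[i] = R_NilValue; continue; }
    NumericMatrix Wm(dW[i].n_rows, dW[i].n_cols);
    std::copy(dW[i].begin(), dW[i].end(), Wm.begin());
    NumericVector bv(db[i].n_elem);
    std::copy(db[i].begin(), db[i].end(), bv.begin());
    grads[i] = List::create(Named("W") = Wm, Named("b") = bv);
  }
  return List::create(Named("loss") = loss, Named("grads") = grads);
}
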