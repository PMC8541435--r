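// Dual-encoder convolutional encoder-decoder for band segmentation.
//
// Activations are stored as (N*H*W) x C single-precision matrices: sample s
// occupies the contiguous row block [s*H*W, (s+1)*H*W), column-major within
// the sample (flat spatial index = row + col*H).  3x3 convolutions run as
// im2col + GEMM; batch norm is computed over batch x spatial rows per
// channel; PReLU has one learnable slope per channel; optimisation is Adam.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#if defined(__SSE2__)
#include <pmmintrin.h>
#endif

using namespace arma;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.9f;
static const float ADAM_B1 = 0.9f;
static const float ADAM_B2 = 0.999f;
static const float ADAM_EPS = 1e-8f;

// ---------------------------------------------------------------- im2col ---

// X: (N*H*W) x C input; returns (N*H*W) x (9*C); column c*9+o holds channel c
// shifted by offset o (zero padding, 'same' geometry).
static fmat im2col3(const fmat& X, int H, int W, int N) {
  const int HW = H * W;
  const int C = X.n_cols;
  fmat M(X.n_rows, 9 * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int o = 0; o < 9; ++o) {
      const int dr = o % 3 - 1, dc = o / 3 - 1;
      const int r0o = std::max(0, -dr), r1o = H - 1 - std::max(0, dr);
      const int c0o = std::max(0, -dc), c1o = W - 1 - std::max(0, dc);
      if (r0o > r1o || c0o > c1o) continue;
      for (int s = 0; s < N; ++s) {
        const fmat Xv(const_cast<float*>(X.colptr(c)) + (size_t)s * HW, H, W, false, true);
        fmat Mv(M.colptr(c * 9 + o) + (size_t)s * HW, H, W, false, true);
        Mv.submat(r0o, c0o, r1o, c1o) = Xv.submat(r0o + dr, c0o + dc, r1o + dr, c1o + dc);
      }
    }
  }
  return M;
}

// adjoint of im2col3: scatter-add the 9*C columns back onto C channels
static fmat col2im3(const fmat& M, int H, int W, int N) {
  const int HW = H * W;
  const int C = M.n_cols / 9;
  fmat X(M.n_rows, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int o = 0; o < 9; ++o) {
      const int dr = o % 3 - 1, dc = o / 3 - 1;
      const int r0o = std::max(0, -dr), r1o = H - 1 - std::max(0, dr);
      const int c0o = std::max(0, -dc), c1o = W - 1 - std::max(0, dc);
      if (r0o > r1o || c0o > c1o) continue;
      for (int s = 0; s < N; ++s) {
        const fmat Mv(const_cast<float*>(M.colptr(c * 9 + o)) + (size_t)s * HW, H, W, false, true);
        fmat Xv(X.colptr(c) + (size_t)s * HW, H, W, false, true);
        Xv.submat(r0o + dr, c0o + dc, r1o + dr, c1o + dc) += Mv.submat(r0o, c0o, r1o, c1o);
      }
    }
  }
  return X;
}

// ------------------------------------------------------------------ layer ---

struct AdamState {
  fmat m, v;
  void init(int r, int c) { m.zeros(r, c); v.zeros(r, c); }
  void step(fmat& p, const fmat& g, float lr, long t) {
    m = ADAM_B1 * m + (1.0f - ADAM_B1) * g;
    v = ADAM_B2 * v + (1.0f - ADAM_B2) * square(g);
    const float bc1 = 1.0f - std::pow(ADAM_B1, (float)t);
    const float bc2 = 1.0f - std::pow(ADAM_B2, (float)t);
    p -= lr * (m / bc1) / (sqrt(v / bc2) + ADAM_EPS);
  }
};

struct Conv {
  int k = 3, Cin = 0, Cout = 0;
  bool bn = true, act = true;
  fmat W;                   // (k*k*Cin) x Cout
  frowvec b, gamma, beta, rmean, rvar, alpha;
  AdamState aW, ab, agamma, abeta, aalpha;
  // caches (training)
  fmat M, zh, a_in;
  frowvec istd;

  void init(int k_, int Cin_, int Cout_, bool bn_, bool act_, std::mt19937& rng) {
    k = k_; Cin = Cin_; Cout = Cout_; bn = bn_; act = act_;
    const int fan_in = k * k * Cin;
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / fan_in));
    W.set_size(fan_in, Cout);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
    b.zeros(Cout);
    gamma.ones(Cout); beta.zeros(Cout);
    rmean.zeros(Cout); rvar.ones(Cout);
    alpha.set_size(Cout); alpha.fill(0.25f);
    aW.init(fan_in, Cout); ab.init(1, Cout);
    agamma.init(1, Cout); abeta.init(1, Cout); aalpha.init(1, Cout);
  }

  fmat forward(const fmat& X, int H, int Wd, int N, bool train) {
    fmat z;
    if (k == 3) { M = im2col3(X, H, Wd, N); z = M * W; }
    else { M = X; z = X * W; }
    z.each_row() += b;
    if (bn) {
      if (train) {
        frowvec mu = mean(z, 0);
        frowvec var = mean(square(z.each_row() - mu), 0);
        istd = 1.0f / sqrt(var + BN_EPS);
        zh = (z.each_row() - mu).each_row() % istd;
        rmean = BN_MOMENTUM * rmean + (1.0f - BN_MOMENTUM) * mu;
        rvar = BN_MOMENTUM * rvar + (1.0f - BN_MOMENTUM) * var;
      } else {
        frowvec is = 1.0f / sqrt(rvar + BN_EPS);
        zh = (z.each_row() - rmean).each_row() % is;
      }
      z = (zh.each_row() % gamma).each_row() + beta;
    }
    if (act) {
      a_in = z;
      fmat negpart = min(z, fmat(size(z), fill::zeros));
      z = max(z, fmat(size(z), fill::zeros)) + negpart.each_row() % alpha;
    }
    if (!train) { M.reset(); zh.reset(); a_in.reset(); }
    return z;
  }

  // consumes caches; returns gradient w.r.t. the layer input and applies Adam
  fmat backward(fmat dY, int H, int Wd, int N, float lr, long t) {
    if (act) {
      fmat neg = min(a_in, fmat(size(a_in), fill::zeros));
      frowvec dalpha = sum(dY % neg, 0);
      fmat pos = conv_to<fmat>::from(a_in > 0.0f);
      fmat negi = 1.0f - pos;
      dY %= pos + negi.each_row() % alpha;
      aalpha.step(alpha, dalpha, lr, t);
    }
    if (bn) {
      frowvec dgamma = sum(dY % zh, 0);
      frowvec dbeta = sum(dY, 0);
      fmat dzh = dY.each_row() % gamma;
      const float mrows = (float)dY.n_rows;
      frowvec s1 = sum(dzh, 0);
      frowvec s2 = sum(dzh % zh, 0);
      fmat dz = dzh * mrows;
      dz.each_row() -= s1;
      dz -= zh.each_row() % s2;
      dz.each_row() %= istd;
      dY = dz / mrows;
      agamma.step(gamma, dgamma, lr, t);
      abeta.step(beta, dbeta, lr, t);
    }
    frowvec db = sum(dY, 0);
    fmat dW = M.t() * dY;
    fmat dM = dY * W.t();
    aW.step(W, dW, lr, t);
    ab.step(b, db, lr, t);
    M.reset(); zh.reset(); a_in.reset();
    if (k == 3) return col2im3(dM, H, Wd, N);
    return dM;
  }
};

// ------------------------------------------------------------------- pool ---

static fmat maxpool2(const fmat& X, int H, int W, int N, umat& idx) {
  const int H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
  const int C = X.n_cols;
  fmat Y((size_t)N * HW2, C);
  idx.set_size((size_t)N * HW2, C);
  for (int c = 0; c < C; ++c) {
    const float* xc = X.colptr(c);
    float* yc = Y.colptr(c);
    uword* ic = idx.colptr(c);
    for (int s = 0; s < N; ++s) {
      const size_t xo = (size_t)s * HW, yo = (size_t)s * HW2;
      for (int j = 0; j < W2; ++j) {
        for (int i = 0; i < H2; ++i) {
          const size_t p00 = xo + (2 * i) + (2 * j) * H;
          size_t best = p00; float bv = xc[p00];
          const size_t cand[3] = {p00 + 1, p00 + (size_t)H, p00 + (size_t)H + 1};
          for (int q = 0; q < 3; ++q) if (xc[cand[q]] > bv) { bv = xc[cand[q]]; best = cand[q]; }
          yc[yo + i + (size_t)j * H2] = bv;
          ic[yo + i + (size_t)j * H2] = best;
        }
      }
    }
  }
  return Y;
}

static fmat maxpool2_back(const fmat& dY, const umat& idx, size_t in_rows) {
  fmat dX(in_rows, dY.n_cols, fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c) {
    const float* dyc = dY.colptr(c);
    const uword* ic = idx.colptr(c);
    float* dxc = dX.colptr(c);
    for (uword r = 0; r < dY.n_rows; ++r) dxc[ic[r]] += dyc[r];
  }
  return dX;
}

static fmat upsample2(const fmat& X, int H, int W, int N) {
  const int H2 = H * 2, W2 = W * 2, HW = H * W, HW2 = H2 * W2;
  fmat Y((size_t)X.n_rows * 4, X.n_cols);
  for (uword c = 0; c < X.n_cols; ++c) {
    const float* xc = X.colptr(c);
    float* yc = Y.colptr(c);
    for (int s = 0; s < N; ++s) {
      const size_t xo = (size_t)s * HW, yo = (size_t)s * HW2;
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i)
          yc[yo + i + (size_t)j * H2] = xc[xo + i / 2 + (size_t)(j / 2) * H];
    }
  }
  return Y;
}

static fmat upsample2_back(const fmat& dY, int H, int W, int N) {
  // H, W: input (coarse) dims
  const int H2 = H * 2, HW = H * W, HW2 = H2 * W * 2;
  fmat dX((size_t)N * HW, dY.n_cols, fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c) {
    const float* dyc = dY.colptr(c);
    float* dxc = dX.colptr(c);
    for (int s = 0; s < N; ++s) {
      const size_t xo = (size_t)s * HW, yo = (size_t)s * HW2;
      for (int j = 0; j < 2 * W; ++j)
        for (int i = 0; i < H2; ++i)
          dxc[xo + i / 2 + (size_t)(j / 2) * H] += dyc[yo + i + (size_t)j * H2];
    }
  }
  return dX;
}

// -------------------------------------------------------------------- net ---

// Subnormal float arithmetic is microcoded on x86 and can slow training by
// an order of magnitude; decayed activations/gradients hit it constantly.
// Flush-to-zero / denormals-are-zero is numerically harmless here.
static inline void set_ftz() {
#if defined(__SSE2__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

struct Net {
  int H, W, k_classes, blocks, base;
  bool use_bn;
  std::vector<std::vector<Conv>> enc1, enc2, dec;
  Conv fuse, out;
  long t = 0;

  static int block_channels(int base, int b) {            // b is 1-based
    return base * (1 << std::min(b - 1, 3));
  }
  static int block_convs(int b) { return b <= 2 ? 2 : 4; }

  void build(int H_, int W_, int k_, int blocks_, int base_, bool bn_, int seed) {
    H = H_; W = W_; k_classes = k_; blocks = blocks_; base = base_; use_bn = bn_;
    std::mt19937 rng((unsigned)seed);
    auto make_encoder = [&](std::vector<std::vector<Conv>>& enc) {
      enc.assign(blocks, {});
      int cin = 1;
      for (int b = 1; b <= blocks; ++b) {
        const int cb = block_channels(base, b);
        for (int q = 0; q < block_convs(b); ++q) {
          Conv cv; cv.init(3, q == 0 ? cin : cb, cb, use_bn, true, rng);
          enc[b - 1].push_back(std::move(cv));
        }
        cin = cb;
      }
    };
    make_encoder(enc1);
    make_encoder(enc2);
    const int cB = block_channels(base, blocks);
    fuse.init(1, 2 * cB, cB, use_bn, true, rng);
    dec.assign(blocks, {});
    for (int b = blocks; b >= 1; --b) {
      const int cb = block_channels(base, b);
      const int cout_last = (b == 1) ? base : block_channels(base, b - 1);
      const int nconv = block_convs(b);
      for (int q = 0; q < nconv; ++q) {
        Conv cv; cv.init(3, cb, q == nconv - 1 ? cout_last : cb, use_bn, true, rng);
        dec[blocks - b].push_back(std::move(cv));
      }
    }
    out.init(1, base, k_classes, false, false, rng);
    t = 0;
  }

  // forward; fills caches when train = true
  fmat forward(const fmat& x1, const fmat& x2, int N, bool train,
               std::vector<umat>& idx1, std::vector<umat>& idx2) {
    idx1.assign(blocks, umat());
    idx2.assign(blocks, umat());
    fmat a1 = x1, a2 = x2;
    int h = H, w = W;
    for (int b = 0; b < blocks; ++b) {
      for (auto& cv : enc1[b]) a1 = cv.forward(a1, h, w, N, train);
      for (auto& cv : enc2[b]) a2 = cv.forward(a2, h, w, N, train);
      a1 = maxpool2(a1, h, w, N, idx1[b]);
      a2 = maxpool2(a2, h, w, N, idx2[b]);
      h /= 2; w /= 2;
    }
    fmat f = join_rows(a1, a2);
    f = fuse.forward(f, h, w, N, train);
    for (int d = 0; d < blocks; ++d) {
      f = upsample2(f, h, w, N);
      h *= 2; w *= 2;
      for (auto& cv : dec[d]) f = cv.forward(f, h, w, N, train);
    }
    fmat logits = out.forward(f, h, w, N, train);
    return logits;
  }

  static fmat softmax_rows(const fmat& z) {
    fmat p = z.each_col() - max(z, 1);
    p = exp(p);
    p.each_col() /= sum(p, 1);
    return p;
  }

  double train_step(const fmat& x1, const fmat& x2, const fmat& y, int N, float lr) {
    std::vector<umat> idx1, idx2;
    fmat logits = forward(x1, x2, N, true, idx1, idx2);
    fmat P = softmax_rows(logits);
    const float rows = (float)P.n_rows;
    double loss = -accu(y % log(P + 1e-12f)) / rows;
    ++t;
    fmat d = (P - y) / rows;
    int h = H, w = W;
    d = out.backward(std::move(d), h, w, N, lr, t);
    for (int dblk = blocks - 1; dblk >= 0; --dblk) {
      for (int q = (int)dec[dblk].size() - 1; q >= 0; --q)
        d = dec[dblk][q].backward(std::move(d), h, w, N, lr, t);
      h /= 2; w /= 2;
      d = upsample2_back(d, h, w, N);
    }
    d = fuse.backward(std::move(d), h, w, N, lr, t);
    const int cB = block_channels(base, blocks);
    fmat d1 = d.cols(0, cB - 1), d2 = d.cols(cB, 2 * cB - 1);
    for (int b = blocks - 1; b >= 0; --b) {
      const size_t in_rows = (size_t)N * (H >> b) * (W >> b);
      d1 = maxpool2_back(d1, idx1[b], in_rows);
      d2 = maxpool2_back(d2, idx2[b], in_rows);
      h = H >> b; w = W >> b;
      for (int q = (int)enc1[b].size() - 1; q >= 0; --q)
        d1 = enc1[b][q].backward(std::move(d1), h, w, N, lr, t);
      for (int q = (int)enc2[b].size() - 1; q >= 0; --q)
        d2 = enc2[b][q].backward(std::move(d2), h, w, N, lr, t);
    }
    return loss;
  }

  std::vector<Conv*> all_layers() {
    std::vector<Conv*> v;
    for (auto& blk : enc1) for (auto& c : blk) v.push_back(&c);
    for (auto& blk : enc2) for (auto& c : blk) v.push_back(&c);
    v.push_back(&fuse);
    for (auto& blk : dec) for (auto& c : blk) v.push_back(&c);
    v.push_back(&out);
    return v;
  }
};

// -------------------------------------------------------------- R bridge ---

// batch cube (H x W x N, single channel) -> (N*H*W) x 1 float matrix
static fmat cube_to_batch(const cube& x) {
  fmat X(x.n_elem, 1);
  for (uword i = 0; i < x.n_elem; ++i) X(i, 0) = (float)x(i);
  return X;
}

// [[Rcpp::export]]
SEXP net_create(int H, int W, int k, int blocks, int base, bool batch_norm, int seed) {
  if (H % (1 << blocks) != 0 || W % (1 << blocks) != 0)
    Rcpp::stop("input shape %dx%d not divisible by 2^%d", H, W, blocks);
  Net* net = new Net();
  net->build(H, W, k, blocks, base, batch_norm, seed);
  Rcpp::XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
double net_train_step(SEXP handle, const arma::cube& x1, const arma::cube& x2,
                      const arma::cube& fg, double lr) {
  set_ftz();
  Rcpp::XPtr<Net> net(handle);
  const int N = x1.n_slices;
  fmat X1 = cube_to_batch(x1), X2 = cube_to_batch(x2);
  fmat Y(X1.n_rows, net->k_classes, fill::zeros);
  for (uword i = 0; i < fg.n_elem; ++i) {
    const int cls = fg(i) > 0.5 ? 1 : 0;
    Y(i, cls) = 1.0f;
  }
  return net->train_step(X1, X2, Y, N, (float)lr);
}

// Forward pass in training mode without any weight update: refreshes the
// batch-norm running statistics ("precise BN" finalization).  After a short
// high-rate Adam run the running averages lag the final weights badly enough
// to collapse inference-mode predictions.
// [[Rcpp::export]]
void net_calibrate(SEXP handle, const arma::cube& x1, const arma::cube& x2) {
  set_ftz();
  Rcpp::XPtr<Net> net(handle);
  std::vector<umat> i1, i2;
  net->forward(cube_to_batch(x1), cube_to_batch(x2), x1.n_slices, true, i1, i2);
  for (Conv* c : net->all_layers()) { c->M.reset(); c->zh.reset(); c->a_in.reset(); }
}

// [[Rcpp::export]]
Rcpp::NumericVector net_predict(SEXP handle, const arma::cube& x1, const arma::cube& x2) {
  set_ftz();
  Rcpp::XPtr<Net> net(handle);
  const int N = x1.n_slices, H = net->H, W = net->W, k = net->k_classes;
  std::vector<umat> i1, i2;
  fmat logits = net->forward(cube_to_batch(x1), cube_to_batch(x2), N, false, i1, i2);
  fmat P = Net::softmax_rows(logits);
  Rcpp::NumericVector outv((R_xlen_t)H * W * k * N);
  outv.attr("dim") = Rcpp::IntegerVector::create(H, W, k, N);
  const size_t HW = (size_t)H * W;
  for (int s = 0; s < N; ++s)
    for (int j = 0; j < k; ++j)
      for (size_t p = 0; p < HW; ++p)
        outv[p + HW * j + HW * k * s] = P((size_t)s * HW + p, j);
  return outv;
}

// [[Rcpp::export]]
Rcpp::List net_describe(SEXP handle) {
  Rcpp::XPtr<Net> net(handle);
  long n_par = 0;
  for (Conv* c : net->all_layers())
    n_par += c->W.n_elem + c->b.n_elem + (c->bn ? c->gamma.n_elem * 2 : 0) + (c->act ? c->alpha.n_elem : 0);
  return Rcpp::List::create(
    Rcpp::Named("H") = net->H, Rcpp::Named("W") = net->W,
    Rcpp::Named("k") = net->k_classes, Rcpp::Named("blocks") = net->blocks,
    Rcpp::Named("base_filters") = net->base, Rcpp::Named("n_layers") = (int)net->all_layers().size(),
    Rcpp::Named("n_params") = (double)n_par, Rcpp::Named("adam_t") = (double)net->t);
}

// [[Rcpp::export]]
Rcpp::List net_weights(SEXP handle) {
  Rcpp::XPtr<Net> net(handle);
  std::vector<Conv*> layers = net->all_layers();
  Rcpp::List outl(layers.size());
  for (size_t i = 0; i < layers.size(); ++i) {
    Conv* c = layers[i];
    outl[i] = Rcpp::List::create(
      Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(c->W)),
      Rcpp::Named("b") = Rcpp::wrap(conv_to<rowvec>::from(c->b)),
      Rcpp::Named("gamma") = Rcpp::wrap(conv_to<rowvec>::from(c->gamma)),
      Rcpp::Named("beta") = Rcpp::wrap(conv_to<rowvec>::from(c->beta)),
      Rcpp::Named("rmean") = Rcpp::wrap(conv_to<rowvec>::from(c->rmean)),
      Rcpp::Named("rvar") = Rcpp::wrap(conv_to<rowvec>::from(c->rvar)),
      Rcpp::Named("alpha") = Rcpp::wrap(conv_to<rowvec>::from(c->alpha)));
  }
  return outl;
}

// [[Rcpp::export]]
void net_set_weights(SEXP handle, Rcpp::List weights) {
  Rcpp::XPtr<Net> net(handle);
  std::vector<Conv*> layers = net->all_layers();
  if ((size_t)weights.size() != layers.size())
    Rcpp::stop("weight list has %d entries, model has %d layers", weights.size(), (int)layers.size());
  for (size_t i = 0; i < layers.size(); ++i) {
    Rcpp::List wl = weights[i];
    Conv* c = layers[i];
    fmat Wn = conv_to<fmat>::from(Rcpp::as<mat>(wl["W"]));
    if (Wn.n_rows != c->W.n_rows || Wn.n_cols != c->W.n_cols)
      Rcpp::stop("layer %d: weight shape mismatch", (int)i + 1);
    c->W = Wn;
    c->b = conv_to<frowvec>::from(Rcpp::as<rowvec>(wl["b"]));
    c->gamma = conv_to<frowvec>::from(Rcpp::as<rowvec>(wl["gamma"]));
    c->beta = conv_to<frowvec>::from(Rcpp::as<rowvec>(wl["beta"]));
    c->rmean = conv_to<frowvec>::from(Rcpp::as<rowvec>(wl["rmean"]));
    c->rvar = conv_to<frowvec>::from(Rcpp::as<rowvec>(wl["rvar"]));
    c->alpha = conv_to<frowvec>::from(Rcpp::as<rowvec>(wl["alpha"]));
  }
}

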