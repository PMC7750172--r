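// Convolutional encoder-decoder (U-Net) engine: single-precision im2col +
// BLAS sgemm. Feature maps are stored as C x (H*W*N) matrices, one column per
// pixel, pixel order h + H*w within an image, images consecutive.
// Trainable parameters live in an R named list; this file only computes
// forward passes and gradients (the optimizer runs in R).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>

using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::Named;

static const float BN_EPS = 1e-5f;

// xorshift RNG for dropout masks (fast, seeded, R-independent)
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) {
    // splitmix64 scramble so nearby seeds give unrelated streams
    s = seed + 0x9E3779B97F4A7C15ULL;
    s = (s ^ (s >> 30)) * 0xBF58476D1CE4E5B9ULL;
    s = (s ^ (s >> 27)) * 0x94D049BB133111EBULL;
    s = s ^ (s >> 31);
    if (s == 0) s = 0x853C49E6748FEA9BULL;
  }
  inline float unif() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return (float)((s >> 11) * (1.0 / 9007199254740992.0));
  }
};

static fmat get_fmat(const List& p, const std::string& nm) {
  NumericMatrix m = p[nm];
  fmat out(m.nrow(), m.ncol());
  const double* src = m.begin();
  float* dst = out.memptr();
  const size_t n = (size_t)m.nrow() * m.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static fvec get_fvec(const List& p, const std::string& nm) {
  NumericVector v = p[nm];
  fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static NumericMatrix to_Rmat(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  const float* src = m.memptr();
  double* dst = out.begin();
  const size_t n = (size_t)m.n_rows * m.n_cols;
  for (size_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return out;
}

static NumericVector to_Rvec(const fvec& v) {
  NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = (double)v[i];
  return out;
}

// im2col for 3x3, stride 1, zero pad 1.  k = (dw+1)*3 + (dh+1).
// Only border entries are zeroed (interior is fully overwritten).
static void im2col3(const fmat& X, int H, int W, int N, fmat& cols) {
  const int C = X.n_rows, HW = H * W;
  const size_t cs = C * sizeof(float);
  for (int n = 0; n < N; ++n) {
    const int off = n * HW;
    for (int k = 0; k < 9; ++k) {
      const int dh = k % 3 - 1, dw = k / 3 - 1;
      const size_t ko = (size_t)k * C;
      for (int w = 0; w < W; ++w) {
        const int ws = w + dw;
        if (ws < 0 || ws >= W) {
          for (int h = 0; h < H; ++h)
            std::memset(cols.colptr(off + w * H + h) + ko, 0, cs);
          continue;
        }
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        for (int h = 0; h < h0; ++h)
          std::memset(cols.colptr(off + w * H + h) + ko, 0, cs);
        for (int h = h1; h < H; ++h)
          std::memset(cols.colptr(off + w * H + h) + ko, 0, cs);
        for (int h = h0; h < h1; ++h)
          std::memcpy(cols.colptr(off + w * H + h) + ko,
                      X.colptr(off + ws * H + h + dh), cs);
      }
    }
  }
}

// adjoint of im2col3: accumulate dcols (9C x HWN) into dX (C x HWN)
static void col2im3(const fmat& dcols, int H, int W, int N, fmat& dX) {
  const int C = dX.n_rows, HW = H * W;
  for (int n = 0; n < N; ++n) {
    const int off = n * HW;
    for (int k = 0; k < 9; ++k) {
      const int dh = k % 3 - 1, dw = k / 3 - 1;
      for (int w = 0; w < W; ++w) {
        const int ws = w + dw;
        if (ws < 0 || ws >= W) continue;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        for (int h = h0; h < h1; ++h) {
          float* dst = dX.colptr(off + ws * H + h + dh);
          const float* src = dcols.colptr(off + w * H + h) + (size_t)k * C;
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

static inline void relu_inplace(fmat& Y) {
  float* p = Y.memptr();
  const size_t n = Y.n_elem;
  for (size_t i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

// conv3x3 -> (batchnorm) -> ReLU block with cached tensors for backward.
// Elementwise stages are fused into single passes; the im2col buffer is
// kept between forward and backward.
struct ConvBN {
  std::string id;
  fmat W; fvec b, g, be, rm, rv;
  bool use_bn = true;
  // caches
  fmat cols, xhat, out;
  fvec invstd;
  int H = 0, Wd = 0, N = 0;
  // grads
  fmat dW; fvec db, dg, dbe;

  void load(const List& p, const std::string& name, bool bn) {
    id = name; use_bn = bn;
    W = get_fmat(p, name + ".W");
    b = get_fvec(p, name + ".b");
    if (use_bn) {
      g  = get_fvec(p, name + ".g");
      be = get_fvec(p, name + ".be");
      rm = get_fvec(p, name + ".rm");
      rv = get_fvec(p, name + ".rv");
    }
  }

  fmat fwd(const fmat& X, int H_, int W_, int N_, bool train, float bnmom,
           bool cache) {
    H = H_; Wd = W_; N = N_;
    const int Cin = X.n_rows;
    const int C = W.n_rows;
    fmat colsLocal;
    fmat& cl = cache ? cols : colsLocal;
    cl.set_size(9 * Cin, X.n_cols);
    im2col3(X, H, Wd, N, cl);
    fmat Y = W * cl;
    const size_t M = Y.n_cols;
    if (use_bn && train) {
      // single-pass mean/var of the conv output (bias folded analytically)
      fvec s(C, fill::zeros), ss(C, fill::zeros);
      for (size_t j = 0; j < M; ++j) {
        const float* y = Y.colptr(j);
        for (int c = 0; c < C; ++c) { s[c] += y[c]; ss[c] += y[c] * y[c]; }
      }
      fvec mu = s / (float)M;
      fvec v = ss / (float)M - square(mu);
      invstd = 1.0f / sqrt(v + BN_EPS);
      rm = (1.0f - bnmom) * rm + bnmom * (mu + b);
      rv = (1.0f - bnmom) * rv + bnmom * v;
      if (cache) xhat.set_size(C, M);
      // fused normalize + affine + ReLU  (xhat = (y + b - (mu + b)) inv)
      for (size_t j = 0; j < M; ++j) {
        float* y = Y.colptr(j);
        float* xh = cache ? xhat.colptr(j) : (float*)nullptr;
        for (int c = 0; c < C; ++c) {
          const float z = (y[c] - mu[c]) * invstd[c];
          if (xh) xh[c] = z;
          const float o = g[c] * z + be[c];
          y[c] = o > 0.0f ? o : 0.0f;
        }
      }
    } else if (use_bn) {
      fvec inv = 1.0f / sqrt(rv + BN_EPS);
      fvec a = g % inv;
      fvec c0 = be - (rm - b) % a;  // folds the conv bias into the affine map
      for (size_t j = 0; j < M; ++j) {
        float* y = Y.colptr(j);
        for (int c = 0; c < C; ++c) {
          const float o = a[c] * y[c] + c0[c];
          y[c] = o > 0.0f ? o : 0.0f;
        }
      }
    } else {
      for (size_t j = 0; j < M; ++j) {
        float* y = Y.colptr(j);
        for (int c = 0; c < C; ++c) {
          const float o = y[c] + b[c];
          y[c] = o > 0.0f ? o : 0.0f;
        }
      }
    }
    if (cache) out = Y;
    return Y;
  }

  fmat bwd(fmat dY) {
    const int C = W.n_rows;
    const size_t M = dY.n_cols;
    if (use_bn) {
      // pass 1: ReLU gate + accumulate dbeta, dgamma
      dbe.zeros(C); dg.zeros(C);
      for (size_t j = 0; j < M; ++j) {
        float* d = dY.colptr(j);
        const float* o = out.colptr(j);
        const float* xh = xhat.colptr(j);
        for (int c = 0; c < C; ++c) {
          if (o[c] <= 0.0f) d[c] = 0.0f;
          dbe[c] += d[c];
          dg[c] += d[c] * xh[c];
        }
      }
      // pass 2: dConv = invstd (g dY - (s1 + xhat s2)/M)
      fvec s1 = g % dbe, s2 = g % dg;
      fvec a = g % invstd;
      fvec q = invstd / (float)M;
      for (size_t j = 0; j < M; ++j) {
        float* d = dY.colptr(j);
        const float* xh = xhat.colptr(j);
        for (int c = 0; c < C; ++c)
          d[c] = a[c] * d[c] - q[c] * (s1[c] + xh[c] * s2[c]);
      }
      db.zeros(C);  // the conv bias is absorbed by batch-norm centring
    } else {
      db.zeros(C);
      for (size_t j = 0; j < M; ++j) {
        float* d = dY.colptr(j);
        const float* o = out.colptr(j);
        for (int c = 0; c < C; ++c) {
          if (o[c] <= 0.0f) d[c] = 0.0f;
          db[c] += d[c];
        }
      }
    }
    dW = dY * cols.t();
    fmat dcols = W.t() * dY;
    const int Cin = W.n_cols / 9;
    fmat dX(Cin, M, fill::zeros);
    col2im3(dcols, H, Wd, N, dX);
    cols.reset(); xhat.reset(); out.reset();
    return dX;
  }
};

struct Dropout {
  fmat mask;  // scaled keep mask, empty => inactive
  fmat fwd(fmat Y, float rate, XRng& rng, bool active, bool cache) {
    if (!active || rate <= 0.0f) { mask.reset(); return Y; }
    const float scale = 1.0f / (1.0f - rate);
    fmat m(Y.n_rows, Y.n_cols);
    float* mp = m.memptr();
    const size_t n = m.n_elem;
    for (size_t i = 0; i < n; ++i) mp[i] = (rng.unif() < rate) ? 0.0f : scale;
    Y %= m;
    if (cache) mask = m;
    return Y;
  }
  fmat bwd(fmat dY) {
    if (mask.n_elem > 0) { dY %= mask; mask.reset(); }
    return dY;
  }
};

struct Pool2 {
  umat idx;  // chosen input column per (channel, out pixel)
  int H = 0, W = 0, N = 0;
  fmat fwd(const fmat& X, int H_, int W_, int N_) {
    H = H_; W = W_; N = N_;
    const int C = X.n_rows, Ho = H / 2, Wo = W / 2;
    fmat Y(C, (size_t)Ho * Wo * N);
    idx.set_size(C, (size_t)Ho * Wo * N);
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const size_t oc = (size_t)n * Ho * Wo + (size_t)wo * Ho + ho;
          const size_t base = (size_t)n * H * W + (size_t)(2 * wo) * H + 2 * ho;
          const size_t cand[4] = {base, base + 1, base + H, base + H + 1};
          for (int c = 0; c < C; ++c) {
            float best = X(c, cand[0]); size_t bi = cand[0];
            for (int q = 1; q < 4; ++q) {
              const float v = X(c, cand[q]);
              if (v > best) { best = v; bi = cand[q]; }
            }
            Y(c, oc) = best;
            idx(c, oc) = (uword)bi;
          }
        }
      }
    }
    return Y;
  }
  fmat bwd(const fmat& dY) {
    const int C = dY.n_rows;
    fmat dX(C, (size_t)H * W * N, fill::zeros);
    for (size_t oc = 0; oc < dY.n_cols; ++oc)
      for (int c = 0; c < C; ++c)
        dX(c, idx(c, oc)) += dY(c, oc);
    idx.reset();
    return dX;
  }
};

// transposed conv 2x2 stride 2; W stored Cout x 4*Cin, block k = i + 2*j
// (i,j) = offset of the output pixel within the 2x2 cell
struct TConv {
  std::string id;
  fmat W; fvec b;
  fmat in;
  int H = 0, Wd = 0, N = 0;
  fmat dW; fvec db;

  void load(const List& p, const std::string& name) {
    id = name;
    W = get_fmat(p, name + ".W");
    b = get_fvec(p, name + ".b");
  }

  fmat fwd(const fmat& X, int H_, int W_, int N_, bool cache) {
    H = H_; Wd = W_; N = N_;
    const int Cin = X.n_rows, Cout = b.n_elem;
    const int Ho = 2 * H, Wo = 2 * Wd;
    fmat Y(Cout, (size_t)Ho * Wo * N, fill::zeros);
    if (cache) in = X;
    for (int k = 0; k < 4; ++k) {
      const int i = k % 2, j = k / 2;
      fmat Z = W.cols((size_t)k * Cin, (size_t)(k + 1) * Cin - 1) * X;
      for (int n = 0; n < N; ++n) {
        for (int w = 0; w < Wd; ++w) {
          for (int h = 0; h < H; ++h) {
            float* dst = Y.colptr((size_t)n * Ho * Wo +
                                  (size_t)(2 * w + j) * Ho + 2 * h + i);
            const float* src = Z.colptr((size_t)n * H * Wd + (size_t)w * H + h);
            for (int c = 0; c < Cout; ++c) dst[c] += src[c];
          }
        }
      }
    }
    Y.each_col() += b;
    return Y;
  }

  fmat bwd(const fmat& dY) {
    const int Cin = in.n_rows, Cout = b.n_elem;
    const int Ho = 2 * H, Wo = 2 * Wd;
    db = arma::sum(dY, 1);
    dW.set_size(Cout, 4 * Cin);
    fmat dX(Cin, in.n_cols, fill::zeros);
    for (int k = 0; k < 4; ++k) {
      const int i = k % 2, j = k / 2;
      fmat G(Cout, in.n_cols);
      for (int n = 0; n < N; ++n)
        for (int w = 0; w < Wd; ++w)
          for (int h = 0; h < H; ++h)
            std::memcpy(G.colptr((size_t)n * H * Wd + (size_t)w * H + h),
                        dY.colptr((size_t)n * Ho * Wo +
                                  (size_t)(2 * w + j) * Ho + 2 * h + i),
                        Cout * sizeof(float));
      dW.cols((size_t)k * Cin, (size_t)(k + 1) * Cin - 1) = G * in.t();
      dX += W.cols((size_t)k * Cin, (size_t)(k + 1) * Cin - 1).t() * G;
    }
    in.reset();
    return dX;
  }
};

struct UNet {
  int depth, base, H, W, N;
  bool use_bn;
  float drop_rate;
  std::vector<ConvBN> enc1, enc2, dec1, dec2;
  ConvBN bot1, bot2;
  std::vector<TConv> ups;
  std::vector<Pool2> pools;
  std::vector<Dropout> encdrop, decdrop;
  Dropout botdrop;
  fmat outW; fvec outb;       // final 1x1 conv
  fmat out_in;                // cache for final conv backward
  fmat outdW; fvec outdb;
  std::vector<fmat> skips;

  void load(const List& p, int depth_, int base_, bool bn) {
    depth = depth_; base = base_; use_bn = bn;
    enc1.resize(depth); enc2.resize(depth);
    dec1.resize(depth); dec2.resize(depth);
    ups.resize(depth); pools.resize(depth);
    encdrop.resize(depth); decdrop.resize(depth);
    for (int l = 0; l < depth; ++l) {
      const std::string el = "enc" + std::to_string(l + 1);
      const std::string dl = "dec" + std::to_string(l + 1);
      enc1[l].load(p, el + ".c1", bn);
      enc2[l].load(p, el + ".c2", bn);
      dec1[l].load(p, dl + ".c1", bn);
      dec2[l].load(p, dl + ".c2", bn);
      ups[l].load(p, dl + ".up");
    }
    bot1.load(p, "bott.c1", bn);
    bot2.load(p, "bott.c2", bn);
    outW = get_fmat(p, "out.W");
    outb = get_fvec(p, "out.b");
  }

  // train: BN batch statistics + dropout; mc: eval BN but dropout active
  fmat forward(const fmat& x0, int H_, int W_, int N_, bool train, bool mc,
               float rate, float bnmom, XRng& rng, bool cache) {
    H = H_; W = W_; N = N_;
    drop_rate = rate;
    const bool dropon = (train || mc) && rate > 0.0f;
    skips.assign(depth, fmat());
    fmat x = x0;
    int h = H, w = W;
    for (int l = 0; l < depth; ++l) {
      x = enc1[l].fwd(x, h, w, N, train, bnmom, cache);
      x = enc2[l].fwd(x, h, w, N, train, bnmom, cache);
      x = encdrop[l].fwd(std::move(x), rate, rng, dropon, cache);
      skips[l] = x;
      x = pools[l].fwd(x, h, w, N);
      h /= 2; w /= 2;
    }
    x = bot1.fwd(x, h, w, N, train, bnmom, cache);
    x = bot2.fwd(x, h, w, N, train, bnmom, cache);
    x = botdrop.fwd(std::move(x), rate, rng, dropon, cache);
    for (int l = depth - 1; l >= 0; --l) {
      x = ups[l].fwd(x, h, w, N, cache);
      h *= 2; w *= 2;
      x = join_cols(x, skips[l]);
      if (!cache) skips[l].reset();
      x = dec1[l].fwd(x, h, w, N, train, bnmom, cache);
      x = dec2[l].fwd(x, h, w, N, train, bnmom, cache);
      x = decdrop[l].fwd(std::move(x), rate, rng, dropon, cache);
    }
    if (cache) out_in = x;
    fmat y = outW * x;
    y.each_col() += outb;
    return y;
  }

  void backward(fmat dY) {
    outdW = dY * out_in.t();
    outdb = arma::sum(dY, 1);
    fmat dx = outW.t() * dY;
    out_in.reset();
    int h = H / (1 << depth) * 2, w = W / (1 << depth) * 2;
    // walk decoder from top (l=0) back down
    for (int l = 0; l < depth; ++l) {
      const int hh = H >> l, ww = W >> l;
      dx = decdrop[l].bwd(std::move(dx));
      dx = dec2[l].bwd(std::move(dx));
      dx = dec1[l].bwd(std::move(dx));
      const int cup = ups[l].b.n_elem;
      fmat dup = dx.rows(0, cup - 1);
      fmat dskip = dx.rows(cup, dx.n_rows - 1);
      dx = ups[l].bwd(dup);
      // stash skip gradient on the encoder side
      skips[l] = dskip;
      (void)hh; (void)ww; (void)h; (void)w;
    }
    dx = botdrop.bwd(std::move(dx));
    dx = bot2.bwd(std::move(dx));
    dx = bot1.bwd(std::move(dx));
    for (int l = depth - 1; l >= 0; --l) {
      dx = pools[l].bwd(dx);
      dx += skips[l];
      skips[l].reset();
      dx = encdrop[l].bwd(std::move(dx));
      dx = enc2[l].bwd(std::move(dx));
      dx = enc1[l].bwd(std::move(dx));
    }
  }

  void collect(List& grads, List& stats) const {
    for (int l = 0; l < depth; ++l) {
      const std::string el = "enc" + std::to_string(l + 1);
      const std::string dl = "dec" + std::to_string(l + 1);
      const ConvBN* cs[4] = {&enc1[l], &enc2[l], &dec1[l], &dec2[l]};
      const std::string nm[4] = {el + ".c1", el + ".c2", dl + ".c1", dl + ".c2"};
      for (int q = 0; q < 4; ++q) {
        grads[nm[q] + ".W"] = to_Rmat(cs[q]->dW);
        grads[nm[q] + ".b"] = to_Rvec(cs[q]->db);
        if (use_bn) {
          grads[nm[q] + ".g"] = to_Rvec(cs[q]->dg);
          grads[nm[q] + ".be"] = to_Rvec(cs[q]->dbe);
          stats[nm[q] + ".rm"] = to_Rvec(cs[q]->rm);
          stats[nm[q] + ".rv"] = to_Rvec(cs[q]->rv);
        }
      }
      grads[dl + ".up.W"] = to_Rmat(ups[l].dW);
      grads[dl + ".up.b"] = to_Rvec(ups[l].db);
    }
    const ConvBN* bs[2] = {&bot1, &bot2};
    const std::string bn[2] = {"bott.c1", "bott.c2"};
    for (int q = 0; q < 2; ++q) {
      grads[bn[q] + ".W"] = to_Rmat(bs[q]->dW);
      grads[bn[q] + ".b"] = to_Rvec(bs[q]->db);
      if (use_bn) {
        grads[bn[q] + ".g"] = to_Rvec(bs[q]->dg);
        grads[bn[q] + ".be"] = to_Rvec(bs[q]->dbe);
        stats[bn[q] + ".rm"] = to_Rvec(bs[q]->rm);
        stats[bn[q] + ".rv"] = to_Rvec(bs[q]->rv);
      }
    }
    grads["out.W"] = to_Rmat(outdW);
    grads["out.b"] = to_Rvec(outdb);
  }
};

static fmat input_to_fmat(const NumericVector& x, int H, int W, int N) {
  fmat X(1, (size_t)H * W * N);
  const double* src = x.begin();
  float* dst = X.memptr();
  const size_t n = (size_t)H * W * N;
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return X;
}

// [[Rcpp::export]]
List cpp_unet_train_step(List params, NumericVector x, NumericVector target,
                         int H, int W, int N, int depth, int base, bool use_bn,
                         double dropout, double seed, double bn_momentum) {
  UNet net;
  net.load(params, depth, base, use_bn);
  XRng rng((uint64_t)seed);
  fmat X = input_to_fmat(x, H, W, N);
  fmat T = input_to_fmat(target, H, W, N);
  fmat Y = net.forward(X, H, W, N, true, false, (float)dropout,
                       (float)bn_momentum, rng, true);
  fmat R = Y - T;
  const double loss = arma::accu(square(conv_to<mat>::from(R))) / R.n_elem;
  fmat dY = (2.0f / (float)R.n_elem) * R;
  net.backward(std::move(dY));
  List grads, stats;
  net.collect(grads, stats);
  return List::create(Named("loss") = loss, Named("grads") = grads,
                      Named("stats") = stats);
}

// [[Rcpp::export]]
NumericVector cpp_unet_predict(List params, NumericVector x, int H, int W,
                               int N, int depth, int base, bool use_bn,
                               bool mc_dropout, double dropout, double seed) {
  UNet net;
  net.load(params, depth, base, use_bn);
  XRng rng((uint64_t)seed);
  fmat X = input_to_fmat(x, H, W, N);
  fmat Y = net.forward(X, H, W, N, false, mc_dropout, (float)dropout, 0.0f,
                       rng, false);
  NumericVector out((R_xlen_t)Y.n_elem);
  const float* src = Y.memptr();
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = (double)src[i];
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, N);
  return out;
}

// Adam update in C++: m and v are updated in place (they are owned solely
// by the training loop); the returned parameter list is freshly allocated
// so that best-epoch snapshots held in R remain valid.
// [[Rcpp::export]]
List cpp_adam_step(List params, List grads, List m, List v,
                   Rcpp::CharacterVector nms, int t, double lr, double b1,
                   double b2, double eps) {
  List out = Rcpp::clone(params);
  const double c1 = 1.0 - std::pow(b1, (double)t);
  const double c2 = 1.0 - std::pow(b2, (double)t);
  for (R_xlen_t k = 0; k < nms.size(); ++k) {
    const std::string s = Rcpp::as<std::string>(nms[k]);
    NumericVector p = out[s], g = grads[s], mm = m[s], vv = v[s];
    const R_xlen_t n = p.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      mm[i] = b1 * mm[i] + (1.0 - b1) * g[i];
      vv[i] = b2 * vv[i] + (1.0 - b2) * g[i] * g[i];
      p[i] -= lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + eps);
    }
  }
  return out;
}
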