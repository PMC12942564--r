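// Spectral-spatial CNN for hematoma age regression.
//
// Architecture (per sample, patch of P x P pixels, nb bands):
//   per-pixel spectral encoder: Conv1D stack along the band axis with
//   shared weights across pixels (pixels are folded into the batch
//   dimension), each conv followed by ReLU then BatchNorm; adaptive
//   average pooling to length L; average over the L positions -> one
//   embedding vector per pixel; the embedding map is then processed by two
//   3x3 Conv2D blocks (ReLU + BatchNorm) with 2x2 max pooling, adaptive
//   average pooling to q x q, and a dropout-regularized two-layer linear
//   regression head ending in a scalar age.
//
// Everything is implemented directly on Armadillo float matrices; the
// heavy lifting is shifted-window GEMMs (Conv1D) and im2col GEMMs
// (Conv2D).  Training uses Adam with MSE loss, optional flip
// augmentation, and early stopping on validation MAE with best-epoch
// weight restoration.  All randomness flows from one std::mt19937 seed,
// so runs are bit-reproducible on a fixed BLAS.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// large activation matrices are allocated and freed once per batch; keep
// them on the heap instead of round-tripping through mmap/munmap
static void keep_large_allocs() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 1 << 30);
    mallopt(M_TRIM_THRESHOLD, 1 << 30);
    done = true;
  }
#endif
}

using arma::fmat;
using arma::fvec;
using arma::frowvec;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.2f;

struct Conv1D { fmat W; fvec b; int in, out, k, pad; };
struct BN     { fvec g, be, rm, rv; };
struct Conv2D { fmat W; fvec b; int in, out; };   // 3x3, pad 1
struct Linear { fmat W; fvec b; };

struct NetCfg {
  int nb;
  int sc[3], sk[3];     // spectral channels / kernels
  int L;                // spectral pooled length
  int tc[2];            // spatial channels
  int q;                // adaptive spatial pool output side
  int hid;
  float drop;
};

struct Net {
  NetCfg cfg;
  Conv1D s[3];
  BN bn[5];             // 0..2 spectral, 3..4 spatial
  Conv2D t[2];
  Linear h1, h2;

  void reg(std::vector<arma::Mat<float>*>& v, bool with_bn_stats = false) {
    for (int i = 0; i < 3; ++i) { v.push_back(&s[i].W); v.push_back(&s[i].b); }
    for (int i = 0; i < 5; ++i) {
      v.push_back(&bn[i].g); v.push_back(&bn[i].be);
      if (with_bn_stats) { v.push_back(&bn[i].rm); v.push_back(&bn[i].rv); }
    }
    for (int i = 0; i < 2; ++i) { v.push_back(&t[i].W); v.push_back(&t[i].b); }
    v.push_back(&h1.W); v.push_back(&h1.b);
    v.push_back(&h2.W); v.push_back(&h2.b);
  }
};

static void he_init(fmat& W, int fan_in, std::mt19937& rng) {
  std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / fan_in));
  for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
}

static NetCfg parse_cfg(const Rcpp::List& cfg) {
  NetCfg c;
  c.nb = Rcpp::as<int>(cfg["n_bands"]);
  Rcpp::IntegerVector sc = cfg["spec_channels"], sk = cfg["spec_kernels"],
                      tc = cfg["spat_channels"];
  for (int i = 0; i < 3; ++i) { c.sc[i] = sc[i]; c.sk[i] = sk[i]; }
  for (int i = 0; i < 2; ++i) c.tc[i] = tc[i];
  c.L = Rcpp::as<int>(cfg["spec_pool_len"]);
  c.q = Rcpp::as<int>(cfg["spat_pool"]);
  c.hid = Rcpp::as<int>(cfg["head_hidden"]);
  c.drop = Rcpp::as<double>(cfg["dropout"]);
  return c;
}

static Net make_net(const NetCfg& c, unsigned int seed) {
  Net n; n.cfg = c;
  std::mt19937 rng(seed);
  int ins[3] = {1, c.sc[0], c.sc[1]};
  for (int i = 0; i < 3; ++i) {
    n.s[i].in = ins[i]; n.s[i].out = c.sc[i]; n.s[i].k = c.sk[i];
    n.s[i].pad = c.sk[i] / 2;
    n.s[i].W.set_size(c.sc[i], ins[i] * c.sk[i]);
    he_init(n.s[i].W, ins[i] * c.sk[i], rng);
    n.s[i].b.zeros(c.sc[i]);
  }
  int bnch[5] = {c.sc[0], c.sc[1], c.sc[2], c.tc[0], c.tc[1]};
  for (int i = 0; i < 5; ++i) {
    n.bn[i].g.ones(bnch[i]); n.bn[i].be.zeros(bnch[i]);
    n.bn[i].rm.zeros(bnch[i]); n.bn[i].rv.ones(bnch[i]);
  }
  int tins[2] = {c.sc[2], c.tc[0]};
  for (int i = 0; i < 2; ++i) {
    n.t[i].in = tins[i]; n.t[i].out = c.tc[i];
    n.t[i].W.set_size(c.tc[i], tins[i] * 9);
    he_init(n.t[i].W, tins[i] * 9, rng);
    n.t[i].b.zeros(c.tc[i]);
  }
  int feat = c.tc[1] * c.q * c.q;
  n.h1.W.set_size(c.hid, feat); he_init(n.h1.W, feat, rng); n.h1.b.zeros(c.hid);
  n.h2.W.set_size(1, c.hid);    he_init(n.h2.W, c.hid, rng); n.h2.b.zeros(1);
  return n;
}

// ---- weight (de)serialization ------------------------------------------

static Rcpp::List net_to_list(const Net& n) {
  Rcpp::List out;
  for (int i = 0; i < 3; ++i) {
    out[std::string("s") + std::to_string(i + 1) + "_W"] = n.s[i].W;
    out[std::string("s") + std::to_string(i + 1) + "_b"] = n.s[i].b;
  }
  for (int i = 0; i < 5; ++i) {
    std::string p = std::string("bn") + std::to_string(i + 1);
    out[p + "_g"] = n.bn[i].g;  out[p + "_b"] = n.bn[i].be;
    out[p + "_rm"] = n.bn[i].rm; out[p + "_rv"] = n.bn[i].rv;
  }
  for (int i = 0; i < 2; ++i) {
    out[std::string("t") + std::to_string(i + 1) + "_W"] = n.t[i].W;
    out[std::string("t") + std::to_string(i + 1) + "_b"] = n.t[i].b;
  }
  out["h1_W"] = n.h1.W; out["h1_b"] = n.h1.b;
  out["h2_W"] = n.h2.W; out["h2_b"] = n.h2.b;
  return out;
}

static Net list_to_net(const NetCfg& c, const Rcpp::List& w) {
  Net n = make_net(c, 0u);
  for (int i = 0; i < 3; ++i) {
    n.s[i].W = Rcpp::as<fmat>(w[std::string("s") + std::to_string(i + 1) + "_W"]);
    n.s[i].b = Rcpp::as<fvec>(w[std::string("s") + std::to_string(i + 1) + "_b"]);
  }
  for (int i = 0; i < 5; ++i) {
    std::string p = std::string("bn") + std::to_string(i + 1);
    n.bn[i].g = Rcpp::as<fvec>(w[p + "_g"]);
    n.bn[i].be = Rcpp::as<fvec>(w[p + "_b"]);
    n.bn[i].rm = Rcpp::as<fvec>(w[p + "_rm"]);
    n.bn[i].rv = Rcpp::as<fvec>(w[p + "_rv"]);
  }
  for (int i = 0; i < 2; ++i) {
    n.t[i].W = Rcpp::as<fmat>(w[std::string("t") + std::to_string(i + 1) + "_W"]);
    n.t[i].b = Rcpp::as<fvec>(w[std::string("t") + std::to_string(i + 1) + "_b"]);
  }
  n.h1.W = Rcpp::as<fmat>(w["h1_W"]); n.h1.b = Rcpp::as<fvec>(w["h1_b"]);
  n.h2.W = Rcpp::as<fmat>(w["h2_W"]); n.h2.b = Rcpp::as<fvec>(w["h2_b"]);
  return n;
}

// ---- layer primitives ---------------------------------------------------

// non-owning view of a contiguous column range (full rows), so GEMMs can
// read from and accumulate into slices without materializing temporaries
static inline fmat cview(const fmat& M, arma::uword c0, arma::uword ncols) {
  return fmat(const_cast<float*>(M.colptr(c0)), M.n_rows, ncols, false, true);
}

// Spectral-stage activations are stored as (Npix, ch*nb) matrices: band b
// occupies the `ch` contiguous columns [b*ch, (b+1)*ch).  Each channel of
// each band is one contiguous column of Npix floats, so per-channel
// elementwise work vectorizes, and a Conv1D band shift is a tall-skinny
// GEMM between contiguous column blocks.

// Conv1D over the band axis.  Because band blocks are contiguous columns,
// the full receptive window of an output band is one contiguous column
// range, so each band needs a single (Npix x in*k) x (in*k x out) GEMM.
static fmat conv1d_fwd(const Conv1D& c, const fmat& In, int nb, int Npix) {
  fmat Out((arma::uword)Npix, (arma::uword)c.out * nb);
  for (int b = 0; b < nb; ++b) {
    for (int o = 0; o < c.out; ++o) {
      Out.col((arma::uword)b * c.out + o).fill(c.b(o));
    }
  }
  // (in*k, out), row block dk holds the transposed taps of offset dk
  fmat Wt(c.in * c.k, c.out);
  for (int dk = 0; dk < c.k; ++dk) {
    Wt.rows(dk * c.in, dk * c.in + c.in - 1) =
      c.W.cols(dk * c.in, dk * c.in + c.in - 1).t();
  }
  for (int b = 0; b < nb; ++b) {
    int dk0 = std::max(0, c.pad - b);
    int dk1 = std::min(c.k - 1, nb - 1 - b + c.pad);
    int bi0 = b + dk0 - c.pad;
    fmat Ov = cview(Out, (arma::uword)b * c.out, c.out);
    Ov += cview(In, (arma::uword)bi0 * c.in, (arma::uword)(dk1 - dk0 + 1) * c.in) *
          Wt.rows(dk0 * c.in, (dk1 + 1) * c.in - 1);
  }
  return Out;
}

static void conv1d_bwd(const Conv1D& c, const fmat& In, const fmat& dOut,
                       fmat& dW, fvec& db, fmat* dIn, int nb, int Npix) {
  db.zeros(c.out);
  for (int b = 0; b < nb; ++b) {
    for (int o = 0; o < c.out; ++o) {
      db(o) += arma::accu(dOut.col((arma::uword)b * c.out + o));
    }
  }
  fmat Wt(c.in * c.k, c.out);     // as in the forward pass
  for (int dk = 0; dk < c.k; ++dk) {
    Wt.rows(dk * c.in, dk * c.in + c.in - 1) =
      c.W.cols(dk * c.in, dk * c.in + c.in - 1).t();
  }
  fmat dWt(c.in * c.k, c.out, arma::fill::zeros);
  if (dIn) dIn->zeros(In.n_rows, In.n_cols);
  for (int b = 0; b < nb; ++b) {
    int dk0 = std::max(0, c.pad - b);
    int dk1 = std::min(c.k - 1, nb - 1 - b + c.pad);
    int bi0 = b + dk0 - c.pad;
    arma::uword nc = (arma::uword)(dk1 - dk0 + 1) * c.in;
    fmat Ov = cview(dOut, (arma::uword)b * c.out, c.out);
    fmat Iv = cview(In, (arma::uword)bi0 * c.in, nc);
    dWt.rows(dk0 * c.in, (dk1 + 1) * c.in - 1) += Iv.t() * Ov;
    if (dIn) {
      fmat dIv = cview(*dIn, (arma::uword)bi0 * c.in, nc);
      dIv += Ov * Wt.rows(dk0 * c.in, (dk1 + 1) * c.in - 1).t();
    }
  }
  dW.set_size(c.W.n_rows, c.W.n_cols);
  for (int dk = 0; dk < c.k; ++dk) {
    dW.cols(dk * c.in, dk * c.in + c.in - 1) =
      dWt.rows(dk * c.in, dk * c.in + c.in - 1).t();
  }
}

// Fused ReLU (in place on the conv output) + BatchNorm forward.  Train
// mode computes batch statistics and updates running stats; eval mode
// uses running statistics.  Returns the BN output.
static fmat bn_relu_fwd(BN& bn, fmat& Z, bool train, fvec& mu, fvec& inv) {
  const arma::uword ch = bn.g.n_elem, ncol = Z.n_cols;
  const arma::uword nbands = ncol / ch;
  const double N = (double)Z.n_rows * nbands;
  float* z = Z.memptr();
  const arma::uword n_elem = Z.n_elem;
  for (arma::uword i = 0; i < n_elem; ++i) if (z[i] < 0.0f) z[i] = 0.0f;
  if (train) {
    std::vector<double> s(ch, 0.0), ss(ch, 0.0);
    for (arma::uword j = 0; j < ncol; ++j) {
      const arma::uword r = j % ch;
      s[r] += arma::accu(Z.col(j));
      ss[r] += arma::dot(Z.col(j), Z.col(j));
    }
    mu.set_size(ch); inv.set_size(ch);
    for (arma::uword r = 0; r < ch; ++r) {
      double m = s[r] / N;
      double v = std::max(0.0, ss[r] / N - m * m);
      mu(r) = (float)m;
      inv(r) = 1.0f / std::sqrt((float)v + BN_EPS);
      bn.rm(r) = (1.0f - BN_MOM) * bn.rm(r) + BN_MOM * (float)m;
      bn.rv(r) = (1.0f - BN_MOM) * bn.rv(r) + BN_MOM * (float)v;
    }
  } else {
    mu = bn.rm;
    inv = 1.0f / arma::sqrt(bn.rv + BN_EPS);
  }
  fvec sc = bn.g % inv;
  fvec sh = bn.be - mu % sc;
  fmat Y(Z.n_rows, ncol);
  for (arma::uword j = 0; j < ncol; ++j) {
    const arma::uword r = j % ch;
    Y.col(j) = sc(r) * Z.col(j) + sh(r);
  }
  return Y;
}

// Fused BatchNorm + ReLU backward: given the gradient at the BN output and
// the post-ReLU activations A (the BN input), returns the gradient at the
// conv pre-activation (ReLU mask applied).
static fmat bn_relu_bwd(const BN& bn, const fmat& A, const fmat& dY,
                        const fvec& mu, const fvec& inv,
                        fvec& dg, fvec& dbe, bool train) {
  const arma::uword ch = bn.g.n_elem, ncol = A.n_cols, nr = A.n_rows;
  const double N = (double)nr * (ncol / ch);
  std::vector<double> sdy(ch, 0.0), sdya(ch, 0.0);
  for (arma::uword j = 0; j < ncol; ++j) {
    const arma::uword r = j % ch;
    sdy[r] += arma::accu(dY.col(j));
    sdya[r] += arma::dot(dY.col(j), A.col(j));
  }
  dbe.set_size(ch); dg.set_size(ch);
  for (arma::uword r = 0; r < ch; ++r) {
    dbe(r) = (float)sdy[r];
    dg(r) = inv(r) * ((float)sdya[r] - mu(r) * dbe(r));
  }
  fvec c1(ch), c2(ch), c3(ch);
  for (arma::uword r = 0; r < ch; ++r) {
    float gi = bn.g(r) * inv(r);
    if (train) {
      c1(r) = gi;
      c2(r) = -gi * inv(r) * dg(r) / (float)N;
      c3(r) = gi * (mu(r) * inv(r) * dg(r) / (float)N - dbe(r) / (float)N);
    } else {
      c1(r) = gi; c2(r) = 0.0f; c3(r) = 0.0f;
    }
  }
  fmat dZ(nr, ncol);
  for (arma::uword j = 0; j < ncol; ++j) {
    const arma::uword r = j % ch;
    const float* pa = A.colptr(j); const float* pd = dY.colptr(j);
    float* pz = dZ.colptr(j);
    const float k1 = c1(r), k2 = c2(r), k3 = c3(r);
    for (arma::uword i = 0; i < nr; ++i) {
      pz[i] = pa[i] > 0.0f ? k1 * pd[i] + k2 * pa[i] + k3 : 0.0f;
    }
  }
  return dZ;
}

static inline void adaptive_window(int i, int n_in, int n_out, int& s, int& e) {
  s = (int)std::floor((double)i * n_in / n_out);
  e = (int)std::ceil((double)(i + 1) * n_in / n_out);
}

// im2col for 3x3 pad-1 conv over one image of P x P pixels stored as a
// (ch, P*P) block with column-major pixel order (r fastest).
static void im2col3(const fmat& Img, int ch, int P, fmat& C) {
  C.zeros(ch * 9, (arma::uword)P * P);
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      int blk = (dr + 1) * 3 + (dc + 1);
      int c0 = std::max(0, -dc), c1 = P - 1 - std::max(0, dc);
      int r0 = std::max(0, -dr), r1 = P - 1 - std::max(0, dr);
      if (c0 > c1 || r0 > r1) continue;
      for (int c = c0; c <= c1; ++c) {
        arma::uword dst0 = (arma::uword)c * P + r0;
        arma::uword src0 = (arma::uword)(c + dc) * P + (r0 + dr);
        C.submat(blk * ch, dst0, blk * ch + ch - 1, dst0 + (r1 - r0)) =
          Img.cols(src0, src0 + (r1 - r0));
      }
    }
  }
}

static void col2im3(const fmat& dC, int ch, int P, fmat& dImg) {
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      int blk = (dr + 1) * 3 + (dc + 1);
      int c0 = std::max(0, -dc), c1 = P - 1 - std::max(0, dc);
      int r0 = std::max(0, -dr), r1 = P - 1 - std::max(0, dr);
      if (c0 > c1 || r0 > r1) continue;
      for (int c = c0; c <= c1; ++c) {
        arma::uword dst0 = (arma::uword)c * P + r0;
        arma::uword src0 = (arma::uword)(c + dc) * P + (r0 + dr);
        dImg.cols(src0, src0 + (r1 - r0)) +=
          dC.submat(blk * ch, dst0, blk * ch + ch - 1, dst0 + (r1 - r0));
      }
    }
  }
}

// ---- forward / backward ------------------------------------------------

struct Cache {
  int B, P, Npix;
  fmat X0;
  fmat sa[3]; fvec smu[3], sinv[3]; fmat sy[3];
  fmat pooled, emb;
  fmat cols[2];                 // concatenated im2col matrices
  fmat ta[2]; fvec tmu[2], tinv[2]; fmat ty[2];
  arma::umat mp_idx[2]; fmat mp_out[2];
  int Pc[4];                    // spatial sizes: P, P/2, P/2, P/4
  fmat ap_out, F, Fd, H1, H1d;
  fmat dmask1, dmask2;
  frowvec y;
};

static frowvec forward(Net& net, Cache& cc, bool train, std::mt19937* rng) {
  const NetCfg& c = net.cfg;
  int nb = c.nb, B = cc.B, P = cc.P;
  int Npix = cc.Npix;                     // P*P*B

  // spectral encoder
  const fmat* in = &cc.X0;
  for (int l = 0; l < 3; ++l) {
    cc.sa[l] = conv1d_fwd(net.s[l], *in, nb, Npix);
    cc.sy[l] = bn_relu_fwd(net.bn[l], cc.sa[l], train, cc.smu[l], cc.sinv[l]);
    in = &cc.sy[l];
  }
  // adaptive average pool nb -> L (band-block columns of width c3)
  int c3 = c.sc[2];
  cc.pooled.zeros((arma::uword)Npix, (arma::uword)c3 * c.L);
  for (int i = 0; i < c.L; ++i) {
    int s, e; adaptive_window(i, nb, c.L, s, e);
    fmat Pv = cview(cc.pooled, (arma::uword)i * c3, c3);
    for (int b = s; b < e; ++b) {
      Pv += cview(*in, (arma::uword)b * c3, c3) / (float)(e - s);
    }
  }
  // average over the L pooled positions -> one embedding per pixel;
  // transpose to (channels, pixels) for the spatial stage
  fmat embN((arma::uword)Npix, c3, arma::fill::zeros);
  for (int i = 0; i < c.L; ++i) {
    embN += cview(cc.pooled, (arma::uword)i * c3, c3) / (float)c.L;
  }
  cc.emb = embN.t();

  // spatial stage
  cc.Pc[0] = P;
  const fmat* sp_in = &cc.emb;
  for (int l = 0; l < 2; ++l) {
    int Pl = cc.Pc[2 * l];
    int ch_in = net.t[l].in, ch_out = net.t[l].out;
    arma::uword P2 = (arma::uword)Pl * Pl;
    cc.cols[l].set_size(ch_in * 9, P2 * B);
    fmat z(ch_out, P2 * B);
    fmat Ctmp;
    for (int n = 0; n < B; ++n) {
      im2col3(sp_in->cols(n * P2, (n + 1) * P2 - 1), ch_in, Pl, Ctmp);
      cc.cols[l].cols(n * P2, (n + 1) * P2 - 1) = Ctmp;
      z.cols(n * P2, (n + 1) * P2 - 1) = net.t[l].W * Ctmp;
    }
    z.each_col() += net.t[l].b;
    cc.ta[l] = z;
    cc.ty[l] = bn_relu_fwd(net.bn[3 + l], cc.ta[l], train, cc.tmu[l], cc.tinv[l]);
    // 2x2 max pool
    int Po = Pl / 2;
    cc.Pc[2 * l + 1] = Po;
    arma::uword Po2 = (arma::uword)Po * Po;
    cc.mp_out[l].set_size(ch_out, Po2 * B);
    cc.mp_idx[l].set_size(ch_out, Po2 * B);
    for (int n = 0; n < B; ++n) {
      for (int oc = 0; oc < Po; ++oc) {
        for (int orr = 0; orr < Po; ++orr) {
          arma::uword dst = (arma::uword)n * Po2 + (arma::uword)oc * Po + orr;
          arma::uword s00 = (arma::uword)n * Pl * Pl + (arma::uword)(2 * oc) * Pl + 2 * orr;
          arma::uword cand[4] = {s00, s00 + 1, s00 + Pl, s00 + Pl + 1};
          for (int ch = 0; ch < ch_out; ++ch) {
            float best = cc.ty[l](ch, cand[0]); arma::uword bi = cand[0];
            for (int j = 1; j < 4; ++j) {
              float v = cc.ty[l](ch, cand[j]);
              if (v > best) { best = v; bi = cand[j]; }
            }
            cc.mp_out[l](ch, dst) = best;
            cc.mp_idx[l](ch, dst) = bi;
          }
        }
      }
    }
    sp_in = &cc.mp_out[l];
    if (l == 0) cc.Pc[2] = Po;
  }
  // adaptive average pool to q x q
  int m = cc.Pc[3], q = c.q, ch2 = c.tc[1];
  arma::uword q2 = (arma::uword)q * q, m2 = (arma::uword)m * m;
  cc.ap_out.zeros(ch2, q2 * B);
  for (int n = 0; n < B; ++n) {
    for (int oc = 0; oc < q; ++oc) {
      int sc0, ec0; adaptive_window(oc, m, q, sc0, ec0);
      for (int orr = 0; orr < q; ++orr) {
        int sr, er; adaptive_window(orr, m, q, sr, er);
        arma::uword dst = (arma::uword)n * q2 + (arma::uword)oc * q + orr;
        float w = 1.0f / ((ec0 - sc0) * (er - sr));
        for (int ic = sc0; ic < ec0; ++ic) {
          for (int ir = sr; ir < er; ++ir) {
            cc.ap_out.col(dst) += w * cc.mp_out[1].col((arma::uword)n * m2 + (arma::uword)ic * m + ir);
          }
        }
      }
    }
  }
  // flatten + head
  int feat = ch2 * q2;
  cc.F.set_size(feat, B);
  for (int n = 0; n < B; ++n) {
    cc.F.col(n) = arma::vectorise(cc.ap_out.cols(n * q2, (n + 1) * q2 - 1));
  }
  float keep = 1.0f - c.drop;
  if (train && c.drop > 0 && rng) {
    std::uniform_real_distribution<float> ud(0.0f, 1.0f);
    cc.dmask1.set_size(cc.F.n_rows, cc.F.n_cols);
    for (arma::uword i = 0; i < cc.dmask1.n_elem; ++i)
      cc.dmask1(i) = ud(*rng) < keep ? 1.0f / keep : 0.0f;
    cc.Fd = cc.F % cc.dmask1;
  } else cc.Fd = cc.F;
  fmat h = net.h1.W * cc.Fd;
  h.each_col() += net.h1.b;
  cc.H1 = arma::clamp(h, 0.0f, std::numeric_limits<float>::max());
  if (train && c.drop > 0 && rng) {
    std::uniform_real_distribution<float> ud(0.0f, 1.0f);
    cc.dmask2.set_size(cc.H1.n_rows, cc.H1.n_cols);
    for (arma::uword i = 0; i < cc.dmask2.n_elem; ++i)
      cc.dmask2(i) = ud(*rng) < keep ? 1.0f / keep : 0.0f;
    cc.H1d = cc.H1 % cc.dmask2;
  } else cc.H1d = cc.H1;
  fmat yy = net.h2.W * cc.H1d;
  yy += net.h2.b(0);
  cc.y = yy.row(0);
  return cc.y;
}

// backward from dy (1 x B); fills g (gradient net); optionally returns dX0
static void backward(Net& net, Cache& cc, const frowvec& dy, Net& g,
                     bool train, bool want_dx, fmat& dX0) {
  const NetCfg& c = net.cfg;
  int nb = c.nb, B = cc.B;
  int Npix = cc.Npix;
  bool dropped = cc.dmask1.n_elem > 0;

  // head
  fmat dYrow(1, B);
  dYrow.row(0) = dy;
  g.h2.W = dYrow * cc.H1d.t();
  g.h2.b = arma::sum(dYrow, 1);
  fmat dH1d = net.h2.W.t() * dYrow;
  if (dropped) dH1d %= cc.dmask2;
  fmat dH = dH1d % arma::conv_to<fmat>::from(cc.H1 > 0);
  g.h1.W = dH * cc.Fd.t();
  g.h1.b = arma::sum(dH, 1);
  fmat dFd = net.h1.W.t() * dH;
  if (dropped) dFd %= cc.dmask1;

  // un-flatten
  int ch2 = c.tc[1], q = c.q;
  arma::uword q2 = (arma::uword)q * q;
  fmat dAp(ch2, q2 * B);
  for (int n = 0; n < B; ++n) {
    dAp.cols(n * q2, (n + 1) * q2 - 1) =
      arma::reshape(dFd.col(n), ch2, q2);
  }
  // adaptive pool 2d backward
  int m = cc.Pc[3];
  arma::uword m2 = (arma::uword)m * m;
  fmat dMp1(ch2, m2 * B, arma::fill::zeros);
  for (int n = 0; n < B; ++n) {
    for (int oc = 0; oc < q; ++oc) {
      int sc0, ec0; adaptive_window(oc, m, q, sc0, ec0);
      for (int orr = 0; orr < q; ++orr) {
        int sr, er; adaptive_window(orr, m, q, sr, er);
        arma::uword src = (arma::uword)n * q2 + (arma::uword)oc * q + orr;
        float w = 1.0f / ((ec0 - sc0) * (er - sr));
        for (int ic = sc0; ic < ec0; ++ic) {
          for (int ir = sr; ir < er; ++ir) {
            dMp1.col((arma::uword)n * m2 + (arma::uword)ic * m + ir) += w * dAp.col(src);
          }
        }
      }
    }
  }

  // spatial blocks, reverse order
  fmat dPool = dMp1;
  fmat dEmb;
  for (int l = 1; l >= 0; --l) {
    int Pl = cc.Pc[2 * l];
    arma::uword P2 = (arma::uword)Pl * Pl;
    int ch_out = net.t[l].out, ch_in = net.t[l].in;
    // max pool backward
    fmat dTy(ch_out, P2 * B, arma::fill::zeros);
    for (arma::uword j = 0; j < cc.mp_idx[l].n_cols; ++j) {
      for (int ch = 0; ch < ch_out; ++ch) {
        dTy(ch, cc.mp_idx[l](ch, j)) += dPool(ch, j);
      }
    }
    fvec dg_, dbe_;
    fmat dZ = bn_relu_bwd(net.bn[3 + l], cc.ta[l], dTy, cc.tmu[l], cc.tinv[l], dg_, dbe_, train);
    g.bn[3 + l].g = dg_; g.bn[3 + l].be = dbe_;
    g.t[l].W.zeros(ch_out, ch_in * 9);
    g.t[l].b = arma::sum(dZ, 1);
    fmat dIn(ch_in, P2 * B, arma::fill::zeros);
    for (int n = 0; n < B; ++n) {
      fmat dZn = dZ.cols(n * P2, (n + 1) * P2 - 1);
      g.t[l].W += dZn * cc.cols[l].cols(n * P2, (n + 1) * P2 - 1).t();
      fmat dC = net.t[l].W.t() * dZn;
      fmat dImg(ch_in, P2, arma::fill::zeros);
      col2im3(dC, ch_in, Pl, dImg);
      dIn.cols(n * P2, (n + 1) * P2 - 1) = dImg;
    }
    if (l == 1) dPool = dIn; else dEmb = dIn;
  }

  // spectral average + adaptive pool 1d backward
  int c3 = c.sc[2];
  fmat dEmbN = dEmb.t() / (float)c.L;        // (Npix, c3)
  fmat dSy((arma::uword)Npix, (arma::uword)c3 * nb, arma::fill::zeros);
  for (int i = 0; i < c.L; ++i) {
    int s, e; adaptive_window(i, nb, c.L, s, e);
    for (int b = s; b < e; ++b) {
      fmat v = cview(dSy, (arma::uword)b * c3, c3);
      v += dEmbN / (float)(e - s);
    }
  }

  // spectral conv stack, reverse
  fmat dOut = dSy;
  for (int l = 2; l >= 0; --l) {
    fvec dg_, dbe_;
    fmat dZ = bn_relu_bwd(net.bn[l], cc.sa[l], dOut, cc.smu[l], cc.sinv[l], dg_, dbe_, train);
    g.bn[l].g = dg_; g.bn[l].be = dbe_;
    const fmat& In = (l == 0) ? cc.X0 : cc.sy[l - 1];
    bool need_din = (l > 0) || want_dx;
    fmat dIn;
    conv1d_bwd(net.s[l], In, dZ, g.s[l].W, g.s[l].b, need_din ? &dIn : nullptr, nb, Npix);
    if (l > 0) dOut = dIn; else if (want_dx) dX0 = dIn;
  }
}

// gather an R patch matrix column (nb*P*P values, band fastest) into the
// band-major-block layout of X0, with optional spatial flips
static void gather_sample(const fmat& Xall, arma::uword col, int nb, int P,
                          fmat& X0, int n, int B, bool flip_r, bool flip_c) {
  arma::uword P2 = (arma::uword)P * P;
  arma::uword Npix = P2 * B;
  const float* src = Xall.colptr(col);
  float* dst = X0.memptr();
  // band-outer loop: contiguous writes per band, strided cache-resident reads
  for (int b = 0; b < nb; ++b) {
    float* db_ = dst + (arma::uword)b * Npix + (arma::uword)n * P2;
    for (int cpos = 0; cpos < P; ++cpos) {
      int cs = flip_c ? P - 1 - cpos : cpos;
      const float* sc_ = src + (arma::uword)nb * cs * P + b;
      float* dc = db_ + (arma::uword)cpos * P;
      if (!flip_r) {
        for (int r = 0; r < P; ++r) dc[r] = sc_[(arma::uword)nb * r];
      } else {
        for (int r = 0; r < P; ++r) dc[r] = sc_[(arma::uword)nb * (P - 1 - r)];
      }
    }
  }
}

static fmat as_patch_matrix(const Rcpp::NumericVector& x, int nb, int P, int N) {
  fmat out(nb * P * P, N);
  const double* p = x.begin();
  for (arma::uword i = 0; i < out.n_elem; ++i) out(i) = (float)p[i];
  return out;
}

static frowvec predict_all(Net& net, const fmat& Xall, int nb, int P,
                           int chunk = 16) {
  int N = Xall.n_cols;
  frowvec out(N);
  for (int s = 0; s < N; s += chunk) {
    int B = std::min(chunk, N - s);
    Cache cc; cc.B = B; cc.P = P; cc.Npix = P * P * B;
    cc.X0.set_size((arma::uword)cc.Npix, nb);
    for (int n = 0; n < B; ++n) gather_sample(Xall, s + n, nb, P, cc.X0, n, B, false, false);
    frowvec y = forward(net, cc, false, nullptr);
    out.subvec(s, s + B - 1) = y;
  }
  return out;
}

// ---- exported entry points ---------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_cnn_init(Rcpp::List cfg, int seed) {
  Net n = make_net(parse_cfg(cfg), (unsigned int)seed);
  return net_to_list(n);
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::List cfg, Rcpp::List weights,
                         Rcpp::NumericVector x_train, Rcpp::NumericVector y_train,
                         Rcpp::IntegerVector dim_train,
                         Rcpp::NumericVector x_val, Rcpp::NumericVector y_val,
                         Rcpp::IntegerVector dim_val,
                         Rcpp::List tcfg) {
  keep_large_allocs();
  NetCfg c = parse_cfg(cfg);
  Net net = list_to_net(c, weights);
  int nb = dim_train[0], P = dim_train[1], Ntr = dim_train[3];
  int Nval = dim_val[3];
  if (nb != c.nb) Rcpp::stop("input band count %d does not match config n_bands %d", nb, c.nb);
  fmat Xtr = as_patch_matrix(x_train, nb, P, Ntr);
  fmat Xval = as_patch_matrix(x_val, nb, P, Nval);
  fvec ytr = Rcpp::as<fvec>(y_train);
  fvec yval = Rcpp::as<fvec>(y_val);

  // standardize inputs with training-set statistics (stored in the
  // returned model and applied at prediction time)
  double in_mean = arma::mean(arma::conv_to<arma::vec>::from(arma::vectorise(Xtr)));
  double in_sd = arma::stddev(arma::conv_to<arma::vec>::from(arma::vectorise(Xtr)));
  if (!(in_sd > 0)) in_sd = 1.0;
  Xtr = (Xtr - (float)in_mean) / (float)in_sd;
  Xval = (Xval - (float)in_mean) / (float)in_sd;
  // start the regression head at the training-mean age
  net.h2.b(0) = arma::mean(ytr);

  double lr = Rcpp::as<double>(tcfg["lr"]);
  std::string lr_schedule = tcfg.containsElementNamed("lr_schedule") ?
    Rcpp::as<std::string>(tcfg["lr_schedule"]) : std::string("constant");
  double lr_end = tcfg.containsElementNamed("lr_end") ?
    Rcpp::as<double>(tcfg["lr_end"]) : lr / 20.0;
  int bs = Rcpp::as<int>(tcfg["batch_size"]);
  double wd = Rcpp::as<double>(tcfg["weight_decay"]);
  int max_epochs = Rcpp::as<int>(tcfg["max_epochs"]);
  int patience = Rcpp::as<int>(tcfg["patience"]);
  double min_delta = Rcpp::as<double>(tcfg["min_delta"]);
  bool augment = Rcpp::as<bool>(tcfg["augment"]);
  unsigned int seed = (unsigned int)Rcpp::as<int>(tcfg["seed"]);

  std::mt19937 rng(seed);
  std::uniform_real_distribution<float> ud(0.0f, 1.0f);

  // Adam state
  Net gnet = make_net(c, 0u);
  std::vector<arma::Mat<float>*> params, grads;
  net.reg(params); gnet.reg(grads);
  std::vector<fmat> mstate(params.size()), vstate(params.size());
  for (size_t i = 0; i < params.size(); ++i) {
    mstate[i].zeros(params[i]->n_rows, params[i]->n_cols);
    vstate[i].zeros(params[i]->n_rows, params[i]->n_cols);
  }
  const float b1 = 0.9f, b2 = 0.999f, adam_eps = 1e-8f;
  long step = 0;

  std::vector<double> hist_loss, hist_val;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = -1, since = 0;
  Rcpp::List best_weights = net_to_list(net);

  std::vector<int> order(Ntr);
  for (int i = 0; i < Ntr; ++i) order[i] = i;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double lr_now = lr;
    if (lr_schedule == "cosine" && max_epochs > 1) {
      lr_now = lr_end + (lr - lr_end) *
               0.5 * (1.0 + std::cos(M_PI * epoch / (max_epochs - 1)));
    }
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; int n_batches = 0;
    for (int s = 0; s < Ntr; s += bs) {
      int B = std::min(bs, Ntr - s);
      Cache cc; cc.B = B; cc.P = P; cc.Npix = P * P * B;
      cc.X0.set_size((arma::uword)cc.Npix, nb);
      fvec t(B);
      for (int n = 0; n < B; ++n) {
        bool fr = augment && ud(rng) < 0.5f;
        bool fc = augment && ud(rng) < 0.5f;
        gather_sample(Xtr, order[s + n], nb, P, cc.X0, n, B, fr, fc);
        t(n) = ytr(order[s + n]);
      }
      frowvec y = forward(net, cc, true, &rng);
      frowvec err = y - t.t();
      ep_loss += arma::mean(arma::square(err));
      n_batches++;
      frowvec dy = 2.0f * err / (float)B;
      fmat dX0_unused;
      backward(net, cc, dy, gnet, true, false, dX0_unused);
      // clip the global gradient norm (tames loss spikes from ReLU/BN
      // interactions on small batches)
      double gnorm2 = 0;
      for (size_t i = 0; i < grads.size(); ++i) {
        gnorm2 += arma::accu(arma::square(
          arma::conv_to<arma::mat>::from(*grads[i])));
      }
      double gnorm = std::sqrt(gnorm2);
      const double clip = 25.0;
      if (gnorm > clip) {
        float sc_ = (float)(clip / gnorm);
        for (size_t i = 0; i < grads.size(); ++i) *grads[i] *= sc_;
      }
      // Adam with L2 weight decay on all trainable params
      step++;
      float bc1 = 1.0f - std::pow(b1, (float)step);
      float bc2 = 1.0f - std::pow(b2, (float)step);
      for (size_t i = 0; i < params.size(); ++i) {
        fmat gr = *grads[i] + (float)wd * (*params[i]);
        mstate[i] = b1 * mstate[i] + (1.0f - b1) * gr;
        vstate[i] = b2 * vstate[i] + (1.0f - b2) * arma::square(gr);
        *params[i] -= (float)lr_now * (mstate[i] / bc1) /
                      (arma::sqrt(vstate[i] / bc2) + adam_eps);
      }
    }
    hist_loss.push_back(ep_loss / std::max(n_batches, 1));
    frowvec pv = predict_all(net, Xval, nb, P);
    double val_mae = arma::mean(arma::abs(pv - yval.t()));
    hist_val.push_back(val_mae);
    if (val_mae < best_val - min_delta) {
      best_val = val_mae;
      best_epoch = epoch;
      best_weights = net_to_list(net);
      since = 0;
    } else {
      since++;
      if (since >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (best_epoch < 0) best_weights = net_to_list(net);
  return Rcpp::List::create(
    Rcpp::Named("weights") = best_weights,
    Rcpp::Named("train_loss") = hist_loss,
    Rcpp::Named("val_mae") = hist_val,
    Rcpp::Named("best_epoch") = best_epoch + 1,
    Rcpp::Named("best_val_mae") = best_val,
    Rcpp::Named("in_mean") = in_mean,
    Rcpp::Named("in_sd") = in_sd
  );
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_cnn_predict(Rcpp::List cfg, Rcpp::List weights,
                                    Rcpp::NumericVector x, Rcpp::IntegerVector dims) {
  keep_large_allocs();
  NetCfg c = parse_cfg(cfg);
  Net net = list_to_net(c, weights);
  int nb = dims[0], P = dims[1], N = dims[3];
  if (nb != c.nb) Rcpp::stop("input band count %d does not match config n_bands %d", nb, c.nb);
  fmat Xall = as_patch_matrix(x, nb, P, N);
  frowvec y = predict_all(net, Xall, nb, P);
  Rcpp::NumericVector out(N);
  for (int i = 0; i < N; ++i) out[i] = y(i);
  return out;
}

// gradient of the scalar output w.r.t. the input patch, per sample,
// computed in inference mode (running BN statistics, no dropout)
// [[Rcpp::export]]
Rcpp::NumericVector cpp_cnn_input_grad(Rcpp::List cfg, Rcpp::List weights,
                                       Rcpp::NumericVector x, Rcpp::IntegerVector dims) {
  keep_large_allocs();
  NetCfg c = parse_cfg(cfg);
  Net net = list_to_net(c, weights);
  int nb = dims[0], P = dims[1], N = dims[3];
  if (nb != c.nb) Rcpp::stop("input band count %d does not match config n_bands %d", nb, c.nb);
  fmat Xall = as_patch_matrix(x, nb, P, N);
  Net gnet = make_net(c, 0u);
  Rcpp::NumericVector out(x.size());
  int chunk = 8;
  arma::uword P2 = (arma::uword)P * P;
  for (int s = 0; s < N; s += chunk) {
    int B = std::min(chunk, N - s);
    Cache cc; cc.B = B; cc.P = P; cc.Npix = P * P * B;
    cc.X0.set_size((arma::uword)cc.Npix, nb);
    for (int n = 0; n < B; ++n) gather_sample(Xall, s + n, nb, P, cc.X0, n, B, false, false);
    forward(net, cc, false, nullptr);
    frowvec dy(B, arma::fill::ones);
    fmat dX0;
    backward(net, cc, dy, gnet, false, true, dX0);
    // scatter back to R layout (band fastest within pixel)
    arma::uword Npix = cc.Npix;
    for (int n = 0; n < B; ++n) {
      double* dst = out.begin() + ((arma::uword)(s + n)) * nb * P2;
      for (arma::uword p = 0; p < P2; ++p) {
        arma::uword pix = (arma::uword)n * P2 + p;
        for (int b = 0; b < nb; ++b) dst[nb * p + b] = dX0.memptr()[(arma::uword)b * Npix + pix];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// layer-by-layer shape trace of an actual forward pass on one sample
// [[Rcpp::export]]
Rcpp::List cpp_cnn_trace(Rcpp::List cfg, Rcpp::List weights,
                         Rcpp::NumericVector x, Rcpp::IntegerVector dims) {
  keep_large_allocs();
  NetCfg c = parse_cfg(cfg);
  Net net = list_to_net(c, weights);
  int nb = dims[0], P = dims[1];
  if (nb != c.nb) Rcpp::stop("input band count %d does not match config n_bands %d", nb, c.nb);
  fmat Xall = as_patch_matrix(x, nb, P, 1);
  Cache cc; cc.B = 1; cc.P = P; cc.Npix = P * P;
  cc.X0.set_size((arma::uword)cc.Npix, nb);
  gather_sample(Xall, 0, nb, P, cc.X0, 0, 1, false, false);
  forward(net, cc, false, nullptr);
  auto iv = [](std::initializer_list<int> v) { return Rcpp::IntegerVector(v); };
  Rcpp::List tr;
  tr["input"] = iv({nb, P, P});
  tr["pixel_reshape"] = iv({1, nb});
  for (int l = 0; l < 3; ++l) {
    tr[std::string("spec_conv") + std::to_string(l + 1)] =
      iv({(int)(cc.sy[l].n_cols / nb), nb});
  }
  tr["spec_pool"] = iv({(int)(cc.pooled.n_cols / c.L), c.L});
  tr["spec_average"] = iv({(int)cc.emb.n_rows});
  tr["embedding_map"] = iv({(int)cc.emb.n_rows, P, P});
  tr["spat_conv1"] = iv({(int)cc.ty[0].n_rows, cc.Pc[0], cc.Pc[0]});
  tr["maxpool1"] = iv({(int)cc.mp_out[0].n_rows, cc.Pc[1], cc.Pc[1]});
  tr["spat_conv2"] = iv({(int)cc.ty[1].n_rows, cc.Pc[2], cc.Pc[2]});
  tr["maxpool2"] = iv({(int)cc.mp_out[1].n_rows, cc.Pc[3], cc.Pc[3]});
  tr["adaptive_pool"] = iv({(int)cc.ap_out.n_rows, c.q, c.q});
  tr["flatten"] = iv({(int)cc.F.n_rows});
  tr["linear1"] = iv({(int)cc.H1.n_rows});
  tr["linear2"] = iv({1});
  return tr;
}

// training-mode loss and full parameter gradient for one batch; used by
// the finite-difference gradient checks in the test suite
// [[Rcpp::export]]
Rcpp::List cpp_cnn_loss_grad(Rcpp::List cfg, Rcpp::List weights,
                             Rcpp::NumericVector x, Rcpp::NumericVector y,
                             Rcpp::IntegerVector dims, bool want_input_grad = false) {
  keep_large_allocs();
  NetCfg c = parse_cfg(cfg);
  Net net = list_to_net(c, weights);
  int nb = dims[0], P = dims[1], N = dims[3];
  fmat Xall = as_patch_matrix(x, nb, P, N);
  fvec yt = Rcpp::as<fvec>(y);
  Cache cc; cc.B = N; cc.P = P; cc.Npix = P * P * N;
  cc.X0.set_size((arma::uword)cc.Npix, nb);
  for (int n = 0; n < N; ++n) gather_sample(Xall, n, nb, P, cc.X0, n, N, false, false);
  frowvec yy = forward(net, cc, true, nullptr);   // no dropout without rng
  frowvec err = yy - yt.t();
  double loss = arma::mean(arma::square(err));
  frowvec dy = 2.0f * err / (float)N;
  Net gnet = make_net(c, 0u);
  fmat dX0;
  backward(net, cc, dy, gnet, true, want_input_grad, dX0);
  Rcpp::List out;
  out["loss"] = loss;
  out["grad"] = net_to_list(gnet);
  if (want_input_grad) {
    Rcpp::NumericVector gx(x.size());
    arma::uword P2 = (arma::uword)P * P;
    for (int n = 0; n < N; ++n) {
      double* dst = gx.begin() + ((arma::uword)n) * nb * P2;
      for (arma::uword p = 0; p < P2; ++p) {
        arma::uword pix = (arma::uword)n * P2 + p;
        for (int b = 0; b < nb; ++b) dst[nb * p + b] = dX0.memptr()[(arma::uword)b * cc.Npix + pix];
      }
    }
    gx.attr("dim") = dims;
    out["input_grad"] = gx;
  }
  return out;
}
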