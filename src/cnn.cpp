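// Lightweight attention-fusion separable-convolution network: forward,
// hand-derived backprop and Adam, in single precision.
//
// Architecture (input H x W x 3, "same" 3x3 depthwise + 1x1 pointwise
// convolutions, ReLU, 2x2 floor max-pool):
//   block1 -> 32 ch, block2 -> 64 ch, block3 -> 128 ch
//   per-block branch: flatten(pooled) -> dense(32) -> layer norm
//   stack 3 branches; shared dense(32, ReLU); shared dense(1) -> 3 logits
//   softmax attention; fused = sum_b alpha_b * branch_b; dense(1, sigmoid)
//
// Activation layout: a whole batch is one (nb*H*W, C) float matrix, samples
// stacked along the rows of each channel column, so every pointwise
// convolution and dense layer is a single BLAS gemm; the depthwise stencil
// and max-pool walk per-sample column segments. All randomness (init,
// shuffling) comes from R; this file is deterministic given its inputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerMatrix;

static const char* WEIGHT_NAMES[] = {
  "dw1", "pw1", "b1", "dw2", "pw2", "b2", "dw3", "pw3", "b3",
  "Wd1", "bd1", "Wd2", "bd2", "Wd3", "bd3",
  "g1", "be1", "g2", "be2", "g3", "be3",
  "Wt1", "bt1", "wt2", "bt2", "wo", "bo"};
static const int N_WEIGHTS = 27;

static field<fmat> weights_from_list(const List& w) {
  field<fmat> out(N_WEIGHTS);
  for (int i = 0; i < N_WEIGHTS; ++i) {
    NumericMatrix m = Rcpp::as<NumericMatrix>(w[WEIGHT_NAMES[i]]);
    fmat f(m.nrow(), m.ncol());
    for (R_xlen_t j = 0; j < (R_xlen_t)m.nrow() * m.ncol(); ++j) {
      f.memptr()[j] = (float)m[j];
    }
    out(i) = f;
  }
  return out;
}

static List weights_to_list(const field<fmat>& w) {
  List out;
  for (int i = 0; i < N_WEIGHTS; ++i) {
    NumericMatrix m(w(i).n_rows, w(i).n_cols);
    for (uword j = 0; j < w(i).n_elem; ++j) m[j] = (double)w(i).memptr()[j];
    out[WEIGHT_NAMES[i]] = m;
  }
  return out;
}

// 3x3 depthwise correlation of one H x W plane, zero padding; k holds the 9
// taps with index r = (dy+1) + 3*(dx+1). One fused pass: one read of the
// 3-column neighbourhood, one write.
static void dw_plane(const float* src, float* dst, const float* k, int H,
                     int W, const float* zcol) {
  for (int x = 0; x < W; ++x) {
    const float* cL = (x > 0) ? src + (size_t)(x - 1) * H : zcol;
    const float* cC = src + (size_t)x * H;
    const float* cR = (x < W - 1) ? src + (size_t)(x + 1) * H : zcol;
    float* o = dst + (size_t)x * H;
    o[0] = k[1] * cL[0] + k[4] * cC[0] + k[7] * cR[0] +
           (H > 1 ? k[2] * cL[1] + k[5] * cC[1] + k[8] * cR[1] : 0.0f);
    for (int y = 1; y < H - 1; ++y) {
      o[y] = k[0] * cL[y - 1] + k[1] * cL[y] + k[2] * cL[y + 1] +
             k[3] * cC[y - 1] + k[4] * cC[y] + k[5] * cC[y + 1] +
             k[6] * cR[y - 1] + k[7] * cR[y] + k[8] * cR[y + 1];
    }
    if (H > 1) {
      const int y = H - 1;
      o[y] = k[0] * cL[y - 1] + k[1] * cL[y] +
             k[3] * cC[y - 1] + k[4] * cC[y] +
             k[6] * cR[y - 1] + k[7] * cR[y];
    }
  }
}

// accumulate the 9 kernel gradients of one plane: dK(r) += sum src(p+r)*g(p)
static void dw_plane_kgrad(const float* src, const float* g, float* acc,
                           int H, int W, const float* zcol) {
  for (int x = 0; x < W; ++x) {
    const float* cL = (x > 0) ? src + (size_t)(x - 1) * H : zcol;
    const float* cC = src + (size_t)x * H;
    const float* cR = (x < W - 1) ? src + (size_t)(x + 1) * H : zcol;
    const float* go = g + (size_t)x * H;
    {
      const float gv = go[0];
      acc[1] += cL[0] * gv; acc[4] += cC[0] * gv; acc[7] += cR[0] * gv;
      if (H > 1) {
        acc[2] += cL[1] * gv; acc[5] += cC[1] * gv; acc[8] += cR[1] * gv;
      }
    }
    for (int y = 1; y < H - 1; ++y) {
      const float gv = go[y];
      acc[0] += cL[y - 1] * gv; acc[1] += cL[y] * gv; acc[2] += cL[y + 1] * gv;
      acc[3] += cC[y - 1] * gv; acc[4] += cC[y] * gv; acc[5] += cC[y + 1] * gv;
      acc[6] += cR[y - 1] * gv; acc[7] += cR[y] * gv; acc[8] += cR[y + 1] * gv;
    }
    if (H > 1) {
      const int y = H - 1;
      const float gv = go[y];
      acc[0] += cL[y - 1] * gv; acc[1] += cL[y] * gv;
      acc[3] += cC[y - 1] * gv; acc[4] += cC[y] * gv;
      acc[6] += cR[y - 1] * gv; acc[7] += cR[y] * gv;
    }
  }
}

// batch depthwise conv: in/out are (nb*H*W, C), sample s occupying the row
// segment [s*H*W, (s+1)*H*W) of each channel column
static void dwconv_fwd(const fmat& in, const fmat& K9, int H, int W, int nb,
                       fmat& out) {
  const int C = in.n_cols;
  const size_t HW = (size_t)H * W;
  out.set_size(in.n_rows, C);
  std::vector<float> zcol(H, 0.0f);
  for (int c = 0; c < C; ++c) {
    const float* k = K9.colptr(c);
    for (int s = 0; s < nb; ++s) {
      dw_plane(in.colptr(c) + s * HW, out.colptr(c) + s * HW, k, H, W,
               zcol.data());
    }
  }
}

// gradient w.r.t. the depthwise input: the forward stencil with the 9 taps
// point-reflected
static void dwconv_bwd_input(const fmat& dout, const fmat& K9, int H, int W,
                             int nb, fmat& din) {
  const fmat Kflip = flipud(K9);
  dwconv_fwd(dout, Kflip, H, W, nb, din);
}

static void dwconv_bwd_kernel(const fmat& in, const fmat& dout, int H, int W,
                              int nb, fmat& dK9) {
  const int C = in.n_cols;
  const size_t HW = (size_t)H * W;
  std::vector<float> zcol(H, 0.0f);
  for (int c = 0; c < C; ++c) {
    float acc[9] = {0};
    for (int s = 0; s < nb; ++s) {
      dw_plane_kgrad(in.colptr(c) + s * HW, dout.colptr(c) + s * HW, acc,
                     H, W, zcol.data());
    }
    for (int r = 0; r < 9; ++r) dK9(r, c) += acc[r];
  }
}

// batch 2x2 max-pool with floor division; argmax recorded as the linear
// index within the sample's H x W plane
static void maxpool_fwd(const fmat& in, int H, int W, int nb, fmat& out,
                        Mat<unsigned int>& idx) {
  const int C = in.n_cols, H2 = H / 2, W2 = W / 2;
  const size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
  out.set_size(nb * HW2, C);
  idx.set_size(nb * HW2, C);
  for (int c = 0; c < C; ++c) {
    for (int s = 0; s < nb; ++s) {
      const float* src = in.colptr(c) + s * HW;
      float* dst = out.colptr(c) + s * HW2;
      unsigned int* id = idx.colptr(c) + s * HW2;
      for (int x = 0; x < W2; ++x) {
        for (int y = 0; y < H2; ++y) {
          const int base = 2 * y + 2 * x * H;
          const int cand[4] = {base, base + 1, base + H, base + H + 1};
          int best = cand[0];
          float bv = src[cand[0]];
          for (int t = 1; t < 4; ++t) {
            if (src[cand[t]] > bv) { bv = src[cand[t]]; best = cand[t]; }
          }
          dst[y + x * H2] = bv;
          id[y + x * H2] = (unsigned int)best;
        }
      }
    }
  }
}

static void maxpool_bwd(const fmat& dout, const Mat<unsigned int>& idx,
                        int H, int W, int nb, fmat& din) {
  const int C = dout.n_cols;
  const size_t HW = (size_t)H * W;
  const size_t HW2 = dout.n_rows / nb;
  din.zeros(nb * HW, C);
  for (int c = 0; c < C; ++c) {
    for (int s = 0; s < nb; ++s) {
      const float* g = dout.colptr(c) + s * HW2;
      const unsigned int* id = idx.colptr(c) + s * HW2;
      float* dst = din.colptr(c) + s * HW;
      for (size_t i = 0; i < HW2; ++i) dst[id[i]] += g[i];
    }
  }
}

// whole-batch cache of one separable-conv block
struct BlockCache {
  fmat u;                  // depthwise output (nb*HW, Cin)
  fmat a;                  // post-ReLU pointwise output (nb*HW, Cout)
  fmat p;                  // pooled output (nb*H2W2, Cout)
  Mat<unsigned int> idx;   // pool argmax
};

static void block_fwd(const fmat& x, const fmat& K9, const fmat& pw,
                      const fmat& b, int H, int W, int nb, BlockCache& cc) {
  dwconv_fwd(x, K9, H, W, nb, cc.u);
  cc.a = cc.u * pw;
  cc.a.each_row() += conv_to<frowvec>::from(b);
  float* ap = cc.a.memptr();
  for (uword i = 0; i < cc.a.n_elem; ++i) ap[i] = ap[i] > 0.0f ? ap[i] : 0.0f;
  maxpool_fwd(cc.a, H, W, nb, cc.p, cc.idx);
}

// backward scratch reused across batches
struct BwdScratch {
  fmat da1, du1, da2, du2, dx2, da3, du3, dx3;
};

// backward through one block: accumulates dK9/dpw/db and, unless first,
// the gradient w.r.t. the block input
static void block_bwd(const BlockCache& cc, const fmat& x, const fmat& K9,
                      const fmat& pw, int H, int W, int nb, const fmat& dp,
                      fmat& dK9, fmat& dpw, fmat& db, fmat* dx, fmat& da,
                      fmat& du) {
  maxpool_bwd(dp, cc.idx, H, W, nb, da);
  {
    const float* ap = cc.a.memptr();
    float* dvp = da.memptr();
    for (uword i = 0; i < da.n_elem; ++i) if (ap[i] <= 0.0f) dvp[i] = 0.0f;
  }
  db += sum(da, 0).t();
  dpw += cc.u.t() * da;
  du = da * pw.t();
  dwconv_bwd_kernel(x, du, H, W, nb, dK9);
  if (dx != nullptr) dwconv_bwd_input(du, K9, H, W, nb, *dx);
}

struct HeadCache {
  fmat F1, F2, F3;       // flattened pooled maps, transposed (flat_j, nb)
  fmat D[3];             // dense outputs (nb, 32)
  fmat xhat[3];          // layer-norm normalized inputs
  fvec inv_sd[3];        // 1/sqrt(var + eps) per row
  fmat N[3];             // layer-norm outputs
  fmat A[3];             // shared ReLU dense outputs
  fmat Lg;               // branch logits (nb, 3)
  fmat alpha;            // attention weights (nb, 3)
  fmat fused;            // (nb, 32)
  fvec p;                // probabilities
};

static const float LN_EPS = 1e-5f;

static void head_fwd(const field<fmat>& w, HeadCache& hc) {
  const fmat* Wd[3] = {&w(9), &w(11), &w(13)};
  const fmat* bd[3] = {&w(10), &w(12), &w(14)};
  const fmat* Fj[3] = {&hc.F1, &hc.F2, &hc.F3};
  const int n = hc.F1.n_cols;
  for (int j = 0; j < 3; ++j) {
    hc.D[j] = Fj[j]->t() * (*Wd[j]);
    hc.D[j].each_row() += conv_to<frowvec>::from(*bd[j]);
    const fmat& g = w(15 + 2 * j);
    const fmat& be = w(16 + 2 * j);
    fvec mu = mean(hc.D[j], 1);
    fmat centered = hc.D[j];
    centered.each_col() -= mu;
    fvec var = mean(square(centered), 1);
    hc.inv_sd[j] = 1.0f / sqrt(var + LN_EPS);
    hc.xhat[j] = centered;
    hc.xhat[j].each_col() %= hc.inv_sd[j];
    hc.N[j] = hc.xhat[j];
    hc.N[j].each_row() %= conv_to<frowvec>::from(g);
    hc.N[j].each_row() += conv_to<frowvec>::from(be);
  }
  const fmat& Wt1 = w(21); const fmat& bt1 = w(22);
  const fmat& wt2 = w(23); const fmat& bt2 = w(24);
  hc.Lg.set_size(n, 3);
  for (int j = 0; j < 3; ++j) {
    fmat pre = hc.N[j] * Wt1;
    pre.each_row() += conv_to<frowvec>::from(bt1);
    hc.A[j] = clamp(pre, 0.0f, std::numeric_limits<float>::max());
    hc.Lg.col(j) = hc.A[j] * wt2 + bt2(0, 0);
  }
  fmat e = hc.Lg;
  e.each_col() -= max(hc.Lg, 1);
  e = exp(e);
  fvec esum = sum(e, 1);
  e.each_col() /= esum;
  hc.alpha = e;
  hc.fused.zeros(n, hc.N[0].n_cols);
  for (int j = 0; j < 3; ++j) {
    fmat tmp = hc.N[j];
    tmp.each_col() %= hc.alpha.col(j);
    hc.fused += tmp;
  }
  fvec z = hc.fused * w(25) + w(26)(0, 0);
  hc.p = 1.0f / (1.0f + exp(-z));
}

// backward through the head; fills per-branch flatten gradients (flat_j, nb)
static void head_bwd(const field<fmat>& w, const HeadCache& hc, const fvec& y,
                     field<fmat>& gr, fmat* dF) {
  const int n = hc.p.n_elem;
  const fmat& Wt1 = w(21); const fmat& wt2 = w(23);
  fvec dz = (hc.p - y) / (float)n;
  gr(25) += hc.fused.t() * dz;          // dwo
  gr(26)(0, 0) += accu(dz);             // dbo
  fmat dfused = dz * w(25).t();         // (n, 32)
  fmat dalpha(n, 3);
  fmat dN[3];
  for (int j = 0; j < 3; ++j) {
    dalpha.col(j) = sum(dfused % hc.N[j], 1);
    dN[j] = dfused;
    dN[j].each_col() %= hc.alpha.col(j);
  }
  fvec dot = sum(hc.alpha % dalpha, 1);
  fmat dl = dalpha;
  dl.each_col() -= dot;
  dl %= hc.alpha;
  for (int j = 0; j < 3; ++j) {
    fmat dA = dl.col(j) * wt2.t();
    fmat dpre = dA % conv_to<fmat>::from(hc.A[j] > 0.0f);
    gr(23) += hc.A[j].t() * dl.col(j);  // dwt2
    gr(24)(0, 0) += accu(dl.col(j));    // dbt2
    gr(21) += hc.N[j].t() * dpre;       // dWt1
    gr(22) += sum(dpre, 0).t();         // dbt1
    dN[j] += dpre * Wt1.t();
  }
  for (int j = 0; j < 3; ++j) {
    const fmat& g = w(15 + 2 * j);
    // layer norm backward over the feature axis
    fmat dxhat = dN[j];
    dxhat.each_row() %= conv_to<frowvec>::from(g);
    gr(15 + 2 * j) += sum(dN[j] % hc.xhat[j], 0).t();  // dgain
    gr(16 + 2 * j) += sum(dN[j], 0).t();               // dbias
    fvec m1 = mean(dxhat, 1);
    fvec m2 = mean(dxhat % hc.xhat[j], 1);
    fmat dD = dxhat;
    dD.each_col() -= m1;
    fmat xm2 = hc.xhat[j];
    xm2.each_col() %= m2;
    dD -= xm2;
    dD.each_col() %= hc.inv_sd[j];
    const fmat* Fj = (j == 0) ? &hc.F1 : (j == 1) ? &hc.F2 : &hc.F3;
    // the dense gradients are produced exactly once per batch, so they are
    // assigned, not accumulated (their zero-fill would dominate traffic)
    gr(9 + 2 * j) = (*Fj) * dD;          // dWd
    gr(10 + 2 * j) = sum(dD, 0).t();     // dbd
    dF[j] = w(9 + 2 * j) * dD.t();       // (flat_j, nb), column per sample
  }
}

struct Dims {
  int H, W;
  int H2, W2, H3, W3, H4, W4;
  int C1, C2, C3;
  Dims(int H_, int W_, const field<fmat>& w) : H(H_), W(W_) {
    H2 = H / 2; W2 = W / 2;
    H3 = H2 / 2; W3 = W2 / 2;
    H4 = H3 / 2; W4 = W3 / 2;
    C1 = w(1).n_cols; C2 = w(4).n_cols; C3 = w(7).n_cols;
  }
};

// copy pooled batch matrix (nb*HW2, C) into per-sample flatten columns
static void pooled_to_flat(const fmat& p, int nb, fmat& F) {
  const int C = p.n_cols;
  const size_t HW2 = p.n_rows / nb;
  F.set_size(HW2 * C, nb);
  for (int s = 0; s < nb; ++s) {
    float* dst = F.colptr(s);
    for (int c = 0; c < C; ++c) {
      std::memcpy(dst + c * HW2, p.colptr(c) + s * HW2, HW2 * sizeof(float));
    }
  }
}

// spread per-sample flatten gradient columns back into (nb*HW2, C)
static void flat_to_pooled(const fmat& dF, int nb, int C, fmat& dp) {
  const size_t HW2 = dF.n_rows / C;
  dp.set_size(nb * HW2, C);
  for (int s = 0; s < nb; ++s) {
    const float* src = dF.colptr(s);
    for (int c = 0; c < C; ++c) {
      std::memcpy(dp.colptr(c) + s * HW2, src + c * HW2, HW2 * sizeof(float));
    }
  }
}

// rearrange a batch of input columns (H*W*3, nb) into the stacked conv
// layout (nb*HW, 3)
static void input_to_batch(const fmat& Xb, int H, int W, fmat& x) {
  const int nb = Xb.n_cols;
  const size_t HW = (size_t)H * W;
  x.set_size(nb * HW, 3);
  for (int s = 0; s < nb; ++s) {
    for (int c = 0; c < 3; ++c) {
      std::memcpy(x.colptr(c) + s * HW, Xb.colptr(s) + c * HW,
                  HW * sizeof(float));
    }
  }
}

static fvec batch_fwd(const field<fmat>& w, const fmat& Xb, const Dims& dm,
                      fmat& x1, BlockCache& c1, BlockCache& c2, BlockCache& c3,
                      HeadCache& hc) {
  const int nb = Xb.n_cols;
  input_to_batch(Xb, dm.H, dm.W, x1);
  block_fwd(x1, w(0), w(1), w(2), dm.H, dm.W, nb, c1);
  block_fwd(c1.p, w(3), w(4), w(5), dm.H2, dm.W2, nb, c2);
  block_fwd(c2.p, w(6), w(7), w(8), dm.H3, dm.W3, nb, c3);
  pooled_to_flat(c1.p, nb, hc.F1);
  pooled_to_flat(c2.p, nb, hc.F2);
  pooled_to_flat(c3.p, nb, hc.F3);
  head_fwd(w, hc);
  return hc.p;
}

static void batch_bwd(const field<fmat>& w, const Dims& dm, const fvec& y,
                      const fmat& x1, BlockCache& c1, BlockCache& c2,
                      BlockCache& c3, HeadCache& hc, field<fmat>& gr,
                      BwdScratch& ws) {
  const int nb = y.n_elem;
  fmat dF[3];
  head_bwd(w, hc, y, gr, dF);
  fmat dP3, dtmp;
  flat_to_pooled(dF[2], nb, dm.C3, dP3);
  block_bwd(c3, c2.p, w(6), w(7), dm.H3, dm.W3, nb, dP3, gr(6), gr(7), gr(8),
            &ws.dx3, ws.da3, ws.du3);
  flat_to_pooled(dF[1], nb, dm.C2, dtmp);
  ws.dx3 += dtmp;
  block_bwd(c2, c1.p, w(3), w(4), dm.H2, dm.W2, nb, ws.dx3, gr(3), gr(4),
            gr(5), &ws.dx2, ws.da2, ws.du2);
  flat_to_pooled(dF[0], nb, dm.C1, dtmp);
  ws.dx2 += dtmp;
  block_bwd(c1, x1, w(0), w(1), dm.H, dm.W, nb, ws.dx2, gr(0), gr(1), gr(2),
            nullptr, ws.da1, ws.du1);
}

static double bce_loss(const fvec& p, const fvec& y) {
  fvec pc = clamp(p, 1e-7f, 1.0f - 1e-7f);
  return (double)mean(-y % log(pc) - (1.0f - y) % log(1.0f - pc));
}

// [[Rcpp::export]]
NumericVector cnn_predict_cpp(List weights, NumericMatrix X, int H, int W,
                              int batch_size = 32) {
  field<fmat> w = weights_from_list(weights);
  Dims dm(H, W, w);
  const int n = X.ncol();     // X is (H*W*3, n): one column per sample
  fmat Xa(X.nrow(), n);
  for (R_xlen_t j = 0; j < (R_xlen_t)X.nrow() * n; ++j) {
    Xa.memptr()[j] = (float)X[j];
  }
  NumericVector out(n);
  fmat x1;
  BlockCache c1, c2, c3;
  for (int s = 0; s < n; s += batch_size) {
    const int e = std::min(n, s + batch_size);
    HeadCache hc;
    fvec p = batch_fwd(w, Xa.cols(s, e - 1), dm, x1, c1, c2, c3, hc);
    for (int i = s; i < e; ++i) out[i] = (double)p(i - s);
  }
  return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, NumericMatrix X, NumericVector y,
                   IntegerMatrix perms, int batch_size, double lr,
                   double beta1, double beta2, double adam_eps,
                   int H, int W) {
  field<fmat> w = weights_from_list(weights);
  Dims dm(H, W, w);
  const int n = X.ncol();     // X is (H*W*3, n): one column per sample
  const int epochs = perms.nrow();
  fmat Xa(X.nrow(), n);
  for (R_xlen_t j = 0; j < (R_xlen_t)X.nrow() * n; ++j) {
    Xa.memptr()[j] = (float)X[j];
  }
  fvec ya(n);
  for (int i = 0; i < n; ++i) ya(i) = (float)y[i];

  field<fmat> m(N_WEIGHTS), v(N_WEIGHTS), gr(N_WEIGHTS);
  for (int i = 0; i < N_WEIGHTS; ++i) {
    m(i).zeros(w(i).n_rows, w(i).n_cols);
    v(i).zeros(w(i).n_rows, w(i).n_cols);
    gr(i).zeros(w(i).n_rows, w(i).n_cols);
  }
  NumericVector epoch_loss(epochs), epoch_acc(epochs);
  long t = 0;
  fmat x1;
  BlockCache c1, c2, c3;
  BwdScratch ws;
  const float flr = (float)lr, fb1 = (float)beta1, fb2 = (float)beta2,
              fee = (float)adam_eps;
  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    long correct = 0;
    for (int s = 0; s < n; s += batch_size) {
      const int e = std::min(n, s + batch_size);
      const int nb = e - s;
      fmat Xb(Xa.n_rows, nb);
      fvec yb(nb);
      for (int i = 0; i < nb; ++i) {
        const int src = perms(ep, s + i);
        Xb.col(i) = Xa.col(src);
        yb(i) = ya(src);
      }
      HeadCache hc;
      fvec p = batch_fwd(w, Xb, dm, x1, c1, c2, c3, hc);
      loss_sum += bce_loss(p, yb) * nb;
      for (int i = 0; i < nb; ++i) {
        if ((p(i) >= 0.5f) == (yb(i) >= 0.5f)) ++correct;
      }
      for (int i = 0; i < N_WEIGHTS; ++i) {
        if (i == 9 || i == 11 || i == 13) continue;   // assigned in head_bwd
        gr(i).zeros();
      }
      batch_bwd(w, dm, yb, x1, c1, c2, c3, hc, gr, ws);
      ++t;
      const float bc1 = 1.0f - std::pow(fb1, (float)t);
      const float bc2 = 1.0f - std::pow(fb2, (float)t);
      for (int i = 0; i < N_WEIGHTS; ++i) {
        float* pm = m(i).memptr();
        float* pv = v(i).memptr();
        float* pw_ = w(i).memptr();
        const float* pg = gr(i).memptr();
        const uword ne = w(i).n_elem;
        for (uword j = 0; j < ne; ++j) {
          const float g = pg[j];
          pm[j] = fb1 * pm[j] + (1.0f - fb1) * g;
          pv[j] = fb2 * pv[j] + (1.0f - fb2) * g * g;
          pw_[j] -= flr * (pm[j] / bc1) / (std::sqrt(pv[j] / bc2) + fee);
        }
      }
      Rcpp::checkUserInterrupt();
    }
    epoch_loss[ep] = loss_sum / n;
    epoch_acc[ep] = (double)correct / n;
  }
  return List::create(Rcpp::Named("weights") = weights_to_list(w),
                      Rcpp::Named("loss") = epoch_loss,
                      Rcpp::Named("accuracy") = epoch_acc);
}

// single full-batch loss + analytic gradients (for finite-difference checks)
// [[Rcpp::export]]
List cnn_loss_grads_cpp(List weights, NumericMatrix X, NumericVector y,
                        int H, int W) {
  field<fmat> w = weights_from_list(weights);
  Dims dm(H, W, w);
  const int n = X.ncol();     // X is (H*W*3, n): one column per sample
  fmat Xa(X.nrow(), n);
  for (R_xlen_t j = 0; j < (R_xlen_t)X.nrow() * n; ++j) {
    Xa.memptr()[j] = (float)X[j];
  }
  fvec ya(n);
  for (int i = 0; i < n; ++i) ya(i) = (float)y[i];
  fmat x1;
  BlockCache c1, c2, c3;
  HeadCache hc;
  fvec p = batch_fwd(w, Xa, dm, x1, c1, c2, c3, hc);
  field<fmat> gr(N_WEIGHTS);
  for (int i = 0; i < N_WEIGHTS; ++i) gr(i).zeros(w(i).n_rows, w(i).n_cols);
  BwdScratch ws;
  batch_bwd(w, dm, ya, x1, c1, c2, c3, hc, gr, ws);
  return List::create(Rcpp::Named("loss") = bce_loss(p, ya),
                      Rcpp::Named("grads") = weights_to_list(gr),
                      Rcpp::Named("prob") = NumericVector(p.begin(), p.end()));
}
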