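// CPU implementation of the particle-classification CNN.
//
// Layout conventions used throughout:
//  * A batch of feature maps is an arma::cube with n_rows = H, n_cols = W and
//    n_slices = B * C, slice index = img * C + ch (image-major).
//  * Conv weights are mat (F x C*k*k); row f, column ch*k*k + kj*k + ki,
//    matching the im2col row order below. "same" zero padding, stride 1,
//    odd kernels only.
//  * Pooling uses ceil-division output sizes with TF-style asymmetric
//    padding: pad_total = max((Ho-1)*s + p - H, 0), pad_lo = pad_total / 2.
//    Max pooling ignores padded cells; average pooling divides by the count
//    of valid (non-padded) cells.
// All randomness (init, shuffling, augmentation, dropout) flows through one
// std::mt19937 so training is bit-reproducible for a fixed seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uvec;

namespace {

struct BlockSpec {
  int k1, f1, k2, f2;
  bool max_pool;      // false -> average
  int pool_size, pool_stride;
};

struct NetSpec {
  int input_side;
  std::vector<BlockSpec> blocks;
  int fc_width;
  double dropout_p;
  double l2;
  double bn_momentum;
  double bn_eps;
};

NetSpec parse_spec(const List& spec) {
  NetSpec s;
  s.input_side = as<int>(spec["input_side"]);
  s.fc_width = as<int>(spec["fc_width"]);
  s.dropout_p = as<double>(spec["dropout_p"]);
  s.l2 = as<double>(spec["l2_strength"]);
  s.bn_momentum = as<double>(spec["bn_momentum"]);
  s.bn_eps = 1e-3;  // matches the common backend default
  List blocks = spec["conv_blocks"];
  for (int i = 0; i < blocks.size(); ++i) {
    List b = blocks[i];
    IntegerVector kern = b["kernel"];
    IntegerVector filt = b["filters"];
    std::string pool = as<std::string>(b["pool"]);
    BlockSpec bs;
    bs.k1 = kern[0]; bs.k2 = kern[1];
    bs.f1 = filt[0]; bs.f2 = filt[1];
    bs.max_pool = (pool == "max");
    bs.pool_size = as<int>(b["pool_size"]);
    bs.pool_stride = as<int>(b["pool_stride"]);
    if (bs.k1 % 2 == 0 || bs.k2 % 2 == 0)
      stop("convolution kernels must be odd");
    s.blocks.push_back(bs);
  }
  return s;
}

// ---------------------------------------------------------------------------
// im2col / col2im ("same" padding, stride 1)

// Transposed im2col layout: col is (H*W) x (C*k*k); column ch*k*k + kj*k +
// ki holds, at row j*H + i, the input value at (i + ki - pad, j + kj - pad)
// or zero. Every fill is a contiguous run, which keeps the memory traffic
// cache-friendly; the convolution itself is a single BLAS gemm.
void im2col_t(const cube& A, int img, int C, int k, mat& col) {
  const int H = A.n_rows, W = A.n_cols, pad = (k - 1) / 2;
  col.zeros(H * W, C * k * k);
  for (int ch = 0; ch < C; ++ch) {
    const mat& sl = A.slice(img * C + ch);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* dst = col.colptr(ch * k * k + kj * k + ki);
        const int i_lo = std::max(0, pad - ki);
        const int i_hi = std::min(H, H + pad - ki);
        if (i_lo >= i_hi) continue;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          std::memcpy(dst + static_cast<size_t>(j) * H + i_lo,
                      sl.colptr(jj) + (i_lo + ki - pad),
                      static_cast<size_t>(i_hi - i_lo) * sizeof(double));
        }
      }
    }
  }
}

void col2im_t_add(cube& dA, const mat& dcol, int img, int C, int k) {
  const int H = dA.n_rows, W = dA.n_cols, pad = (k - 1) / 2;
  for (int ch = 0; ch < C; ++ch) {
    mat& sl = dA.slice(img * C + ch);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* src = dcol.colptr(ch * k * k + kj * k + ki);
        const int i_lo = std::max(0, pad - ki);
        const int i_hi = std::min(H, H + pad - ki);
        if (i_lo >= i_hi) continue;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          double* dst = sl.colptr(jj) + (i_lo + ki - pad);
          const double* s = src + static_cast<size_t>(j) * H + i_lo;
          for (int i = 0; i < i_hi - i_lo; ++i) dst[i] += s[i];
        }
      }
    }
  }
}

// Forward convolution for a whole batch. A: (H,W,B*Cin) -> (H,W,B*F).
cube conv_forward(const cube& A, const mat& W, const vec& b, int B, int Cin) {
  const int H = A.n_rows, Wd = A.n_cols;
  const int F = W.n_rows;
  const int k = static_cast<int>(std::lround(std::sqrt(double(W.n_cols / Cin))));
  cube out(H, Wd, B * F);
  mat col;
  for (int img = 0; img < B; ++img) {
    im2col_t(A, img, Cin, k, col);
    mat O = col * W.t();             // (HW) x F
    for (int f = 0; f < F; ++f) {
      std::memcpy(out.slice_memptr(img * F + f), O.colptr(f),
                  static_cast<size_t>(H) * Wd * sizeof(double));
      out.slice(img * F + f) += b(f);
    }
  }
  return out;
}

// Backward convolution. dOut: (H,W,B*F). Returns dA; accumulates dW, db.
// The im2col matrices are recomputed per image rather than cached: caching
// them for a whole batch costs gigabytes at 15x15 kernels.
cube conv_backward(const cube& dOut, const cube& A,
                   const mat& W, int B, int Cin, mat& dW, vec& db) {
  const int H = A.n_rows, Wd = A.n_cols;
  const int F = W.n_rows;
  const int k = static_cast<int>(std::lround(std::sqrt(double(W.n_cols / Cin))));
  cube dA(H, Wd, A.n_slices, arma::fill::zeros);
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(F);
  mat dY(H * Wd, F), col;
  for (int img = 0; img < B; ++img) {
    for (int f = 0; f < F; ++f)
      std::memcpy(dY.colptr(f), dOut.slice_memptr(img * F + f),
                  static_cast<size_t>(H) * Wd * sizeof(double));
    im2col_t(A, img, Cin, k, col);
    dW += dY.t() * col;              // F x CKK
    db += arma::sum(dY, 0).t();
    mat dcol = dY * W;               // (HW) x CKK
    col2im_t_add(dA, dcol, img, Cin, k);
  }
  return dA;
}

// ---------------------------------------------------------------------------
// Pooling

inline int pool_out(int H, int s) { return (H + s - 1) / s; }

struct PoolCache {
  arma::umat argmax;   // (Ho*Wo) x n_slices, linear index into input slice
  int H, W, Ho, Wo, p, s;
  bool max_pool;
};

cube pool_forward(const cube& A, int p, int s, bool max_pool, PoolCache* cache) {
  const int H = A.n_rows, W = A.n_cols;
  const int Ho = pool_out(H, s), Wo = pool_out(W, s);
  const int pad_h = std::max((Ho - 1) * s + p - H, 0) / 2;
  const int pad_w = std::max((Wo - 1) * s + p - W, 0) / 2;
  cube out(Ho, Wo, A.n_slices);
  if (cache) {
    cache->H = H; cache->W = W; cache->Ho = Ho; cache->Wo = Wo;
    cache->p = p; cache->s = s; cache->max_pool = max_pool;
    if (max_pool) cache->argmax.set_size(Ho * Wo, A.n_slices);
  }
  for (arma::uword sl = 0; sl < A.n_slices; ++sl) {
    const mat& X = A.slice(sl);
    mat& Y = out.slice(sl);
    for (int jo = 0; jo < Wo; ++jo) {
      const int j0 = std::max(jo * s - pad_w, 0);
      const int j1 = std::min(jo * s - pad_w + p, W);
      for (int io = 0; io < Ho; ++io) {
        const int i0 = std::max(io * s - pad_h, 0);
        const int i1 = std::min(io * s - pad_h + p, H);
        if (max_pool) {
          double best = -arma::datum::inf;
          int bi = i0, bj = j0;
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i)
              if (X(i, j) > best) { best = X(i, j); bi = i; bj = j; }
          Y(io, jo) = best;
          if (cache) cache->argmax(jo * Ho + io, sl) = bj * H + bi;
        } else {
          double acc = 0.0;
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i) acc += X(i, j);
          Y(io, jo) = acc / double((i1 - i0) * (j1 - j0));
        }
      }
    }
  }
  return out;
}

cube pool_backward(const cube& dOut, const PoolCache& c, arma::uword n_slices) {
  cube dA(c.H, c.W, n_slices, arma::fill::zeros);
  const int pad_h = std::max((c.Ho - 1) * c.s + c.p - c.H, 0) / 2;
  const int pad_w = std::max((c.Wo - 1) * c.s + c.p - c.W, 0) / 2;
  for (arma::uword sl = 0; sl < n_slices; ++sl) {
    const mat& dY = dOut.slice(sl);
    mat& dX = dA.slice(sl);
    for (int jo = 0; jo < c.Wo; ++jo) {
      for (int io = 0; io < c.Ho; ++io) {
        if (c.max_pool) {
          dX(c.argmax(jo * c.Ho + io, sl)) += dY(io, jo);
        } else {
          const int j0 = std::max(jo * c.s - pad_w, 0);
          const int j1 = std::min(jo * c.s - pad_w + c.p, c.W);
          const int i0 = std::max(io * c.s - pad_h, 0);
          const int i1 = std::min(io * c.s - pad_h + c.p, c.H);
          const double g = dY(io, jo) / double((i1 - i0) * (j1 - j0));
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i) dX(i, j) += g;
        }
      }
    }
  }
  return dA;
}

// ---------------------------------------------------------------------------
// Batch normalization (per channel over batch and spatial dims)

struct BnCache {
  cube x_hat;
  vec mean, var, istd;
};

cube bn_forward_train(const cube& A, const vec& gamma, const vec& beta,
                      vec& run_mean, vec& run_var, double momentum,
                      double eps, int B, int C, BnCache* cache) {
  const double M = double(B) * A.n_rows * A.n_cols;
  vec mean(C, arma::fill::zeros), var(C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int img = 0; img < B; ++img) mean(c) += arma::accu(A.slice(img * C + c));
    mean(c) /= M;
  }
  for (int c = 0; c < C; ++c) {
    for (int img = 0; img < B; ++img) {
      mat d = A.slice(img * C + c) - mean(c);
      var(c) += arma::accu(d % d);
    }
    var(c) /= M;
  }
  vec istd = 1.0 / arma::sqrt(var + eps);
  cube out(A.n_rows, A.n_cols, A.n_slices);
  cube x_hat(A.n_rows, A.n_cols, A.n_slices);
  for (int img = 0; img < B; ++img) {
    for (int c = 0; c < C; ++c) {
      x_hat.slice(img * C + c) = (A.slice(img * C + c) - mean(c)) * istd(c);
      out.slice(img * C + c) = gamma(c) * x_hat.slice(img * C + c) + beta(c);
    }
  }
  run_mean = momentum * run_mean + (1 - momentum) * mean;
  run_var = momentum * run_var + (1 - momentum) * var;
  if (cache) { cache->x_hat = x_hat; cache->mean = mean; cache->var = var; cache->istd = istd; }
  return out;
}

cube bn_forward_infer(const cube& A, const vec& gamma, const vec& beta,
                      const vec& run_mean, const vec& run_var, double eps,
                      int B, int C) {
  cube out(A.n_rows, A.n_cols, A.n_slices);
  for (int img = 0; img < B; ++img)
    for (int c = 0; c < C; ++c)
      out.slice(img * C + c) =
        gamma(c) * (A.slice(img * C + c) - run_mean(c)) / std::sqrt(run_var(c) + eps) + beta(c);
  return out;
}

cube bn_backward(const cube& dOut, const BnCache& cc, const vec& gamma,
                 int B, int C, vec& dgamma, vec& dbeta) {
  const double M = double(B) * dOut.n_rows * dOut.n_cols;
  dgamma.zeros(C);
  dbeta.zeros(C);
  vec mean_dy(C, arma::fill::zeros), mean_dyx(C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int img = 0; img < B; ++img) {
      const mat& dy = dOut.slice(img * C + c);
      const mat& xh = cc.x_hat.slice(img * C + c);
      dgamma(c) += arma::accu(dy % xh);
      dbeta(c) += arma::accu(dy);
    }
    mean_dy(c) = dbeta(c) / M;
    mean_dyx(c) = dgamma(c) / M;
  }
  cube dA(dOut.n_rows, dOut.n_cols, dOut.n_slices);
  for (int img = 0; img < B; ++img)
    for (int c = 0; c < C; ++c)
      dA.slice(img * C + c) = gamma(c) * cc.istd(c) *
        (dOut.slice(img * C + c) - mean_dy(c) - cc.x_hat.slice(img * C + c) * mean_dyx(c));
  return dA;
}

// ---------------------------------------------------------------------------
// Parameter bundle

struct Params {
  std::vector<mat> cW1, cW2;
  std::vector<vec> cb1, cb2, gamma, beta, run_mean, run_var;
  mat fcW, outW;
  vec fcb, outb;
};

Params parse_params(const List& p, int n_blocks) {
  Params P;
  for (int i = 0; i < n_blocks; ++i) {
    std::string pre = "b" + std::to_string(i + 1) + "_";
    P.cW1.push_back(as<mat>(p[pre + "c1_W"]));
    P.cb1.push_back(as<vec>(p[pre + "c1_b"]));
    P.cW2.push_back(as<mat>(p[pre + "c2_W"]));
    P.cb2.push_back(as<vec>(p[pre + "c2_b"]));
    P.gamma.push_back(as<vec>(p[pre + "bn_gamma"]));
    P.beta.push_back(as<vec>(p[pre + "bn_beta"]));
    P.run_mean.push_back(as<vec>(p[pre + "bn_mean"]));
    P.run_var.push_back(as<vec>(p[pre + "bn_var"]));
  }
  P.fcW = as<mat>(p["fc_W"]);
  P.fcb = as<vec>(p["fc_b"]);
  P.outW = as<mat>(p["out_W"]);
  P.outb = as<vec>(p["out_b"]);
  return P;
}

List params_to_list(const Params& P) {
  List out;
  for (size_t i = 0; i < P.cW1.size(); ++i) {
    std::string pre = "b" + std::to_string(i + 1) + "_";
    out[pre + "c1_W"] = P.cW1[i];
    out[pre + "c1_b"] = P.cb1[i];
    out[pre + "c2_W"] = P.cW2[i];
    out[pre + "c2_b"] = P.cb2[i];
    out[pre + "bn_gamma"] = P.gamma[i];
    out[pre + "bn_beta"] = P.beta[i];
    out[pre + "bn_mean"] = P.run_mean[i];
    out[pre + "bn_var"] = P.run_var[i];
  }
  out["fc_W"] = P.fcW;
  out["fc_b"] = P.fcb;
  out["out_W"] = P.outW;
  out["out_b"] = P.outb;
  return out;
}

int flat_features(const NetSpec& s) {
  int H = s.input_side;
  for (const auto& b : s.blocks) H = pool_out(H, b.pool_stride);
  return H * H * s.blocks.back().f2;
}

// ---------------------------------------------------------------------------
// Full forward / backward

struct Tape {
  std::vector<cube> conv1_in, conv1_act, conv2_act_bn;  // cached activations
  std::vector<BnCache> bn;
  std::vector<PoolCache> pool;
  cube pool_out_last;
  mat flat;        // feat x B
  mat fc_act;      // post-relu
  mat drop_mask;   // inverted-dropout mask (already scaled)
  mat probs;       // 2 x B
};

// Forward pass. train = true uses batch BN stats (updating running stats),
// applies dropout with rng; train = false uses running stats, no dropout.
mat forward(const NetSpec& s, Params& P, const cube& X, bool train,
            std::mt19937* rng, Tape* tape) {
  const int B = X.n_slices;
  cube a = X;  // B * 1 channels
  int Cin = 1;
  for (size_t bi = 0; bi < s.blocks.size(); ++bi) {
    const BlockSpec& bs = s.blocks[bi];
    if (tape) tape->conv1_in.push_back(a);
    cube c1 = conv_forward(a, P.cW1[bi], P.cb1[bi], B, Cin);
    c1.transform([](double v) { return v > 0 ? v : 0.0; });
    if (tape) tape->conv1_act.push_back(c1);
    cube c2 = conv_forward(c1, P.cW2[bi], P.cb2[bi], B, bs.f1);
    BnCache bc;
    cube b2 = train
      ? bn_forward_train(c2, P.gamma[bi], P.beta[bi], P.run_mean[bi], P.run_var[bi],
                         s.bn_momentum, s.bn_eps, B, bs.f2, tape ? &bc : nullptr)
      : bn_forward_infer(c2, P.gamma[bi], P.beta[bi], P.run_mean[bi], P.run_var[bi],
                         s.bn_eps, B, bs.f2);
    b2.transform([](double v) { return v > 0 ? v : 0.0; });
    if (tape) { tape->bn.push_back(std::move(bc)); tape->conv2_act_bn.push_back(b2); }
    PoolCache pc;
    a = pool_forward(b2, bs.pool_size, bs.pool_stride, bs.max_pool, tape ? &pc : nullptr);
    if (tape) tape->pool.push_back(std::move(pc));
    Cin = bs.f2;
  }
  if (tape) tape->pool_out_last = a;
  // flatten (channel-major per image, column-major within a channel)
  const int C = Cin, H = a.n_rows, W = a.n_cols;
  mat flat(H * W * C, B);
  for (int img = 0; img < B; ++img)
    for (int c = 0; c < C; ++c)
      flat(arma::span(c * H * W, (c + 1) * H * W - 1), arma::span(img, img)) =
        arma::vectorise(a.slice(img * C + c));
  mat h = P.fcW * flat;
  h.each_col() += P.fcb;
  h.transform([](double v) { return v > 0 ? v : 0.0; });
  mat drop_mask;
  if (train && s.dropout_p > 0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    drop_mask.set_size(h.n_rows, h.n_cols);
    const double keep = 1.0 - s.dropout_p;
    for (arma::uword j = 0; j < h.n_cols; ++j)
      for (arma::uword i = 0; i < h.n_rows; ++i)
        drop_mask(i, j) = (U(*rng) < keep) ? 1.0 / keep : 0.0;
    h %= drop_mask;
  }
  mat logits = P.outW * h;
  logits.each_col() += P.outb;
  mat probs(2, B);
  for (int j = 0; j < B; ++j) {
    vec z = logits.col(j) - logits.col(j).max();
    vec e = arma::exp(z);
    probs.col(j) = e / arma::accu(e);
  }
  if (tape) {
    tape->flat = std::move(flat);
    tape->fc_act = std::move(h);
    tape->drop_mask = std::move(drop_mask);
    tape->probs = probs;
  }
  return probs;
}

struct Grads {
  std::vector<mat> cW1, cW2;
  std::vector<vec> cb1, cb2, gamma, beta;
  mat fcW, outW;
  vec fcb, outb;
};

double backward(const NetSpec& s, const Params& P, const Tape& t,
                const arma::ivec& y, Grads& g) {
  const int B = y.n_elem;
  const int nb = s.blocks.size();
  g.cW1.resize(nb); g.cW2.resize(nb); g.cb1.resize(nb); g.cb2.resize(nb);
  g.gamma.resize(nb); g.beta.resize(nb);
  // cross-entropy loss and softmax gradient
  double loss = 0.0;
  mat dlogits = t.probs;  // 2 x B
  for (int j = 0; j < B; ++j) {
    loss -= std::log(std::max(t.probs(y(j), j), 1e-12));
    dlogits(y(j), j) -= 1.0;
  }
  loss /= B;
  dlogits /= double(B);
  // L2 penalty on all kernel weights
  double l2pen = arma::accu(arma::square(P.fcW)) + arma::accu(arma::square(P.outW));
  for (int i = 0; i < nb; ++i)
    l2pen += arma::accu(arma::square(P.cW1[i])) + arma::accu(arma::square(P.cW2[i]));
  loss += s.l2 * l2pen;

  mat h = t.fc_act;
  g.outW = dlogits * h.t() + 2.0 * s.l2 * P.outW;
  g.outb = arma::sum(dlogits, 1);
  mat dh = P.outW.t() * dlogits;
  if (t.drop_mask.n_elem > 0) dh %= t.drop_mask;
  dh %= arma::conv_to<mat>::from(h > 0);
  g.fcW = dh * t.flat.t() + 2.0 * s.l2 * P.fcW;
  g.fcb = arma::sum(dh, 1);
  mat dflat = P.fcW.t() * dh;
  // unflatten
  const cube& last = t.pool_out_last;
  const int C = s.blocks.back().f2, H = last.n_rows, W = last.n_cols;
  cube da(H, W, last.n_slices);
  for (int img = 0; img < B; ++img)
    for (int c = 0; c < C; ++c)
      da.slice(img * C + c) = arma::reshape(
        dflat(arma::span(c * H * W, (c + 1) * H * W - 1), arma::span(img, img)), H, W);
  for (int bi = nb - 1; bi >= 0; --bi) {
    const BlockSpec& bs = s.blocks[bi];
    cube d_pool_in = pool_backward(da, t.pool[bi], t.conv2_act_bn[bi].n_slices);
    d_pool_in %= arma::conv_to<cube>::from(t.conv2_act_bn[bi] > 0);
    cube d_c2 = bn_backward(d_pool_in, t.bn[bi], P.gamma[bi], B, bs.f2,
                            g.gamma[bi], g.beta[bi]);
    cube d_c1 = conv_backward(d_c2, t.conv1_act[bi], P.cW2[bi],
                              B, bs.f1, g.cW2[bi], g.cb2[bi]);
    g.cW2[bi] += 2.0 * s.l2 * P.cW2[bi];
    d_c1 %= arma::conv_to<cube>::from(t.conv1_act[bi] > 0);
    const int Cin = (bi == 0) ? 1 : s.blocks[bi - 1].f2;
    da = conv_backward(d_c1, t.conv1_in[bi], P.cW1[bi],
                       B, Cin, g.cW1[bi], g.cb1[bi]);
    g.cW1[bi] += 2.0 * s.l2 * P.cW1[bi];
  }
  return loss;
}

// ---------------------------------------------------------------------------
// Adam

struct Adam {
  std::vector<mat*> w;
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  void add(mat* p) { w.push_back(p); m.emplace_back(arma::size(*p), arma::fill::zeros);
                     v.emplace_back(arma::size(*p), arma::fill::zeros); }
  void step(const std::vector<const mat*>& grads, double lr) {
    ++t;
    const double bc1 = 1.0 - std::pow(b1, double(t));
    const double bc2 = 1.0 - std::pow(b2, double(t));
    for (size_t i = 0; i < w.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * (*grads[i]);
      v[i] = b2 * v[i] + (1 - b2) * arma::square(*grads[i]);
      *w[i] -= lr * (m[i] / bc1) / (arma::sqrt(v[i] / bc2) + eps);
    }
  }
};

// Dihedral-group transforms of a square image; op in 1..7 (identity excluded):
// 1..3 rotations by 90/180/270, 4 horizontal flip, 5 vertical flip,
// 6 transpose, 7 anti-transpose.
mat dihedral(const mat& A, int op) {
  switch (op) {
    case 1: return arma::flipud(A.t());
    case 2: return arma::flipud(arma::fliplr(A));
    case 3: return arma::fliplr(A.t());
    case 4: return arma::fliplr(A);
    case 5: return arma::flipud(A);
    case 6: return A.t();
    default: return arma::flipud(arma::fliplr(A)).t();
  }
}

double accuracy(const mat& probs, const arma::ivec& y) {
  int ok = 0;
  for (arma::uword j = 0; j < probs.n_cols; ++j)
    ok += ((probs(1, j) >= 0.5 ? 1 : 0) == y(j));
  return double(ok) / probs.n_cols;
}

mat predict_batched(const NetSpec& s, Params& P, const cube& X, int batch) {
  const int N = X.n_slices;
  mat probs(2, N);
  for (int lo = 0; lo < N; lo += batch) {
    const int hi = std::min(lo + batch, N);
    cube xb = X.slices(lo, hi - 1);
    probs.cols(lo, hi - 1) = forward(s, P, xb, false, nullptr, nullptr);
  }
  return probs;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported entry points

// [[Rcpp::export(name = ".cnn_init")]]
List cnn_init(List spec, int seed) {
  NetSpec s = parse_spec(spec);
  std::mt19937 rng(static_cast<uint32_t>(seed));
  auto glorot = [&](int rows, int cols, int fan_in, int fan_out) {
    const double lim = std::sqrt(6.0 / double(fan_in + fan_out));
    std::uniform_real_distribution<double> U(-lim, lim);
    mat W(rows, cols);
    for (arma::uword j = 0; j < W.n_cols; ++j)
      for (arma::uword i = 0; i < W.n_rows; ++i) W(i, j) = U(rng);
    return W;
  };
  Params P;
  int Cin = 1;
  for (const auto& b : s.blocks) {
    P.cW1.push_back(glorot(b.f1, Cin * b.k1 * b.k1, Cin * b.k1 * b.k1, b.f1 * b.k1 * b.k1));
    P.cb1.push_back(vec(b.f1, arma::fill::zeros));
    P.cW2.push_back(glorot(b.f2, b.f1 * b.k2 * b.k2, b.f1 * b.k2 * b.k2, b.f2 * b.k2 * b.k2));
    P.cb2.push_back(vec(b.f2, arma::fill::zeros));
    P.gamma.push_back(vec(b.f2, arma::fill::ones));
    P.beta.push_back(vec(b.f2, arma::fill::zeros));
    P.run_mean.push_back(vec(b.f2, arma::fill::zeros));
    P.run_var.push_back(vec(b.f2, arma::fill::ones));
    Cin = b.f2;
  }
  const int feat = flat_features(s);
  P.fcW = glorot(s.fc_width, feat, feat, s.fc_width);
  P.fcb = vec(s.fc_width, arma::fill::zeros);
  P.outW = glorot(2, s.fc_width, s.fc_width, 2);
  P.outb = vec(2, arma::fill::zeros);
  return params_to_list(P);
}

// [[Rcpp::export(name = ".cnn_shapes")]]
List cnn_shapes(List spec) {
  NetSpec s = parse_spec(spec);
  List out;
  int H = s.input_side;
  out.push_back(IntegerVector::create(H, H, 1));
  for (const auto& b : s.blocks) {
    out.push_back(IntegerVector::create(H, H, b.f1));
    out.push_back(IntegerVector::create(H, H, b.f2));
    H = pool_out(H, b.pool_stride);
    out.push_back(IntegerVector::create(H, H, b.f2));
  }
  out.push_back(IntegerVector::create(s.fc_width));
  out.push_back(IntegerVector::create(2));
  return out;
}

// [[Rcpp::export(name = ".cnn_predict")]]
NumericMatrix cnn_predict(List spec, List params, const arma::cube& X, int batch) {
  NetSpec s = parse_spec(spec);
  Params P = parse_params(params, s.blocks.size());
  mat probs = predict_batched(s, P, X, batch);
  return wrap(mat(probs.t()));  // N x 2
}

// Loss and analytic gradients on one batch, for finite-difference checks.
// Dropout disabled; BN in training mode (no running-stat update exported).
// [[Rcpp::export(name = ".cnn_loss_grads")]]
List cnn_loss_grads(List spec, List params, const arma::cube& X, const arma::ivec& y) {
  NetSpec s = parse_spec(spec);
  s.dropout_p = 0.0;
  Params P = parse_params(params, s.blocks.size());
  Tape t;
  forward(s, P, X, true, nullptr, &t);
  Grads g;
  double loss = backward(s, P, t, y, g);
  List gl;
  for (size_t i = 0; i < g.cW1.size(); ++i) {
    std::string pre = "b" + std::to_string(i + 1) + "_";
    gl[pre + "c1_W"] = g.cW1[i];
    gl[pre + "c1_b"] = g.cb1[i];
    gl[pre + "c2_W"] = g.cW2[i];
    gl[pre + "c2_b"] = g.cb2[i];
    gl[pre + "bn_gamma"] = g.gamma[i];
    gl[pre + "bn_beta"] = g.beta[i];
  }
  gl["fc_W"] = g.fcW;
  gl["fc_b"] = g.fcb;
  gl["out_W"] = g.outW;
  gl["out_b"] = g.outb;
  return List::create(_["loss"] = loss, _["grads"] = gl);
}

// [[Rcpp::export(name = ".cnn_loss_only")]]
double cnn_loss_only(List spec, List params, const arma::cube& X, const arma::ivec& y) {
  NetSpec s = parse_spec(spec);
  s.dropout_p = 0.0;
  Params P = parse_params(params, s.blocks.size());
  Tape t;
  forward(s, P, X, true, nullptr, &t);
  Grads g;
  return backward(s, P, t, y, g);
}

// Training loop: Adam, plateau LR decay, dihedral augmentation, early stop.
// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train(List spec, List params, const arma::cube& Xtr, const arma::ivec& ytr,
               const arma::cube& Xval, const arma::ivec& yval, List cfg) {
  NetSpec s = parse_spec(spec);
  Params P = parse_params(params, s.blocks.size());
  const double lr0 = as<double>(cfg["initial_lr"]);
  const double decay = as<double>(cfg["lr_decay_factor"]);
  const int patience = as<int>(cfg["patience_batches"]);
  const int batch_size = as<int>(cfg["batch_size"]);
  const int max_epochs = as<int>(cfg["max_epochs"]);
  const double augment_ratio = as<double>(cfg["augment_ratio"]);
  const int eval_every = as<int>(cfg["eval_every"]);
  const int seed = as<int>(cfg["rng_seed"]);
  std::mt19937 rng(static_cast<uint32_t>(seed));

  Adam opt;
  const int nb = s.blocks.size();
  std::vector<mat> gb1(nb), gb2(nb), gg(nb), gbta(nb), gcb1(nb), gcb2(nb);
  // register parameters (biases/vecs as 1-col mats through views is awkward;
  // hold vec params in mats locally)
  std::vector<mat> vcb1(nb), vcb2(nb), vgamma(nb), vbeta(nb);
  for (int i = 0; i < nb; ++i) {
    vcb1[i] = mat(P.cb1[i]);
    vcb2[i] = mat(P.cb2[i]);
    vgamma[i] = mat(P.gamma[i]);
    vbeta[i] = mat(P.beta[i]);
  }
  mat vfcb(P.fcb), voutb(P.outb);
  for (int i = 0; i < nb; ++i) {
    opt.add(&P.cW1[i]); opt.add(&vcb1[i]);
    opt.add(&P.cW2[i]); opt.add(&vcb2[i]);
    opt.add(&vgamma[i]); opt.add(&vbeta[i]);
  }
  opt.add(&P.fcW); opt.add(&vfcb); opt.add(&P.outW); opt.add(&voutb);

  const int N = Xtr.n_slices;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::uniform_int_distribution<int> op_dist(1, 7);

  double lr = lr0;
  double best_val = -1.0;
  int batches_since_improve = 0, n_decays = 0;
  long step = 0;
  bool stop = false;
  double run_loss = 0.0;
  int run_count = 0;
  std::vector<double> h_step, h_lr, h_loss, h_val;

  auto sync_vec_params = [&]() {
    for (int i = 0; i < nb; ++i) {
      P.cb1[i] = vcb1[i].col(0);
      P.cb2[i] = vcb2[i].col(0);
      P.gamma[i] = vgamma[i].col(0);
      P.beta[i] = vbeta[i].col(0);
    }
    P.fcb = vfcb.col(0);
    P.outb = voutb.col(0);
  };

  for (int epoch = 0; epoch < max_epochs && !stop; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int lo = 0; lo < N && !stop; lo += batch_size) {
      const int hi = std::min(lo + batch_size, N);
      const int nb_orig = hi - lo;
      const int n_aug = static_cast<int>(std::lround(augment_ratio * nb_orig));
      cube xb(Xtr.n_rows, Xtr.n_cols, nb_orig + n_aug);
      arma::ivec yb(nb_orig + n_aug);
      for (int i = 0; i < nb_orig; ++i) {
        xb.slice(i) = Xtr.slice(order[lo + i]);
        yb(i) = ytr(order[lo + i]);
      }
      for (int i = 0; i < n_aug; ++i) {
        xb.slice(nb_orig + i) = dihedral(Xtr.slice(order[lo + i]), op_dist(rng));
        yb(nb_orig + i) = ytr(order[lo + i]);
      }
      Tape t;
      forward(s, P, xb, true, &rng, &t);
      Grads g;
      run_loss += backward(s, P, t, yb, g);
      ++run_count;
      std::vector<const mat*> grads;
      std::vector<mat> gv;
      gv.reserve(nb * 4 + 2);
      for (int i = 0; i < nb; ++i) {
        gv.push_back(mat(g.cb1[i])); gv.push_back(mat(g.cb2[i]));
        gv.push_back(mat(g.gamma[i])); gv.push_back(mat(g.beta[i]));
      }
      mat gfcb(g.fcb), goutb(g.outb);
      size_t vi = 0;
      for (int i = 0; i < nb; ++i) {
        grads.push_back(&g.cW1[i]); grads.push_back(&gv[vi * 4 + 0]);
        grads.push_back(&g.cW2[i]); grads.push_back(&gv[vi * 4 + 1]);
        grads.push_back(&gv[vi * 4 + 2]); grads.push_back(&gv[vi * 4 + 3]);
        ++vi;
      }
      grads.push_back(&g.fcW); grads.push_back(&gfcb);
      grads.push_back(&g.outW); grads.push_back(&goutb);
      opt.step(grads, lr);
      sync_vec_params();
      ++step;

      if (step % eval_every == 0) {
        mat vp = predict_batched(s, P, Xval, 64);
        const double vacc = accuracy(vp, yval);
        h_step.push_back(double(step));
        h_lr.push_back(lr);
        h_loss.push_back(run_loss / std::max(run_count, 1));
        h_val.push_back(vacc);
        run_loss = 0.0; run_count = 0;
        if (vacc > best_val + 1e-12) {
          best_val = vacc;
          batches_since_improve = 0;
        } else {
          batches_since_improve += eval_every;
        }
        if (n_decays >= 2 && batches_since_improve >= 3 * patience) {
          stop = true;
        } else if (batches_since_improve >= patience) {
          lr /= decay;
          ++n_decays;
          batches_since_improve = 0;
        }
        Rcpp::checkUserInterrupt();
      }
    }
  }
  sync_vec_params();
  return List::create(
    _["params"] = params_to_list(P),
    _["history"] = DataFrame::create(_["step"] = h_step, _["lr"] = h_lr,
                                     _["loss"] = h_loss, _["val_acc"] = h_val),
    _["best_val_acc"] = best_val,
    _["steps"] = double(step),
    _["converged"] = stop);
}

// Apply one dihedral transform (1..7) to each slice of a stack.
// [[Rcpp::export(name = ".dihedral_stack")]]
arma::cube dihedral_stack(const arma::cube& X, const arma::ivec& ops) {
  if (X.n_rows != X.n_cols) stop("augmentation requires square images");
  if (ops.n_elem != X.n_slices) stop("one op per image required");
  cube out(X.n_rows, X.n_cols, X.n_slices);
  for (arma::uword i = 0; i < X.n_slices; ++i) {
    int op = ops(i);
    if (op < 1 || op > 7) stop("transform op must be in 1..7");
    out.slice(i) = dihedral(X.slice(i), op);
  }
  return out;
}

// Area-preserving (local mean) resampling of a square image to out_side.
// Each output pixel averages the input region it covers, with fractional
// pixel coverage handled exactly; exact block mean when sizes divide evenly.
// [[Rcpp::export(name = ".area_resample")]]
arma::mat area_resample(const arma::mat& img, int out_side) {
  const int H = img.n_rows, W = img.n_cols;
  if (H == out_side && W == out_side) return img;
  mat out(out_side, out_side, arma::fill::zeros);
  const double sy = double(H) / out_side, sx = double(W) / out_side;
  for (int jo = 0; jo < out_side; ++jo) {
    const double x0 = jo * sx, x1 = (jo + 1) * sx;
    const int jlo = int(std::floor(x0)), jhi = std::min(int(std::ceil(x1)), W);
    for (int io = 0; io < out_side; ++io) {
      const double y0 = io * sy, y1 = (io + 1) * sy;
      const int ilo = int(std::floor(y0)), ihi = std::min(int(std::ceil(y1)), H);
      double acc = 0.0, area = 0.0;
      for (int j = jlo; j < jhi; ++j) {
        const double wx = std::min(double(j + 1), x1) - std::max(double(j), x0);
        if (wx <= 0) continue;
        for (int i = ilo; i < ihi; ++i) {
          const double wy = std::min(double(i + 1), y1) - std::max(double(i), y0);
          if (wy <= 0) continue;
          acc += img(i, j) * wx * wy;
          area += wx * wy;
        }
      }
      out(io, jo) = acc / area;
    }
  }
  return out;
}
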