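// U-shaped fully convolutional network for root segmentation.
//
// The network follows the classic encoder/decoder layout with skip
// connections, with three departures from the original design: all 3x3
// convolutions are zero-padded so spatial size is preserved, batch
// normalization follows every convolution and every down/up-sampling
// step, and the head emits a single sigmoid channel (one class: root).
//
// Implemented here from first principles (im2col convolutions, batch
// norm with batch statistics, 2x2 max pooling, nearest-neighbour
// upsampling) because the full training loop -- forward, backward and
// per-parameter gradients for Adam -- must be available to the R side.

#include <RcppArmadillo.h>
using namespace arma;

static const double BN_EPS = 1e-5;

enum OpType { OP_CONV, OP_BN, OP_RELU, OP_POOL, OP_UPSAMPLE, OP_CONCAT, OP_SAVESKIP };

struct TapeOp {
  OpType type;
  int param_idx;  // index into param list for CONV/BN, else -1
  int skip_id;    // for CONCAT/SAVESKIP
  int k;          // conv kernel size (1 or 3)
};

struct ParamSpec {
  bool is_conv;
  int cin, cout, k;  // conv
  int channels;      // bn
  std::string name;
};

// Build the op tape and parameter layout for a given depth/width.
static void build_tape(int levels, int base, int in_ch,
                       std::vector<TapeOp>& ops, std::vector<ParamSpec>& specs) {
  ops.clear(); specs.clear();
  auto add_conv = [&](int cin, int cout, int k, const std::string& nm) {
    ParamSpec s; s.is_conv = true; s.cin = cin; s.cout = cout; s.k = k; s.channels = 0;
    s.name = nm; specs.push_back(s);
    ops.push_back({OP_CONV, (int)specs.size() - 1, -1, k});
  };
  auto add_bn = [&](int ch, const std::string& nm) {
    ParamSpec s; s.is_conv = false; s.cin = 0; s.cout = 0; s.k = 0; s.channels = ch;
    s.name = nm; specs.push_back(s);
    ops.push_back({OP_BN, (int)specs.size() - 1, -1, 0});
  };
  auto relu = [&]() { ops.push_back({OP_RELU, -1, -1, 0}); };

  int prev = in_ch;
  for (int i = 0; i < levels; ++i) {
    int c = base << i;
    std::string tag = "enc" + std::to_string(i + 1);
    add_conv(prev, c, 3, tag + "a"); add_bn(c, tag + "a_bn"); relu();
    add_conv(c, c, 3, tag + "b");    add_bn(c, tag + "b_bn"); relu();
    ops.push_back({OP_SAVESKIP, -1, i, 0});
    ops.push_back({OP_POOL, -1, -1, 0});
    add_bn(c, "pool" + std::to_string(i + 1) + "_bn");
    prev = c;
  }
  int cb = base << levels;
  add_conv(prev, cb, 3, "bota"); add_bn(cb, "bota_bn"); relu();
  add_conv(cb, cb, 3, "botb");   add_bn(cb, "botb_bn"); relu();
  prev = cb;
  for (int i = levels - 1; i >= 0; --i) {
    int c = base << i;
    std::string tag = "dec" + std::to_string(i + 1);
    ops.push_back({OP_UPSAMPLE, -1, -1, 0});
    add_bn(prev, "up" + std::to_string(i + 1) + "_bn");
    ops.push_back({OP_CONCAT, -1, i, 0});
    add_conv(prev + c, c, 3, tag + "a"); add_bn(c, tag + "a_bn"); relu();
    add_conv(c, c, 3, tag + "b");        add_bn(c, tag + "b_bn"); relu();
    prev = c;
  }
  add_conv(prev, 1, 1, "head");
}

typedef std::vector<cube> Batch;

// ---- convolution via im2col --------------------------------------------

static mat im2col(const cube& X, int k) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  if (k == 1) {
    mat M(H * W, C);
    for (int ch = 0; ch < C; ++ch) M.col(ch) = vectorise(X.slice(ch));
    return M;
  }
  mat M(H * W, 9 * C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const mat& S = X.slice(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        int col_idx = ch * 9 + (dc + 1) * 3 + (dr + 1);
        int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
        int c0 = std::max(0, -dc), c1 = std::min(W - 1, W - 1 - dc);
        for (int c = c0; c <= c1; ++c) {
          M.col(col_idx).subvec(c * H + r0, c * H + r1) =
            S(span(r0 + dr, r1 + dr), c + dc);
        }
      }
    }
  }
  return M;
}

static cube col2im(const mat& cols, int H, int W, int C, int k) {
  cube dX(H, W, C, fill::zeros);
  if (k == 1) {
    for (int ch = 0; ch < C; ++ch)
      dX.slice(ch) = reshape(cols.col(ch), H, W);
    return dX;
  }
  for (int ch = 0; ch < C; ++ch) {
    mat& S = dX.slice(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        int col_idx = ch * 9 + (dc + 1) * 3 + (dr + 1);
        int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
        int c0 = std::max(0, -dc), c1 = std::min(W - 1, W - 1 - dc);
        for (int c = c0; c <= c1; ++c) {
          S(span(r0 + dr, r1 + dr), c + dc) +=
            cols.col(col_idx).subvec(c * H + r0, c * H + r1);
        }
      }
    }
  }
  return dX;
}

static Batch conv_fwd(const Batch& X, const mat& W, const rowvec& b, int k) {
  Batch Y(X.size());
  const int cout = W.n_cols;
  for (size_t s = 0; s < X.size(); ++s) {
    const int H = X[s].n_rows, Wd = X[s].n_cols;
    mat M = im2col(X[s], k) * W;
    M.each_row() += b;
    cube Yc(H, Wd, cout);
    for (int o = 0; o < cout; ++o) Yc.slice(o) = reshape(M.col(o), H, Wd);
    Y[s] = std::move(Yc);
  }
  return Y;
}

static Batch conv_bwd(const Batch& X, const Batch& dY, const mat& W, int k,
                      mat& dW, rowvec& db) {
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(W.n_cols);
  Batch dX(X.size());
  for (size_t s = 0; s < X.size(); ++s) {
    const int H = X[s].n_rows, Wd = X[s].n_cols, C = X[s].n_slices;
    const int cout = W.n_cols;
    mat dYm(H * Wd, cout);
    for (int o = 0; o < cout; ++o) dYm.col(o) = vectorise(dY[s].slice(o));
    mat cols = im2col(X[s], k);
    dW += cols.t() * dYm;
    db += sum(dYm, 0);
    dX[s] = col2im(dYm * W.t(), H, Wd, C, k);
  }
  return dX;
}

// ---- batch normalization ------------------------------------------------

struct BNCache { rowvec mean, invstd; };

static Batch bn_fwd(const Batch& X, const rowvec& gamma, const rowvec& beta,
                    rowvec& rm, rowvec& rv, double momentum, bool train,
                    BNCache& cache) {
  const int C = X[0].n_slices;
  const double n_per = X[0].n_rows * X[0].n_cols;
  const double N = n_per * X.size();
  rowvec mean(C), var(C);
  if (train) {
    mean.zeros(); var.zeros();
    for (const cube& x : X)
      for (int ch = 0; ch < C; ++ch) mean(ch) += accu(x.slice(ch));
    mean /= N;
    for (const cube& x : X)
      for (int ch = 0; ch < C; ++ch)
        var(ch) += accu(square(x.slice(ch) - mean(ch)));
    var /= N;
    rm = (1.0 - momentum) * rm + momentum * mean;
    rv = (1.0 - momentum) * rv + momentum * var;
  } else {
    mean = rm; var = rv;
  }
  cache.mean = mean;
  cache.invstd = 1.0 / sqrt(var + BN_EPS);
  Batch Y(X.size());
  for (size_t s = 0; s < X.size(); ++s) {
    cube y(X[s].n_rows, X[s].n_cols, C);
    for (int ch = 0; ch < C; ++ch)
      y.slice(ch) = gamma(ch) * ((X[s].slice(ch) - mean(ch)) * cache.invstd(ch)) + beta(ch);
    Y[s] = std::move(y);
  }
  return Y;
}

static Batch bn_bwd(const Batch& X, const Batch& dY, const rowvec& gamma,
                    const BNCache& cache, rowvec& dgamma, rowvec& dbeta) {
  const int C = X[0].n_slices;
  const double N = (double)X[0].n_rows * X[0].n_cols * X.size();
  dgamma.zeros(C); dbeta.zeros(C);
  rowvec s1(C, fill::zeros), s2(C, fill::zeros);
  for (size_t s = 0; s < X.size(); ++s) {
    for (int ch = 0; ch < C; ++ch) {
      mat xhat = (X[s].slice(ch) - cache.mean(ch)) * cache.invstd(ch);
      s1(ch) += accu(dY[s].slice(ch));
      s2(ch) += accu(dY[s].slice(ch) % xhat);
    }
  }
  dbeta = s1; dgamma = s2;
  Batch dX(X.size());
  for (size_t s = 0; s < X.size(); ++s) {
    cube dx(X[s].n_rows, X[s].n_cols, C);
    for (int ch = 0; ch < C; ++ch) {
      mat xhat = (X[s].slice(ch) - cache.mean(ch)) * cache.invstd(ch);
      dx.slice(ch) = gamma(ch) * cache.invstd(ch) *
        (dY[s].slice(ch) - s1(ch) / N - xhat * (s2(ch) / N));
    }
    dX[s] = std::move(dx);
  }
  return dX;
}

// ---- pooling / upsampling ----------------------------------------------

static Batch pool_fwd(const Batch& X, std::vector<ucube>& argmax) {
  Batch Y(X.size());
  argmax.resize(X.size());
  for (size_t s = 0; s < X.size(); ++s) {
    const int H = X[s].n_rows / 2, W = X[s].n_cols / 2, C = X[s].n_slices;
    cube y(H, W, C);
    ucube am(H, W, C);
    for (int ch = 0; ch < C; ++ch) {
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          double best = -datum::inf; unsigned idx = 0;
          for (int di = 0; di < 2; ++di)
            for (int dj = 0; dj < 2; ++dj) {
              double v = X[s](2 * r + di, 2 * c + dj, ch);
              if (v > best) { best = v; idx = di * 2 + dj; }
            }
          y(r, c, ch) = best; am(r, c, ch) = idx;
        }
      }
    }
    Y[s] = std::move(y); argmax[s] = std::move(am);
  }
  return Y;
}

static Batch pool_bwd(const Batch& dY, const std::vector<ucube>& argmax) {
  Batch dX(dY.size());
  for (size_t s = 0; s < dY.size(); ++s) {
    const int H = dY[s].n_rows, W = dY[s].n_cols, C = dY[s].n_slices;
    cube dx(2 * H, 2 * W, C, fill::zeros);
    for (int ch = 0; ch < C; ++ch)
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          unsigned idx = argmax[s](r, c, ch);
          dx(2 * r + idx / 2, 2 * c + idx % 2, ch) = dY[s](r, c, ch);
        }
    dX[s] = std::move(dx);
  }
  return dX;
}

static Batch upsample_fwd(const Batch& X) {
  Batch Y(X.size());
  for (size_t s = 0; s < X.size(); ++s) {
    const int H = X[s].n_rows, W = X[s].n_cols, C = X[s].n_slices;
    cube y(2 * H, 2 * W, C);
    for (int ch = 0; ch < C; ++ch)
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          double v = X[s](r, c, ch);
          y(2 * r, 2 * c, ch) = v; y(2 * r + 1, 2 * c, ch) = v;
          y(2 * r, 2 * c + 1, ch) = v; y(2 * r + 1, 2 * c + 1, ch) = v;
        }
    Y[s] = std::move(y);
  }
  return Y;
}

static Batch upsample_bwd(const Batch& dY) {
  Batch dX(dY.size());
  for (size_t s = 0; s < dY.size(); ++s) {
    const int H = dY[s].n_rows / 2, W = dY[s].n_cols / 2, C = dY[s].n_slices;
    cube dx(H, W, C);
    for (int ch = 0; ch < C; ++ch)
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r)
          dx(r, c, ch) = dY[s](2 * r, 2 * c, ch) + dY[s](2 * r + 1, 2 * c, ch) +
                         dY[s](2 * r, 2 * c + 1, ch) + dY[s](2 * r + 1, 2 * c + 1, ch);
    dX[s] = std::move(dx);
  }
  return dX;
}

// ---- parameter marshalling ---------------------------------------------

struct Params {
  std::vector<mat> W;        // conv weights, (k*k*cin) x cout
  std::vector<rowvec> b;     // conv bias
  std::vector<rowvec> gamma, beta, rm, rv;  // bn (rm/rv updated in place)
};

static Params read_params(const Rcpp::List& plist, const std::vector<ParamSpec>& specs) {
  Params P;
  P.W.resize(specs.size()); P.b.resize(specs.size());
  P.gamma.resize(specs.size()); P.beta.resize(specs.size());
  P.rm.resize(specs.size()); P.rv.resize(specs.size());
  for (size_t i = 0; i < specs.size(); ++i) {
    Rcpp::List g = plist[i];
    if (specs[i].is_conv) {
      P.W[i] = Rcpp::as<mat>(g["W"]);
      P.b[i] = Rcpp::as<rowvec>(g["b"]);
    } else {
      P.gamma[i] = Rcpp::as<rowvec>(g["gamma"]);
      P.beta[i] = Rcpp::as<rowvec>(g["beta"]);
      P.rm[i] = Rcpp::as<rowvec>(g["running_mean"]);
      P.rv[i] = Rcpp::as<rowvec>(g["running_var"]);
    }
  }
  return P;
}

static Batch read_batch(const Rcpp::List& xs, int in_ch) {
  Batch X(xs.size());
  for (int i = 0; i < xs.size(); ++i) {
    Rcpp::NumericVector a(xs[i]);
    Rcpp::IntegerVector dim = a.attr("dim");
    int H = dim[0], W = dim[1], C = (dim.size() == 3) ? dim[2] : 1;
    if (C != in_ch) Rcpp::stop("input has %d channels, expected %d", C, in_ch);
    X[i] = cube(a.begin(), H, W, C);
  }
  return X;
}

// Forward pass through the tape. Stores per-op outputs when `keep` is true.
struct Trace {
  std::vector<Batch> acts;                 // output of each op
  std::vector<std::vector<ucube>> pool_am; // per pool op
  std::vector<BNCache> bn_cache;           // per bn op
};

static Batch tape_forward(const std::vector<TapeOp>& ops, Params& P, const Batch& input,
                          bool train, double momentum, bool keep, Trace* tr) {
  std::map<int, Batch> skips;
  Batch cur = input;
  if (keep) {
    tr->acts.resize(ops.size());
    tr->pool_am.resize(ops.size());
    tr->bn_cache.resize(ops.size());
  }
  for (size_t t = 0; t < ops.size(); ++t) {
    const TapeOp& op = ops[t];
    switch (op.type) {
      case OP_CONV:
        cur = conv_fwd(cur, P.W[op.param_idx], P.b[op.param_idx], op.k);
        break;
      case OP_BN: {
        BNCache cache;
        cur = bn_fwd(cur, P.gamma[op.param_idx], P.beta[op.param_idx],
                     P.rm[op.param_idx], P.rv[op.param_idx], momentum, train, cache);
        if (keep) tr->bn_cache[t] = cache;
        break;
      }
      case OP_RELU:
        for (cube& x : cur) x.transform([](double v) { return v > 0 ? v : 0.0; });
        break;
      case OP_POOL: {
        std::vector<ucube> am;
        cur = pool_fwd(cur, am);
        if (keep) tr->pool_am[t] = std::move(am);
        break;
      }
      case OP_UPSAMPLE:
        cur = upsample_fwd(cur);
        break;
      case OP_CONCAT: {
        const Batch& sk = skips[op.skip_id];
        Batch joined(cur.size());
        for (size_t s = 0; s < cur.size(); ++s)
          joined[s] = join_slices(cur[s], sk[s]);
        cur = std::move(joined);
        break;
      }
      case OP_SAVESKIP:
        skips[op.skip_id] = cur;
        break;
    }
    if (keep) tr->acts[t] = cur;
  }
  return cur;
}

// ---- exported API -------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List unet_init_cpp(int levels, int base, int in_ch) {
  std::vector<TapeOp> ops; std::vector<ParamSpec> specs;
  build_tape(levels, base, in_ch, ops, specs);
  Rcpp::List out(specs.size());
  Rcpp::CharacterVector names(specs.size());
  for (size_t i = 0; i < specs.size(); ++i) {
    names[i] = specs[i].name;
    if (specs[i].is_conv) {
      int K = specs[i].k * specs[i].k * specs[i].cin;
      double sd = std::sqrt(2.0 / K);  // He initialization
      Rcpp::NumericVector w = Rcpp::rnorm(K * specs[i].cout, 0.0, sd);
      Rcpp::NumericMatrix W(K, specs[i].cout, w.begin());
      out[i] = Rcpp::List::create(
        Rcpp::Named("type") = "conv", Rcpp::Named("W") = W,
        Rcpp::Named("b") = Rcpp::NumericVector(specs[i].cout, 0.0));
    } else {
      int C = specs[i].channels;
      out[i] = Rcpp::List::create(
        Rcpp::Named("type") = "bn",
        Rcpp::Named("gamma") = Rcpp::NumericVector(C, 1.0),
        Rcpp::Named("beta") = Rcpp::NumericVector(C, 0.0),
        Rcpp::Named("running_mean") = Rcpp::NumericVector(C, 0.0),
        Rcpp::Named("running_var") = Rcpp::NumericVector(C, 1.0));
    }
  }
  out.attr("names") = names;
  return out;
}

// One training step: forward with batch statistics, loss, full backward.
// Returns per-parameter gradients, updated running statistics and the
// batch probability maps (for Dice bookkeeping on the R side).
// [[Rcpp::export]]
Rcpp::List unet_grad_cpp(Rcpp::List params, Rcpp::List xs, Rcpp::List ys,
                         int levels, int base, int in_ch,
                         std::string loss_type, double momentum) {
  std::vector<TapeOp> ops; std::vector<ParamSpec> specs;
  build_tape(levels, base, in_ch, ops, specs);
  Params P = read_params(params, specs);
  Batch X = read_batch(xs, in_ch);
  Batch Y = read_batch(ys, 1);
  const size_t B = X.size();

  Trace tr;
  Batch logits = tape_forward(ops, P, X, true, momentum, true, &tr);

  // sigmoid + loss + gradient w.r.t. logits
  double loss = 0.0;
  double npix = 0.0;
  for (size_t s = 0; s < B; ++s) npix += logits[s].n_rows * logits[s].n_cols;
  Batch dZ(B);
  Rcpp::List probs_out(B);
  if (loss_type == "dice") {
    double sp = 0, sy = 0, spy = 0;
    Batch prob(B);
    for (size_t s = 0; s < B; ++s) {
      prob[s] = 1.0 / (1.0 + exp(-logits[s]));
      sp += accu(prob[s]); sy += accu(Y[s]); spy += accu(prob[s] % Y[s]);
    }
    const double smooth = 1.0;
    double num = 2.0 * spy + smooth, den = sp + sy + smooth;
    loss = 1.0 - num / den;
    for (size_t s = 0; s < B; ++s) {
      cube dp = -(2.0 * Y[s] * den - num) / (den * den);
      dZ[s] = dp % prob[s] % (1.0 - prob[s]);
      probs_out[s] = Rcpp::wrap(mat(prob[s].slice(0)));
    }
  } else {  // binary cross-entropy with logits
    for (size_t s = 0; s < B; ++s) {
      const cube& z = logits[s];
      cube p = 1.0 / (1.0 + exp(-z));
      // stable: max(z,0) - z*y + log(1+exp(-|z|))
      cube zmax = z; zmax.transform([](double v) { return v > 0 ? v : 0.0; });
      cube labs = log(1.0 + exp(-abs(z)));
      loss += accu(zmax - z % Y[s] + labs);
      dZ[s] = (p - Y[s]) / npix;
      probs_out[s] = Rcpp::wrap(mat(p.slice(0)));
    }
    loss /= npix;
  }

  // backward over the tape
  std::vector<mat> dW(specs.size());
  std::vector<rowvec> db(specs.size()), dgamma(specs.size()), dbeta(specs.size());
  std::map<int, Batch> skip_grad;
  std::map<int, std::pair<int, int>> concat_split;  // skip_id -> (n_cur, n_skip)
  for (size_t t = 0; t < ops.size(); ++t)
    if (ops[t].type == OP_CONCAT) {
      int n_total = tr.acts[t][0].n_slices;
      int n_cur = (t > 0) ? tr.acts[t - 1][0].n_slices : 0;
      concat_split[ops[t].skip_id] = {n_cur, n_total - n_cur};
    }

  Batch grad = dZ;
  for (int t = (int)ops.size() - 1; t >= 0; --t) {
    const TapeOp& op = ops[t];
    const Batch& in = (t > 0) ? tr.acts[t - 1] : X;
    switch (op.type) {
      case OP_CONV: {
        mat dw; rowvec dbv;
        grad = conv_bwd(in, grad, P.W[op.param_idx], op.k, dw, dbv);
        dW[op.param_idx] = std::move(dw); db[op.param_idx] = std::move(dbv);
        break;
      }
      case OP_BN: {
        rowvec dg, dbta;
        grad = bn_bwd(in, grad, P.gamma[op.param_idx], tr.bn_cache[t], dg, dbta);
        dgamma[op.param_idx] = std::move(dg); dbeta[op.param_idx] = std::move(dbta);
        break;
      }
      case OP_RELU: {
        const Batch& out = tr.acts[t];
        for (size_t s = 0; s < grad.size(); ++s)
          grad[s] = grad[s] % (out[s] > 0);
        break;
      }
      case OP_POOL:
        grad = pool_bwd(grad, tr.pool_am[t]);
        break;
      case OP_UPSAMPLE:
        grad = upsample_bwd(grad);
        break;
      case OP_CONCAT: {
        auto split = concat_split[op.skip_id];
        Batch gcur(grad.size()), gskip(grad.size());
        for (size_t s = 0; s < grad.size(); ++s) {
          gcur[s] = grad[s].slices(0, split.first - 1);
          gskip[s] = grad[s].slices(split.first, split.first + split.second - 1);
        }
        skip_grad[op.skip_id] = std::move(gskip);
        grad = std::move(gcur);
        break;
      }
      case OP_SAVESKIP: {
        const Batch& sg = skip_grad[op.skip_id];
        for (size_t s = 0; s < grad.size(); ++s) grad[s] += sg[s];
        break;
      }
    }
  }

  Rcpp::List grads(specs.size());
  for (size_t i = 0; i < specs.size(); ++i) {
    if (specs[i].is_conv) {
      grads[i] = Rcpp::List::create(Rcpp::Named("W") = Rcpp::wrap(dW[i]),
                                    Rcpp::Named("b") = Rcpp::wrap(db[i]));
    } else {
      grads[i] = Rcpp::List::create(
        Rcpp::Named("gamma") = Rcpp::wrap(dgamma[i]),
        Rcpp::Named("beta") = Rcpp::wrap(dbeta[i]),
        Rcpp::Named("running_mean") = Rcpp::wrap(P.rm[i]),
        Rcpp::Named("running_var") = Rcpp::wrap(P.rv[i]));
    }
  }
  grads.attr("names") = params.attr("names");
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads,
                            Rcpp::Named("probs") = probs_out);
}

// Inference: forward pass with running batch-norm statistics.
// [[Rcpp::export]]
Rcpp::List unet_predict_cpp(Rcpp::List params, Rcpp::List xs,
                            int levels, int base, int in_ch) {
  std::vector<TapeOp> ops; std::vector<ParamSpec> specs;
  build_tape(levels, base, in_ch, ops, specs);
  Params P = read_params(params, specs);
  Batch X = read_batch(xs, in_ch);
  Batch logits = tape_forward(ops, P, X, false, 0.0, false, nullptr);
  Rcpp::List out(X.size());
  for (size_t s = 0; s < X.size(); ++s) {
    mat p = 1.0 / (1.0 + exp(-logits[s].slice(0)));
    out[s] = Rcpp::wrap(p);
  }
  return out;
}
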