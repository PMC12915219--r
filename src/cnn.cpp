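// Convolutional encoder / residual / DUS / decoder network for SoS-map
// reconstruction from stacked ToF inputs, with its own backprop and Adam
// training loop. Feature maps are arma::mat of shape (channels x H*W) with
// column-major spatial indexing (ix * H + iy); all convolutions are 3x3
// with "same" padding, stride 1 or 2. Upsampling is depth-to-space with
// block size 2.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct NetConfig {
  int H;      // input/output side
  int C;      // base channels
  int nEnc;   // encoder residual blocks
  int nDec;   // decoder residual blocks
  int nDUS;   // down-up-scaling units
};

static NetConfig readConfig(IntegerVector cfg) {
  NetConfig c;
  c.H = cfg["H"]; c.C = cfg["C"];
  c.nEnc = cfg["nEnc"]; c.nDec = cfg["nDec"]; c.nDUS = cfg["nDUS"];
  if (c.H % 4 != 0)
    stop("spatial size must be divisible by the cumulative stride (4)");
  return c;
}

// ---- conv primitives -------------------------------------------------------

static arma::mat im2col(const arma::mat& X, int H, int W, int stride) {
  const int Cin = X.n_rows;
  const int Ho = H / stride, Wo = W / stride;
  arma::mat col(Cin * 9, (size_t)Ho * Wo, arma::fill::zeros);
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      const size_t cc = (size_t)ox * Ho + oy;
      for (int dx = -1; dx <= 1; ++dx) {
        const int ix = ox * stride + dx;
        if (ix < 0 || ix >= W) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int iy = oy * stride + dy;
          if (iy < 0 || iy >= H) continue;
          const int koff = (dy + 1) * 3 + (dx + 1);
          const size_t src = (size_t)ix * H + iy;
          for (int c = 0; c < Cin; ++c)
            col(c * 9 + koff, cc) = X(c, src);
        }
      }
    }
  }
  return col;
}

static arma::mat col2im(const arma::mat& dcol, int Cin, int H, int W,
                        int stride) {
  const int Ho = H / stride, Wo = W / stride;
  arma::mat dX(Cin, (size_t)H * W, arma::fill::zeros);
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      const size_t cc = (size_t)ox * Ho + oy;
      for (int dx = -1; dx <= 1; ++dx) {
        const int ix = ox * stride + dx;
        if (ix < 0 || ix >= W) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int iy = oy * stride + dy;
          if (iy < 0 || iy >= H) continue;
          const int koff = (dy + 1) * 3 + (dx + 1);
          const size_t dst = (size_t)ix * H + iy;
          for (int c = 0; c < Cin; ++c)
            dX(c, dst) += dcol(c * 9 + koff, cc);
        }
      }
    }
  }
  return dX;
}

// depth-to-space, block 2: (4C x H*W) -> (C x 2H*2W)
static arma::mat d2s(const arma::mat& X, int H, int W) {
  const int C = X.n_rows / 4;
  const int H2 = 2 * H, W2 = 2 * W;
  arma::mat Y(C, (size_t)H2 * W2);
  for (int ox = 0; ox < W2; ++ox) {
    const int ix = ox / 2, dj = ox % 2;
    for (int oy = 0; oy < H2; ++oy) {
      const int iy = oy / 2, di = oy % 2;
      const size_t src = (size_t)ix * H + iy, dst = (size_t)ox * H2 + oy;
      for (int c = 0; c < C; ++c)
        Y(c, dst) = X(c * 4 + di * 2 + dj, src);
    }
  }
  return Y;
}

static arma::mat d2s_back(const arma::mat& dY, int H, int W) {
  const int C = dY.n_rows;
  const int H2 = 2 * H, W2 = 2 * W;
  arma::mat dX(C * 4, (size_t)H * W);
  for (int ox = 0; ox < W2; ++ox) {
    const int ix = ox / 2, dj = ox % 2;
    for (int oy = 0; oy < H2; ++oy) {
      const int iy = oy / 2, di = oy % 2;
      const size_t dst = (size_t)ix * H + iy, src = (size_t)ox * H2 + oy;
      for (int c = 0; c < C; ++c)
        dX(c * 4 + di * 2 + dj, dst) = dY(c, src);
    }
  }
  return dX;
}

static inline arma::mat relu(const arma::mat& x) {
  return arma::clamp(x, 0.0, arma::datum::inf);
}

static inline arma::mat reluMask(const arma::mat& pre) {
  return arma::conv_to<arma::mat>::from(pre > 0.0);
}

// ---- parameter plumbing ----------------------------------------------------

struct Params {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

static Params readParams(List plist) {
  Params p;
  List Wl = plist["W"], bl = plist["b"];
  for (int i = 0; i < Wl.size(); ++i) {
    p.W.push_back(as<arma::mat>(Wl[i]));
    p.b.push_back(as<arma::vec>(bl[i]));
  }
  return p;
}

static List writeParams(const Params& p) {
  List Wl(p.W.size()), bl(p.b.size());
  for (size_t i = 0; i < p.W.size(); ++i) {
    Wl[i] = wrap(p.W[i]);
    bl[i] = wrap(p.b[i]);
  }
  return List::create(_["W"] = Wl, _["b"] = bl);
}

// expected parameter count: conv0 + 2/enc-res + 2/DUS + 2/dec-res + out
static int nLayers(const NetConfig& c) {
  return 1 + 2 * c.nEnc + 2 * c.nDUS + 2 * c.nDec + 1;
}

// ---- forward / backward ----------------------------------------------------

struct Tape { // per-image caches needed by backward
  arma::mat x0, col0, a0pre;
  std::vector<arma::mat> resIn, resCol1, resA1pre, resCol2, resSumPre;
  std::vector<arma::mat> dusIn, dusColD, dusDpre, dusColP, dusPpre, dusSumPre;
  arma::mat enc, g, colOut;
};

static arma::mat forwardOne(const Params& p, const NetConfig& c,
                            const arma::mat& x0, Tape* tape) {
  const int H = c.H, H2 = H / 2, H4 = H / 4;
  int li = 0;
  // stride-2 feature extraction
  arma::mat col0 = im2col(x0, H, H, 2);
  arma::mat a0pre = p.W[li] * col0;
  a0pre.each_col() += p.b[li];
  ++li;
  arma::mat a = relu(a0pre);
  if (tape) { tape->x0 = x0; tape->col0 = col0; tape->a0pre = a0pre; }

  auto resBlock = [&](arma::mat& z, std::vector<arma::mat>* in,
                      std::vector<arma::mat>* col1, std::vector<arma::mat>* a1p,
                      std::vector<arma::mat>* col2, std::vector<arma::mat>* sp) {
    arma::mat c1 = im2col(z, H2, H2, 1);
    arma::mat a1pre = p.W[li] * c1; a1pre.each_col() += p.b[li]; ++li;
    arma::mat a1 = relu(a1pre);
    arma::mat c2 = im2col(a1, H2, H2, 1);
    arma::mat a2 = p.W[li] * c2; a2.each_col() += p.b[li]; ++li;
    arma::mat spre = z + a2;
    if (tape) {
      in->push_back(z); col1->push_back(c1); a1p->push_back(a1pre);
      col2->push_back(c2); sp->push_back(spre);
    }
    z = relu(spre);
  };

  for (int r = 0; r < c.nEnc; ++r)
    resBlock(a, &tape->resIn, &tape->resCol1, &tape->resA1pre,
             &tape->resCol2, &tape->resSumPre);
  arma::mat e = a;
  if (tape) tape->enc = e;

  arma::mat m = e;
  for (int d = 0; d < c.nDUS; ++d) {
    arma::mat colD = im2col(m, H2, H2, 2);
    arma::mat dpre = p.W[li] * colD; dpre.each_col() += p.b[li]; ++li;
    arma::mat dact = relu(dpre);
    arma::mat colP = im2col(dact, H4, H4, 1);
    arma::mat ppre = p.W[li] * colP; ppre.each_col() += p.b[li]; ++li;
    arma::mat pact = relu(ppre);
    arma::mat u = d2s(pact, H4, H4);
    arma::mat spre = m + u;
    if (tape) {
      tape->dusIn.push_back(m); tape->dusColD.push_back(colD);
      tape->dusDpre.push_back(dpre); tape->dusColP.push_back(colP);
      tape->dusPpre.push_back(ppre); tape->dusSumPre.push_back(spre);
    }
    m = relu(spre);
  }

  for (int r = 0; r < c.nDec; ++r)
    resBlock(m, &tape->resIn, &tape->resCol1, &tape->resA1pre,
             &tape->resCol2, &tape->resSumPre);

  arma::mat g = m + e; // long skip, linear
  arma::mat colOut = im2col(g, H2, H2, 1);
  arma::mat y4 = p.W[li] * colOut; y4.each_col() += p.b[li]; ++li;
  if (tape) { tape->g = g; tape->colOut = colOut; }
  return d2s(y4, H2, H2); // 1 x H*H
}

// forward without caches (inference)
static arma::mat forwardInfer(const Params& p, const NetConfig& c,
                              const arma::mat& x0) {
  Tape tape; // cheap enough; reuse the same path for correctness
  return forwardOne(p, c, x0, &tape);
}

static void backwardOne(const Params& p, const NetConfig& c, const Tape& t,
                        const arma::mat& dy, Params& grad) {
  const int H = c.H, H2 = H / 2, H4 = H / 4;
  int li = nLayers(c) - 1;
  // output head
  arma::mat dy4 = d2s_back(dy, H2, H2); // 4 x (H2*H2)
  grad.W[li] += dy4 * t.colOut.t();
  grad.b[li] += arma::sum(dy4, 1);
  arma::mat dcol = p.W[li].t() * dy4;
  arma::mat dg = col2im(dcol, p.W[li].n_cols / 9, H2, H2, 1);
  --li;
  arma::mat dm = dg;      // decoder output grad
  arma::mat de = dg;      // long-skip grad into encoder output

  auto resBlockBack = [&](arma::mat& dz, int idx) {
    const arma::mat& spre = t.resSumPre[idx];
    arma::mat dr = dz % reluMask(spre);
    arma::mat da2 = dr;
    grad.W[li] += da2 * t.resCol2[idx].t();
    grad.b[li] += arma::sum(da2, 1);
    arma::mat dc2 = p.W[li].t() * da2;
    arma::mat da1 = col2im(dc2, p.W[li].n_cols / 9, H2, H2, 1);
    --li;
    da1 = da1 % reluMask(t.resA1pre[idx]);
    grad.W[li] += da1 * t.resCol1[idx].t();
    grad.b[li] += arma::sum(da1, 1);
    arma::mat dc1 = p.W[li].t() * da1;
    arma::mat dzin = col2im(dc1, p.W[li].n_cols / 9, H2, H2, 1);
    --li;
    dz = dr + dzin;
  };

  // decoder residual blocks (they are the last nDec entries of the res caches)
  for (int r = c.nDec - 1; r >= 0; --r)
    resBlockBack(dm, c.nEnc + r);

  // DUS units
  for (int d = c.nDUS - 1; d >= 0; --d) {
    arma::mat dr = dm % reluMask(t.dusSumPre[d]);
    arma::mat du = dr; // into the upsampled branch
    arma::mat dp = d2s_back(du, H4, H4);
    dp = dp % reluMask(t.dusPpre[d]);
    grad.W[li] += dp * t.dusColP[d].t();
    grad.b[li] += arma::sum(dp, 1);
    arma::mat dcp = p.W[li].t() * dp;
    arma::mat dd = col2im(dcp, p.W[li].n_cols / 9, H4, H4, 1);
    --li;
    dd = dd % reluMask(t.dusDpre[d]);
    grad.W[li] += dd * t.dusColD[d].t();
    grad.b[li] += arma::sum(dd, 1);
    arma::mat dcd = p.W[li].t() * dd;
    arma::mat dmin = col2im(dcd, p.W[li].n_cols / 9, H2, H2, 2);
    --li;
    dm = dr + dmin;
  }

  dm += de; // long skip joins behind the encoder blocks

  for (int r = c.nEnc - 1; r >= 0; --r)
    resBlockBack(dm, r);

  arma::mat da0 = dm % reluMask(t.a0pre);
  grad.W[li] += da0 * t.col0.t();
  grad.b[li] += arma::sum(da0, 1);
  --li;
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export(name = ".cnn_forward")]]
arma::cube cnn_forward(List plist, IntegerVector cfg, arma::cube X) {
  NetConfig c = readConfig(cfg);
  Params p = readParams(plist);
  if ((int)p.W.size() != nLayers(c)) stop("parameter list does not match config");
  arma::cube out(c.H, c.H, X.n_slices);
  for (size_t s = 0; s < X.n_slices; ++s) {
    arma::mat x0 = arma::vectorise(X.slice(s)).t();
    arma::mat y = forwardInfer(p, c, x0);
    out.slice(s) = arma::reshape(y.row(0).t(), c.H, c.H);
  }
  return out;
}

static double lossAndGrad(const Params& p, const NetConfig& c,
                          const arma::cube& X, const arma::cube& Y,
                          const arma::uvec& idx, Params& grad) {
  for (auto& g : grad.W) g.zeros();
  for (auto& g : grad.b) g.zeros();
  double loss = 0.0;
  const double scale = 1.0 / ((double)idx.n_elem * c.H * c.H);
  for (size_t q = 0; q < idx.n_elem; ++q) {
    const size_t s = idx[q];
    arma::mat x0 = arma::vectorise(X.slice(s)).t();
    Tape tape;
    arma::mat yhat = forwardOne(p, c, x0, &tape);
    arma::mat target = arma::vectorise(Y.slice(s)).t();
    arma::mat diff = yhat - target;
    loss += arma::accu(diff % diff) * scale;
    arma::mat dy = 2.0 * scale * diff;
    backwardOne(p, c, tape, dy, grad);
  }
  return loss;
}

static double valLoss(const Params& p, const NetConfig& c,
                      const arma::cube& X, const arma::cube& Y) {
  double loss = 0.0;
  const double scale = 1.0 / ((double)X.n_slices * c.H * c.H);
  for (size_t s = 0; s < X.n_slices; ++s) {
    arma::mat x0 = arma::vectorise(X.slice(s)).t();
    arma::mat yhat = forwardInfer(p, c, x0);
    arma::mat diff = yhat - arma::vectorise(Y.slice(s)).t();
    loss += arma::accu(diff % diff) * scale;
  }
  return loss;
}

// Loss and analytic parameter gradients for a sample set (exposed for
// finite-difference verification of the backward pass).
// [[Rcpp::export(name = ".cnn_loss_grad")]]
List cnn_loss_grad(List plist, IntegerVector cfg, arma::cube X, arma::cube Y) {
  NetConfig c = readConfig(cfg);
  Params p = readParams(plist);
  if ((int)p.W.size() != nLayers(c)) stop("parameter list does not match config");
  Params grad = p;
  arma::uvec idx(X.n_slices);
  for (size_t i = 0; i < X.n_slices; ++i) idx[i] = i;
  double loss = lossAndGrad(p, c, X, Y, idx, grad);
  return List::create(_["loss"] = loss, _["grad"] = writeParams(grad));
}

// Adam + reduce-on-plateau training loop with optional global gradient
// clipping and Polyak (EMA) weight averaging; validation is scored on the
// averaged weights when averaging is enabled. Returns the best-validation
// parameters, final parameters and the per-epoch history.
// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train(List plist, IntegerVector cfg, arma::cube X, arma::cube Y,
               arma::cube Xval, arma::cube Yval, int epochs, int batch,
               double lr0, double lrFactor, int patience, int seed,
               double clipNorm = 0.0, double emaDecay = 0.0,
               bool verbose = false) {
  NetConfig c = readConfig(cfg);
  Params p = readParams(plist);
  if ((int)p.W.size() != nLayers(c)) stop("parameter list does not match config");
  Params grad = p, m1 = p, m2 = p;
  for (auto& g : grad.W) g.zeros();
  for (auto& g : grad.b) g.zeros();
  for (auto& g : m1.W) g.zeros();
  for (auto& g : m1.b) g.zeros();
  for (auto& g : m2.W) g.zeros();
  for (auto& g : m2.b) g.zeros();

  const bool hasVal = Xval.n_slices > 0;
  std::mt19937 rng(seed);
  std::vector<size_t> order(X.n_slices);
  for (size_t i = 0; i < order.size(); ++i) order[i] = i;

  double lr = lr0;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long tstep = 0;
  double bestVal = arma::datum::inf;
  int stale = 0;
  Params best = p;
  Params ema = p;
  const bool useEma = emaDecay > 0.0;
  NumericVector hTrain(epochs), hVal(epochs), hLr(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double epochLoss = 0.0;
    int nb = 0;
    for (size_t start = 0; start < order.size(); start += batch) {
      const size_t stop_ = std::min(order.size(), start + batch);
      arma::uvec idx(stop_ - start);
      for (size_t k = start; k < stop_; ++k) idx[k - start] = order[k];
      epochLoss += lossAndGrad(p, c, X, Y, idx, grad);
      ++nb; ++tstep;
      if (clipNorm > 0.0) {
        double sq = 0.0;
        for (auto& g : grad.W) sq += arma::accu(g % g);
        for (auto& g : grad.b) sq += arma::accu(g % g);
        double nrm = std::sqrt(sq);
        if (nrm > clipNorm) {
          double sc = clipNorm / nrm;
          for (auto& g : grad.W) g *= sc;
          for (auto& g : grad.b) g *= sc;
        }
      }
      const double corr = std::sqrt(1.0 - std::pow(b2, (double)tstep)) /
                          (1.0 - std::pow(b1, (double)tstep));
      for (size_t i = 0; i < p.W.size(); ++i) {
        m1.W[i] = b1 * m1.W[i] + (1 - b1) * grad.W[i];
        m2.W[i] = b2 * m2.W[i] + (1 - b2) * (grad.W[i] % grad.W[i]);
        p.W[i] -= lr * corr * m1.W[i] / (arma::sqrt(m2.W[i]) + eps);
        m1.b[i] = b1 * m1.b[i] + (1 - b1) * grad.b[i];
        m2.b[i] = b2 * m2.b[i] + (1 - b2) * (grad.b[i] % grad.b[i]);
        p.b[i] -= lr * corr * m1.b[i] / (arma::sqrt(m2.b[i]) + eps);
      }
      if (useEma) {
        for (size_t i = 0; i < p.W.size(); ++i) {
          ema.W[i] = emaDecay * ema.W[i] + (1 - emaDecay) * p.W[i];
          ema.b[i] = emaDecay * ema.b[i] + (1 - emaDecay) * p.b[i];
        }
      }
    }
    epochLoss /= std::max(nb, 1);
    const Params& scored = useEma ? ema : p;
    double vl = hasVal ? valLoss(scored, c, Xval, Yval) : epochLoss;
    hTrain[ep] = epochLoss; hVal[ep] = vl; hLr[ep] = lr;
    if (vl < bestVal - 1e-12) {
      bestVal = vl; stale = 0; best = scored;
    } else if (++stale >= patience) {
      lr *= lrFactor; stale = 0;
    }
    if (verbose)
      Rcout << "epoch " << ep + 1 << " train " << epochLoss
            << " val " << vl << " lr " << lr << "\n";
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["best"] = writeParams(best),
                      _["final"] = writeParams(useEma ? ema : p),
                      _["trainLoss"] = hTrain, _["valLoss"] = hVal,
                      _["lr"] = hLr, _["bestVal"] = bestVal);
}
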