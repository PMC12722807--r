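// Twin-branch convolutional encoder: forward pass, backpropagation and
// Adam updates for contrastive training on recurrence-image pairs.
//
// Architecture (fixed): input 128x128x1 -> Conv 32@3x3 valid, ReLU ->
// MaxPool 2x2 -> Conv 64@3x3 valid, ReLU -> MaxPool 2x2 -> Flatten ->
// Dense 128, ReLU.  Single precision throughout.
//
// Implementation notes (single-CPU, memory-bandwidth-bound setting):
//  - feature maps are channel-major (channels x pixels, pixels in
//    column-major plane order), so per-image working sets stay small and
//    cache-resident;
//  - the first convolution uses im2col + GEMM; the second uses the
//    shift-GEMM formulation (nine accumulating GEMMs on contiguous
//    shifted views), which avoids materializing a large im2col buffer;
//  - bias + ReLU are folded into the max-pool pass: max(z)+b and
//    relu share monotonicity, so pooling raw pre-activations and applying
//    bias/ReLU to the pooled value is exact, and the backward ReLU mask is
//    simply "pooled output > 0";
//  - within one minibatch the weights are constant, so each distinct image
//    is forwarded/backpropagated once and its embedding gradient is the
//    sum over all pairs that use it (exactly the batch-mean gradient);
//  - the dense 57600x128 block is applied to all images of a batch in one
//    GEMM rather than per image.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;
typedef arma::Mat<arma::u8> u8mat;

namespace {

struct Dims {
  int S, c1, p1, c2v, p2, flat;
  // c2 grid keeps the conv1-pool size (p1 x p1); only the c2v x c2v
  // interior is valid after the second 3x3 valid convolution
  explicit Dims(int side) : S(side) {
    c1 = S - 2; p1 = c1 / 2; c2v = p1 - 2; p2 = c2v / 2; flat = p2 * p2 * 64;
  }
};

// internal parameter layout: W1t 32x9, W2 64x288 (9 contiguous 64x32
// offset slices), W3 flat x 128 (flatten index = channel + 64*pixel)
struct Params {
  fmat W1t, W2, W3;
  fvec b1, b2, b3;
};

struct Grads {
  fmat W1t, W2, W3;
  fvec b1, b2, b3;
  void zeros(const Params& p) {
    W1t.zeros(arma::size(p.W1t)); W2.zeros(arma::size(p.W2));
    W3.zeros(arma::size(p.W3));
    b1.zeros(p.b1.n_elem); b2.zeros(p.b2.n_elem); b3.zeros(p.b3.n_elem);
  }
};

// per-image state persisted from forward to backward within a batch
struct SlotCache {
  fmat col1;     // (c1*c1) x 9 im2col of the input
  fmat pool1t;   // 32 x (p1*p1), post bias+ReLU
  u8mat arg1;    // 32 x (p1*p1), which-of-4 pool argmax
  u8mat arg2;    // 64 x (p2*p2)
  void alloc(const Dims& d) {
    col1.set_size((uword)d.c1 * d.c1, 9);
    pool1t.set_size(32, (uword)d.p1 * d.p1);
    arg1.set_size(32, (uword)d.p1 * d.p1);
    arg2.set_size(64, (uword)d.p2 * d.p2);
  }
};

// transient per-image workspace
struct Scratch {
  fmat z1t;      // 32 x (c1*c1)
  fmat z2t;      // 64 x (p1*p1), valid interior c2v x c2v
  fmat dz1t, dz2t, dpool1t;
  void alloc(const Dims& d) {
    z1t.set_size(32, (uword)d.c1 * d.c1);
    z2t.zeros(64, (uword)d.p1 * d.p1);
    dz1t.zeros(32, (uword)d.c1 * d.c1);
    dz2t.zeros(64, (uword)d.p1 * d.p1);
    dpool1t.set_size(32, (uword)d.p1 * d.p1);
  }
};

// R-facing layouts: W1 9x32 (row = dr + 3*dc), W2 288x64
// (row = inch*9 + dr + 3*dc), W3 flat x 128
Params asParams(const List& weights) {
  Params p;
  arma::mat W1 = as<arma::mat>(weights["W1"]);
  arma::mat W2 = as<arma::mat>(weights["W2"]);
  p.W1t = arma::conv_to<fmat>::from(W1.t());
  p.W2.set_size(64, 288);
  for (int o = 0; o < 9; ++o)
    for (int inch = 0; inch < 32; ++inch)
      for (int outch = 0; outch < 64; ++outch)
        p.W2(outch, o * 32 + inch) = (float)W2(inch * 9 + o, outch);
  p.W3 = arma::conv_to<fmat>::from(as<arma::mat>(weights["W3"]));
  p.b1 = arma::conv_to<fvec>::from(as<arma::vec>(weights["b1"]));
  p.b2 = arma::conv_to<fvec>::from(as<arma::vec>(weights["b2"]));
  p.b3 = arma::conv_to<fvec>::from(as<arma::vec>(weights["b3"]));
  return p;
}

List paramsToList(const Params& p) {
  arma::mat W1 = arma::conv_to<arma::mat>::from(p.W1t.t());
  arma::mat W2(288, 64);
  for (int o = 0; o < 9; ++o)
    for (int inch = 0; inch < 32; ++inch)
      for (int outch = 0; outch < 64; ++outch)
        W2(inch * 9 + o, outch) = p.W2(outch, o * 32 + inch);
  return List::create(
    Named("W1") = wrap(W1),
    Named("b1") = wrap(arma::conv_to<arma::vec>::from(p.b1)),
    Named("W2") = wrap(W2),
    Named("b2") = wrap(arma::conv_to<arma::vec>::from(p.b2)),
    Named("W3") = wrap(arma::conv_to<arma::mat>::from(p.W3)),
    Named("b3") = wrap(arma::conv_to<arma::vec>::from(p.b3)));
}

void im2col1(const float* img, const Dims& d, fmat& col1) {
  const int S = d.S, oh = d.c1;
  for (int dc = 0; dc < 3; ++dc) {
    for (int dr = 0; dr < 3; ++dr) {
      float* dst = col1.colptr(dr + 3 * dc);
      for (int c = 0; c < oh; ++c) {
        const float* s = img + (uword)(c + dc) * S + dr;
        float* dcol = dst + (uword)c * oh;
        for (int r = 0; r < oh; ++r) dcol[r] = s[r];
      }
    }
  }
}

// 2x2 pool of channel-major map Z (nch x npix on an h x h grid, valid
// width vw), writing relu(max + b); out is nch x (vw/2)^2 (or a column of
// F for the second pool)
void poolBiasRelu(const fmat& Zt, int h, int vw, const fvec& b,
                  float* out, arma::u8* arg, int nch) {
  const int oh = vw / 2;
  for (int c = 0; c < oh; ++c) {
    for (int r = 0; r < oh; ++r) {
      const uword p00 = (uword)(2 * r) + (uword)(2 * c) * h;
      const float* s0 = Zt.colptr(p00);
      const float* s1 = Zt.colptr(p00 + 1);
      const float* s2 = Zt.colptr(p00 + h);
      const float* s3 = Zt.colptr(p00 + h + 1);
      float* o = out + (uword)(r + c * oh) * nch;
      arma::u8* a = arg + (uword)(r + c * oh) * nch;
      for (int ch = 0; ch < nch; ++ch) {
        float m = s0[ch];
        arma::u8 w = 0;
        if (s1[ch] > m) { m = s1[ch]; w = 1; }
        if (s2[ch] > m) { m = s2[ch]; w = 2; }
        if (s3[ch] > m) { m = s3[ch]; w = 3; }
        m += b(ch);
        o[ch] = m > 0 ? m : 0.0f;
        a[ch] = w;
      }
    }
  }
}

// forward one image; fills the slot cache and writes the flat features
// into fCol (length d.flat)
void forwardImage(const float* img, const Params& p, const Dims& d,
                  SlotCache& C, Scratch& W, float* fCol) {
  im2col1(img, d, C.col1);
  W.z1t = p.W1t * C.col1.t();
  poolBiasRelu(W.z1t, d.c1, d.c1, p.b1, C.pool1t.memptr(), C.arg1.memptr(),
               32);
  const uword n = (uword)d.p1 * d.p1;
  W.z2t.zeros();
  for (int dc = 0; dc < 3; ++dc) {
    for (int dr = 0; dr < 3; ++dr) {
      const int o = dr + 3 * dc;
      const uword off = (uword)dr + (uword)dc * d.p1;
      const uword wdt = n - off;
      const fmat Pv(const_cast<float*>(C.pool1t.memptr()) + 32 * off, 32,
                    wdt, false, true);
      fmat Zv(W.z2t.memptr(), 64, wdt, false, true);
      Zv += p.W2.cols(o * 32, o * 32 + 31) * Pv;
    }
  }
  poolBiasRelu(W.z2t, d.p1, d.c2v, p.b2, fCol, C.arg2.memptr(), 64);
}

// backward one image given dL/dF (fCol holds the forward features for the
// ReLU mask); accumulates parameter gradients into g
void backwardImage(const float* dFcol, const float* fCol,
                   const SlotCache& C, const Params& p, const Dims& d,
                   Scratch& W, Grads& g) {
  const int p1 = d.p1, p2 = d.p2;
  const uword n = (uword)p1 * p1;
  W.dz2t.zeros();
  for (int c = 0; c < p2; ++c) {
    for (int r = 0; r < p2; ++r) {
      const uword q = (uword)(r + c * p2);
      const float* v = dFcol + q * 64;
      const float* fv = fCol + q * 64;
      const arma::u8* a = C.arg2.colptr(q);
      for (int ch = 0; ch < 64; ++ch) {
        if (fv[ch] > 0 && v[ch] != 0) {
          const int dr = a[ch] & 1, dc = a[ch] >> 1;
          const uword pix = (uword)(2 * r + dr) + (uword)(2 * c + dc) * p1;
          W.dz2t(ch, pix) = v[ch];
          g.b2(ch) += v[ch];
        }
      }
    }
  }
  W.dpool1t.zeros();
  for (int dc = 0; dc < 3; ++dc) {
    for (int dr = 0; dr < 3; ++dr) {
      const int o = dr + 3 * dc;
      const uword off = (uword)dr + (uword)dc * p1;
      const uword wdt = n - off;
      const fmat Pv(const_cast<float*>(C.pool1t.memptr()) + 32 * off, 32,
                    wdt, false, true);
      const fmat dZv(const_cast<float*>(W.dz2t.memptr()), 64, wdt, false,
                     true);
      g.W2.cols(o * 32, o * 32 + 31) += dZv * Pv.t();
      fmat dPv(W.dpool1t.memptr() + 32 * off, 32, wdt, false, true);
      dPv += p.W2.cols(o * 32, o * 32 + 31).t() * dZv;
    }
  }
  W.dz1t.zeros();
  const int half1 = p1;  // pool1 output grid = p1 x p1
  for (int c = 0; c < half1; ++c) {
    for (int r = 0; r < half1; ++r) {
      const uword q = (uword)(r + c * half1);
      const float* pv = C.pool1t.colptr(q);
      const float* dv = W.dpool1t.colptr(q);
      const arma::u8* a = C.arg1.colptr(q);
      for (int ch = 0; ch < 32; ++ch) {
        if (pv[ch] > 0 && dv[ch] != 0) {
          const int dr = a[ch] & 1, dc = a[ch] >> 1;
          const uword pix = (uword)(2 * r + dr) + (uword)(2 * c + dc) * d.c1;
          W.dz1t(ch, pix) = dv[ch];
          g.b1(ch) += dv[ch];
        }
      }
    }
  }
  g.W1t += W.dz1t * C.col1;
}

// contrastive loss and embedding gradients for one pair
// L = (1-y) * d^2/2 + y * max(0, m-d)^2 / 2, d the Euclidean distance
double pairLossGrad(const fvec& ea, const fvec& eb, int y, double m,
                    fvec& dea, fvec& deb) {
  fvec diff = ea - eb;
  double dist = std::sqrt(std::max(0.0, (double)arma::dot(diff, diff)));
  double loss;
  if (y == 0) {
    loss = 0.5 * dist * dist;
    dea = diff;
    deb = -diff;
  } else {
    double slack = m - dist;
    if (slack <= 0) {
      loss = 0.0;
      dea.zeros(ea.n_elem);
      deb.zeros(eb.n_elem);
    } else if (dist > 0) {
      loss = 0.5 * slack * slack;
      dea = (float)(-slack / dist) * diff;
      deb = -dea;
    } else {
      // d = 0 with y = 1: loss m^2/2; gradient undefined, take 0 subgradient
      loss = 0.5 * m * m;
      dea.zeros(ea.n_elem);
      deb.zeros(eb.n_elem);
    }
  }
  return loss;
}

struct Adam {
  fmat mW1, vW1, mW2, vW2, mW3, vW3;
  fvec mb1, vb1, mb2, vb2, mb3, vb3;
  long t = 0;
  float lr, beta1 = 0.9f, beta2 = 0.999f, eps = 1e-8f;
  explicit Adam(const Params& p, double rate) : lr((float)rate) {
    mW1.zeros(arma::size(p.W1t)); vW1.zeros(arma::size(p.W1t));
    mW2.zeros(arma::size(p.W2)); vW2.zeros(arma::size(p.W2));
    mW3.zeros(arma::size(p.W3)); vW3.zeros(arma::size(p.W3));
    mb1.zeros(arma::size(p.b1)); vb1.zeros(arma::size(p.b1));
    mb2.zeros(arma::size(p.b2)); vb2.zeros(arma::size(p.b2));
    mb3.zeros(arma::size(p.b3)); vb3.zeros(arma::size(p.b3));
  }
  template <class M>
  void stepOne(M& w, const M& g, M& m, M& v, float c1, float c2) {
    m = beta1 * m + (1 - beta1) * g;
    v = beta2 * v + (1 - beta2) * (g % g);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
  void step(Params& p, const Grads& g) {
    ++t;
    float c1 = 1 - std::pow(beta1, (float)t);
    float c2 = 1 - std::pow(beta2, (float)t);
    stepOne(p.W1t, g.W1t, mW1, vW1, c1, c2);
    stepOne(p.W2, g.W2, mW2, vW2, c1, c2);
    stepOne(p.W3, g.W3, mW3, vW3, c1, c2);
    stepOne(p.b1, g.b1, mb1, vb1, c1, c2);
    stepOne(p.b2, g.b2, mb2, vb2, c1, c2);
    stepOne(p.b3, g.b3, mb3, vb3, c1, c2);
  }
};

fmat imagesToF(const NumericMatrix& images) {
  const arma::mat tmp(const_cast<double*>(images.begin()), images.nrow(),
                      images.ncol(), false, true);
  return arma::conv_to<fmat>::from(tmp);
}

Dims checkedDims(int npix, const Params& p) {
  const int side = (int)std::lround(std::sqrt((double)npix));
  if (side * side != npix)
    stop("images must be square, stacked one per column");
  Dims d(side);
  if ((int)p.W3.n_rows != d.flat)
    stop("image size does not match the encoder architecture");
  return d;
}

}  // namespace

namespace {

// mean contrastive loss of a pair set under fixed weights (forward only)
double evalPairs(const fmat& X, const IntegerVector& ia,
                 const IntegerVector& ib, const IntegerVector& y,
                 const Params& p, const Dims& d, double margin,
                 SlotCache& C, Scratch& W) {
  const int n = ia.size();
  if (n == 0) return NA_REAL;
  // embed each distinct image once
  std::vector<int> imgs;
  std::vector<int> slotOf(X.n_cols, -1);
  for (int k = 0; k < n; ++k)
    for (int im : {ia[k] - 1, ib[k] - 1})
      if (slotOf[im] < 0) { slotOf[im] = (int)imgs.size(); imgs.push_back(im); }
  fmat F(d.flat, imgs.size());
  for (size_t s = 0; s < imgs.size(); ++s)
    forwardImage(X.colptr(imgs[s]), p, d, C, W, F.colptr(s));
  fmat e = p.W3.t() * F;
  e.each_col() += p.b3;
  e.transform([](float v) { return v > 0 ? v : 0.0f; });
  fvec dea, deb;
  double s = 0;
  for (int k = 0; k < n; ++k)
    s += pairLossGrad(e.col(slotOf[ia[k] - 1]), e.col(slotOf[ib[k] - 1]),
                      y[k], margin, dea, deb);
  return s / n;
}

}  // namespace

// [[Rcpp::export]]
List siamese_train_cpp(NumericMatrix images, IntegerVector ia,
                       IntegerVector ib, IntegerVector y, List weights,
                       double margin, double lr, int batchSize,
                       IntegerMatrix order, double tolImprove, int patience,
                       IntegerVector va, IntegerVector vb, IntegerVector vy) {
  Params p = asParams(weights);
  Dims d = checkedDims(images.nrow(), p);
  fmat X = imagesToF(images);
  const int nImg = X.n_cols;
  const int nPairs = ia.size();
  const int maxEpochs = order.ncol();
  const int maxSlots = std::min(2 * batchSize, nImg);
  std::vector<SlotCache> slots(maxSlots);
  for (auto& s : slots) s.alloc(d);
  Scratch W;
  W.alloc(d);
  fmat F(d.flat, maxSlots), dF;
  fmat z3, e, dz3;
  std::vector<int> slotOf(nImg, -1);
  std::vector<int> slotImg;
  slotImg.reserve(maxSlots);
  Adam opt(p, lr);
  Grads g;
  fvec dea, deb;
  std::vector<double> epochLoss, valLoss;
  const bool hasVal = va.size() > 0;
  Params bestP = p;
  int bestEpoch = 0;
  double best = std::numeric_limits<double>::infinity();
  int stall = 0;
  for (int ep = 0; ep < maxEpochs; ++ep) {
    double sumLoss = 0.0;
    for (int start = 0; start < nPairs; start += batchSize) {
      const int bEnd = std::min(start + batchSize, nPairs);
      const int bn = bEnd - start;
      const float wsc = 1.0f / bn;
      // assign batch-local slots to distinct images
      slotImg.clear();
      for (int k = start; k < bEnd; ++k) {
        const int pr = order(k, ep) - 1;
        for (int im : {ia[pr] - 1, ib[pr] - 1}) {
          if (slotOf[im] < 0) {
            slotOf[im] = (int)slotImg.size();
            slotImg.push_back(im);
          }
        }
      }
      const int nu = (int)slotImg.size();
      for (int s = 0; s < nu; ++s)
        forwardImage(X.colptr(slotImg[s]), p, d, slots[s], W, F.colptr(s));
      const fmat Fv(F.memptr(), d.flat, nu, false, true);
      z3 = p.W3.t() * Fv;
      z3.each_col() += p.b3;
      e = z3;
      e.transform([](float v) { return v > 0 ? v : 0.0f; });
      dz3.zeros(z3.n_rows, nu);
      for (int k = start; k < bEnd; ++k) {
        const int pr = order(k, ep) - 1;
        const int sa = slotOf[ia[pr] - 1], sb = slotOf[ib[pr] - 1];
        double L = pairLossGrad(e.col(sa), e.col(sb), y[pr], margin, dea,
                                deb);
        if (!std::isfinite(L))
          stop("non-finite contrastive loss at epoch %d", ep + 1);
        sumLoss += L;
        dz3.col(sa) += wsc * dea;
        dz3.col(sb) += wsc * deb;
      }
      dz3.elem(arma::find(z3 <= 0)).zeros();
      g.zeros(p);
      g.W3 += Fv * dz3.t();
      g.b3 += arma::sum(dz3, 1);
      dF = p.W3 * dz3;
      for (int s = 0; s < nu; ++s)
        backwardImage(dF.colptr(s), F.colptr(s), slots[s], p, d, W, g);
      opt.step(p, g);
      for (int im : slotImg) slotOf[im] = -1;
    }
    const double meanLoss = sumLoss / nPairs;
    epochLoss.push_back(meanLoss);
    // early stopping monitors held-out pair loss when a validation set is
    // given (with best-weight restore), otherwise the training loss
    double monitor = meanLoss;
    if (hasVal) {
      monitor = evalPairs(X, va, vb, vy, p, d, margin, slots[0], W);
      valLoss.push_back(monitor);
    }
    if (monitor < best - tolImprove) {
      best = monitor;
      stall = 0;
      if (hasVal) { bestP = p; bestEpoch = ep + 1; }
    } else if (++stall >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  if (hasVal && bestEpoch > 0) p = bestP;
  return List::create(Named("weights") = paramsToList(p),
                      Named("loss") = wrap(epochLoss),
                      Named("val_loss") = wrap(valLoss),
                      Named("best_epoch") = hasVal ? bestEpoch
                                                   : (int)epochLoss.size());
}

// [[Rcpp::export]]
NumericMatrix siamese_embed_cpp(NumericMatrix images, List weights) {
  Params p = asParams(weights);
  Dims d = checkedDims(images.nrow(), p);
  fmat X = imagesToF(images);
  const int n = X.n_cols;
  SlotCache C;
  C.alloc(d);
  Scratch W;
  W.alloc(d);
  fmat F(d.flat, n);
  for (int j = 0; j < n; ++j)
    forwardImage(X.colptr(j), p, d, C, W, F.colptr(j));
  fmat e = p.W3.t() * F;
  e.each_col() += p.b3;
  e.transform([](float v) { return v > 0 ? v : 0.0f; });
  NumericMatrix out(e.n_rows, n);
  for (int j = 0; j < n; ++j)
    for (uword i = 0; i < e.n_rows; ++i) out(i, j) = e(i, j);
  return out;
}

// [[Rcpp::export]]
List siamese_pair_grad_cpp(NumericMatrix imgA, NumericMatrix imgB,
                           List weights, double margin, int y) {
  Params p = asParams(weights);
  Dims d = checkedDims(imgA.nrow() * imgA.ncol(), p);
  arma::mat A(imgA.begin(), imgA.nrow(), imgA.ncol(), false);
  arma::mat B(imgB.begin(), imgB.nrow(), imgB.ncol(), false);
  fmat Xa = arma::conv_to<fmat>::from(arma::vectorise(A));
  fmat Xb = arma::conv_to<fmat>::from(arma::vectorise(B));
  SlotCache Ca, Cb;
  Ca.alloc(d); Cb.alloc(d);
  Scratch W;
  W.alloc(d);
  fmat F(d.flat, 2);
  forwardImage(Xa.memptr(), p, d, Ca, W, F.colptr(0));
  forwardImage(Xb.memptr(), p, d, Cb, W, F.colptr(1));
  fmat z3 = p.W3.t() * F;
  z3.each_col() += p.b3;
  fmat e = z3;
  e.transform([](float v) { return v > 0 ? v : 0.0f; });
  fvec dea, deb;
  double L = pairLossGrad(e.col(0), e.col(1), y, margin, dea, deb);
  fmat dz3(z3.n_rows, 2);
  dz3.col(0) = dea;
  dz3.col(1) = deb;
  dz3.elem(arma::find(z3 <= 0)).zeros();
  Grads g;
  g.zeros(p);
  g.W3 += F * dz3.t();
  g.b3 += arma::sum(dz3, 1);
  fmat dF = p.W3 * dz3;
  backwardImage(dF.colptr(0), F.colptr(0), Ca, p, d, W, g);
  backwardImage(dF.colptr(1), F.colptr(1), Cb, p, d, W, g);
  Params gp;
  gp.W1t = g.W1t; gp.b1 = g.b1; gp.W2 = g.W2; gp.b2 = g.b2;
  gp.W3 = g.W3; gp.b3 = g.b3;
  return List::create(Named("loss") = L, Named("grads") = paramsToList(gp));
}

// [[Rcpp::export]]
double siamese_pair_loss_cpp(NumericMatrix imgA, NumericMatrix imgB,
                             List weights, double margin, int y) {
  List r = siamese_pair_grad_cpp(imgA, imgB, weights, margin, y);
  return as<double>(r["loss"]);
}
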