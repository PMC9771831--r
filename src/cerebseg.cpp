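// Compiled core: small encoder-decoder reference network (forward/backward,
// AdamW), backward-warping resamplers, and brute-force boundary distances.
// Single precision throughout the network; the R side owns all containers.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::fcube;

// ---------------------------------------------------------------------------
// helpers: R array <-> float cube (H x W x C, column-major like R)
// ---------------------------------------------------------------------------

static fcube cube_from_R(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = (d.size() > 2) ? d[2] : 1;
  fcube out(H, W, C);
  const double* p = x.begin();
  for (arma::uword i = 0; i < out.n_elem; ++i) out(i) = (float)p[i];
  return out;
}

static NumericVector cube_to_R(const fcube& x) {
  NumericVector out(x.n_elem);
  for (arma::uword i = 0; i < x.n_elem; ++i) out[i] = x(i);
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

// ---------------------------------------------------------------------------
// conv building blocks (3x3 same-padding via im2col)
// ---------------------------------------------------------------------------

static void im2col3(const fcube& X, fmat& cols) {
  int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cols.zeros(C * 9, H * W);
  for (int c = 0; c < C; ++c) {
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        int r = c * 9 + (di + 1) * 3 + (dj + 1);
        int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
        if (i0 > i1 || j0 > j1) continue;
        fmat G(H, W, arma::fill::zeros);
        G.submat(i0, j0, i1, j1) =
          X.slice(c).submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
        cols.row(r) = arma::vectorise(G).t();
      }
    }
  }
}

static void col2im3(const fmat& dcols, fcube& dX) {
  int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  dX.zeros();
  for (int c = 0; c < C; ++c) {
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        int r = c * 9 + (di + 1) * 3 + (dj + 1);
        int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
        if (i0 > i1 || j0 > j1) continue;
        fmat G(dcols.row(r));
        G.reshape(H, W);
        dX.slice(c).submat(i0 + di, j0 + dj, i1 + di, j1 + dj) +=
          G.submat(i0, j0, i1, j1);
      }
    }
  }
}

struct ConvLayer {
  int in_ch, out_ch, ksize;     // ksize 3 or 1
  bool maxout;                  // local competition: conv 2*out_ch -> pairwise max
  fmat W;                       // (raw_out, in_ch*k*k)
  fvec b;
  fmat mW, vW; fvec mb, vb;     // AdamW moments
  // caches
  fmat cols;                    // im2col of input (k=3) or flattened input (k=1)
  fcube pre;                    // raw pre-activation (raw_out channels)
  arma::ucube win;              // maxout winner (0/1) per output channel

  int raw_out() const { return maxout ? 2 * out_ch : out_ch; }

  void init(std::mt19937& gen) {
    int fan_in = in_ch * ksize * ksize;
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / fan_in));
    W.set_size(raw_out(), fan_in);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = nd(gen);
    b.zeros(raw_out());
    mW.zeros(arma::size(W)); vW.zeros(arma::size(W));
    mb.zeros(raw_out()); vb.zeros(raw_out());
  }

  // forward with ReLU or maxout activation; 'linear' disables activation
  fcube forward(const fcube& X, bool linear, bool cache) {
    int H = X.n_rows, Wd = X.n_cols;
    fmat cm;
    if (ksize == 3) im2col3(X, cm);
    else {            // 1x1: rows are channels
      cm.set_size(X.n_slices, H * Wd);
      for (arma::uword c = 0; c < X.n_slices; ++c)
        cm.row(c) = arma::vectorise(X.slice(c)).t();
    }
    fmat Y = W * cm;
    Y.each_col() += b;
    fcube preact(H, Wd, raw_out());
    for (int c = 0; c < raw_out(); ++c) {
      fmat t(Y.row(c)); t.reshape(H, Wd);
      preact.slice(c) = t;
    }
    if (cache) { cols = cm; pre = preact; }
    if (linear) return preact;
    fcube out(H, Wd, out_ch);
    if (maxout) {
      if (cache) win.set_size(H, Wd, out_ch);
      for (int c = 0; c < out_ch; ++c) {
        const fmat& a = preact.slice(2 * c);
        const fmat& bm = preact.slice(2 * c + 1);
        out.slice(c) = arma::max(a, bm);
        if (cache) {
          arma::umat w(a.n_rows, a.n_cols);
          for (arma::uword i = 0; i < a.n_elem; ++i) w(i) = a(i) >= bm(i) ? 0 : 1;
          win.slice(c) = w;
        }
      }
    } else {
      for (int c = 0; c < out_ch; ++c)
        out.slice(c) = arma::clamp(preact.slice(c), 0.0f, arma::Datum<float>::inf);
    }
    return out;
  }

  // backward: dOut on activated output -> gradient wrt input; accumulates
  // dW/db into provided grads
  fcube backward(const fcube& dOut, bool linear, fmat& gW, fvec& gb,
                 int in_H, int in_W) {
    int H = dOut.n_rows, Wd = dOut.n_cols;
    fcube dPre(H, Wd, raw_out(), arma::fill::zeros);
    if (linear) {
      dPre = dOut;
    } else if (maxout) {
      for (int c = 0; c < out_ch; ++c) {
        for (arma::uword i = 0; i < dOut.slice(c).n_elem; ++i) {
          if (win.slice(c)(i) == 0) dPre.slice(2 * c)(i) = dOut.slice(c)(i);
          else dPre.slice(2 * c + 1)(i) = dOut.slice(c)(i);
        }
      }
    } else {
      for (int c = 0; c < out_ch; ++c)
        for (arma::uword i = 0; i < dOut.slice(c).n_elem; ++i)
          dPre.slice(c)(i) = pre.slice(c)(i) > 0 ? dOut.slice(c)(i) : 0.0f;
    }
    fmat dY(raw_out(), H * Wd);
    for (int c = 0; c < raw_out(); ++c)
      dY.row(c) = arma::vectorise(dPre.slice(c)).t();
    gW += dY * cols.t();
    gb += arma::sum(dY, 1);
    fmat dcols = W.t() * dY;
    fcube dX(in_H, in_W, in_ch);
    if (ksize == 3) col2im3(dcols, dX);
    else {
      for (int c = 0; c < in_ch; ++c) {
        fmat t(dcols.row(c)); t.reshape(in_H, in_W);
        dX.slice(c) = t;
      }
    }
    return dX;
  }
};

static fcube maxpool2(const fcube& X, arma::ucube& amax) {
  int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  fcube out(H, W, C);
  amax.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        float best = -1e30f; int bi = 0;
        for (int q = 0; q < 4; ++q) {
          int ii = 2 * i + q % 2, jj = 2 * j + q / 2;
          float v = X(ii, jj, c);
          if (v > best) { best = v; bi = q; }
        }
        out(i, j, c) = best; amax(i, j, c) = bi;
      }
  return out;
}

static fcube maxpool2_back(const fcube& dY, const arma::ucube& amax,
                           int H, int W) {
  int C = dY.n_slices;
  fcube dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < (int)dY.n_cols; ++j)
      for (int i = 0; i < (int)dY.n_rows; ++i) {
        int q = amax(i, j, c);
        dX(2 * i + q % 2, 2 * j + q / 2, c) += dY(i, j, c);
      }
  return dX;
}

static fcube upsample2(const fcube& X) {
  int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  fcube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        float v = X(i, j, c);
        out(2 * i, 2 * j, c) = v; out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v; out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

static fcube upsample2_back(const fcube& dY) {
  int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  fcube dX(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dX(i, j, c) = dY(2 * i, 2 * j, c) + dY(2 * i + 1, 2 * j, c) +
                      dY(2 * i, 2 * j + 1, c) + dY(2 * i + 1, 2 * j + 1, c);
  return dX;
}

// ---------------------------------------------------------------------------
// the network: U-Net with `levels` resolutions, two convs per level,
// nearest-neighbor unpooling + skip concatenation, 1x1 softmax head
// ---------------------------------------------------------------------------

struct Net {
  int in_channels, n_classes, levels, filters;
  bool competition;
  long step_count = 0;
  std::vector<ConvLayer> layers;   // enc pairs, bottleneck pair, dec pairs, head
  // per-forward caches
  std::vector<fcube> enc_out;               // skip sources
  std::vector<arma::ucube> pool_amax;
  std::vector<std::pair<int,int> > shapes;  // input shapes per conv layer
  fcube probs;

  int ch_at(int level) const { return filters << level; }

  void build(int seed) {
    std::mt19937 gen(seed);
    layers.clear();
    int in_ch = in_channels;
    for (int l = 0; l < levels - 1; ++l) {       // encoders
      add_conv(in_ch, ch_at(l), 3, gen);
      add_conv(ch_at(l), ch_at(l), 3, gen);
      in_ch = ch_at(l);
    }
    add_conv(in_ch, ch_at(levels - 1), 3, gen);  // bottleneck
    add_conv(ch_at(levels - 1), ch_at(levels - 1), 3, gen);
    for (int l = levels - 2; l >= 0; --l) {      // decoders
      add_conv(ch_at(l + 1) + ch_at(l), ch_at(l), 3, gen);
      add_conv(ch_at(l), ch_at(l), 3, gen);
    }
    ConvLayer head;
    head.in_ch = (levels > 1) ? ch_at(0) : ch_at(0);
    head.out_ch = n_classes; head.ksize = 1; head.maxout = false;
    head.init(gen);
    layers.push_back(head);
  }

  void add_conv(int ic, int oc, int k, std::mt19937& gen) {
    ConvLayer c;
    c.in_ch = ic; c.out_ch = oc; c.ksize = k; c.maxout = competition;
    c.init(gen);
    layers.push_back(c);
  }

  fcube forward(const fcube& X, bool cache) {
    enc_out.assign(levels - 1, fcube());
    pool_amax.assign(levels - 1, arma::ucube());
    shapes.assign(layers.size(), std::make_pair(0, 0));
    fcube cur = X;
    int li = 0;
    for (int l = 0; l < levels - 1; ++l) {
      shapes[li] = {(int)cur.n_rows, (int)cur.n_cols};
      cur = layers[li++].forward(cur, false, cache);
      shapes[li] = {(int)cur.n_rows, (int)cur.n_cols};
      cur = layers[li++].forward(cur, false, cache);
      enc_out[l] = cur;
      arma::ucube am;
      cur = maxpool2(cur, am);
      if (cache) pool_amax[l] = am;
    }
    shapes[li] = {(int)cur.n_rows, (int)cur.n_cols};
    cur = layers[li++].forward(cur, false, cache);
    shapes[li] = {(int)cur.n_rows, (int)cur.n_cols};
    cur = layers[li++].forward(cur, false, cache);
    for (int l = levels - 2; l >= 0; --l) {
      cur = upsample2(cur);
      fcube cat(cur.n_rows, cur.n_cols, cur.n_slices + enc_out[l].n_slices);
      for (arma::uword c = 0; c < cur.n_slices; ++c) cat.slice(c) = cur.slice(c);
      for (arma::uword c = 0; c < enc_out[l].n_slices; ++c)
        cat.slice(cur.n_slices + c) = enc_out[l].slice(c);
      shapes[li] = {(int)cat.n_rows, (int)cat.n_cols};
      cur = layers[li++].forward(cat, false, cache);
      shapes[li] = {(int)cur.n_rows, (int)cur.n_cols};
      cur = layers[li++].forward(cur, false, cache);
    }
    shapes[li] = {(int)cur.n_rows, (int)cur.n_cols};
    fcube logits = layers[li].forward(cur, true, cache);
    // softmax over channels
    fcube P(logits.n_rows, logits.n_cols, logits.n_slices);
    for (arma::uword j = 0; j < logits.n_cols; ++j)
      for (arma::uword i = 0; i < logits.n_rows; ++i) {
        float mx = -1e30f;
        for (arma::uword c = 0; c < logits.n_slices; ++c)
          mx = std::max(mx, logits(i, j, c));
        float s = 0;
        for (arma::uword c = 0; c < logits.n_slices; ++c) {
          float e = std::exp(logits(i, j, c) - mx);
          P(i, j, c) = e; s += e;
        }
        for (arma::uword c = 0; c < logits.n_slices; ++c) P(i, j, c) /= s;
      }
    if (cache) probs = P;
    return P;
  }

  // backward from dLogits; accumulate grads
  void backward(const fcube& dLogits, std::vector<fmat>& gW,
                std::vector<fvec>& gb) {
    int li = layers.size() - 1;
    fcube d = layers[li].backward(dLogits, true, gW[li], gb[li],
                                  shapes[li].first, shapes[li].second);
    --li;
    for (int l = 0; l < levels - 1; ++l) {   // decoders in reverse build order
      d = layers[li].backward(d, false, gW[li], gb[li],
                              shapes[li].first, shapes[li].second);
      --li;
      fcube dcat = layers[li].backward(d, false, gW[li], gb[li],
                                       shapes[li].first, shapes[li].second);
      --li;
      // split concat: first part upsampled deep path, second part skip
      int enc_level = l;                     // decoder l corresponds to enc level l
      int skip_ch = ch_at(enc_level);
      int deep_ch = dcat.n_slices - skip_ch;
      fcube ddeep(dcat.n_rows, dcat.n_cols, deep_ch);
      for (int c = 0; c < deep_ch; ++c) ddeep.slice(c) = dcat.slice(c);
      fcube dskip(dcat.n_rows, dcat.n_cols, skip_ch);
      for (int c = 0; c < skip_ch; ++c) dskip.slice(c) = dcat.slice(deep_ch + c);
      d = upsample2_back(ddeep);
      skip_grads[enc_level] = dskip;
    }
    // bottleneck
    d = layers[li].backward(d, false, gW[li], gb[li],
                            shapes[li].first, shapes[li].second);
    --li;
    d = layers[li].backward(d, false, gW[li], gb[li],
                            shapes[li].first, shapes[li].second);
    --li;
    for (int l = levels - 2; l >= 0; --l) {  // encoders in reverse
      fcube dup = maxpool2_back(d, pool_amax[l],
                                enc_out[l].n_rows, enc_out[l].n_cols);
      dup += skip_grads[l];
      d = layers[li].backward(dup, false, gW[li], gb[li],
                              shapes[li].first, shapes[li].second);
      --li;
      d = layers[li].backward(d, false, gW[li], gb[li],
                              shapes[li].first, shapes[li].second);
      --li;
    }
  }

  std::vector<fcube> skip_grads;

  void adamw_step(std::vector<fmat>& gW, std::vector<fvec>& gb,
                  float lr, float wd, int batch) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    ++step_count;
    float bc1 = 1.0f - std::pow(b1, (float)step_count);
    float bc2 = 1.0f - std::pow(b2, (float)step_count);
    for (size_t k = 0; k < layers.size(); ++k) {
      fmat g = gW[k] / (float)batch;
      fvec gbv = gb[k] / (float)batch;
      ConvLayer& L = layers[k];
      L.mW = b1 * L.mW + (1 - b1) * g;
      L.vW = b2 * L.vW + (1 - b2) * arma::square(g);
      L.W -= lr * (L.mW / bc1) / (arma::sqrt(L.vW / bc2) + eps) + lr * wd * L.W;
      L.mb = b1 * L.mb + (1 - b1) * gbv;
      L.vb = b2 * L.vb + (1 - b2) * arma::square(gbv);
      L.b -= lr * (L.mb / bc1) / (arma::sqrt(L.vb / bc2) + eps);
    }
  }
};

// composite loss on one slice: weighted cross-entropy + soft-Dice over the
// classes present in the target; returns loss, fills dLogits
static double slice_loss_grad(const fcube& P, const IntegerVector& target,
                              const fvec& w, float dice_weight, float smooth,
                              fcube& dLogits) {
  int H = P.n_rows, Wd = P.n_cols, C = P.n_slices;
  int N = H * Wd;
  // cross-entropy part
  double ce = 0.0;
  fcube dP(H, Wd, C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    int t = target[n];
    float p = std::max(P(n % H, n / H, t), 1e-12f);
    ce += w(t) * (-std::log((double)p));
  }
  ce /= N;
  // soft-Dice over classes present in target
  std::vector<double> A(C, 0.0), B(C, 0.0);
  std::vector<bool> present(C, false);
  for (int n = 0; n < N; ++n) present[target[n]] = true;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      float p = P(n % H, n / H, c);
      B[c] += p;
      if (target[n] == c) { A[c] += p; B[c] += 1.0; }
    }
  }
  int npres = 0; double dsum = 0.0;
  for (int c = 0; c < C; ++c)
    if (present[c]) { ++npres; dsum += (2.0 * A[c] + smooth) / (B[c] + smooth); }
  double dice_loss = 1.0 - dsum / std::max(npres, 1);
  // gradient wrt probabilities
  for (int n = 0; n < N; ++n) {
    int i = n % H, j = n / H, t = target[n];
    for (int c = 0; c < C; ++c) {
      double g = 0.0;
      if (present[c]) {
        double y = (c == t) ? 1.0 : 0.0;
        double denom = B[c] + smooth;
        g += -dice_weight / npres * (2.0 * y * denom - (2.0 * A[c] + smooth)) /
             (denom * denom);
      }
      dP(i, j, c) = (float)g;
    }
  }
  // chain through softmax; add CE-on-logits gradient directly
  dLogits.set_size(H, Wd, C);
  for (int n = 0; n < N; ++n) {
    int i = n % H, j = n / H, t = target[n];
    double dot = 0.0;
    for (int c = 0; c < C; ++c) dot += dP(i, j, c) * P(i, j, c);
    for (int c = 0; c < C; ++c) {
      double soft = P(i, j, c) * (dP(i, j, c) - dot);
      double ceg = w(t) * (P(i, j, c) - (c == t ? 1.0 : 0.0)) / N;
      dLogits(i, j, c) = (float)(soft + ceg);
    }
  }
  return ce + dice_weight * dice_loss;
}

// [[Rcpp::export]]
SEXP cnet_create(int in_channels, int n_classes, int levels, int filters,
                 bool competition, int seed) {
  if (levels < 1 || filters < 1 || n_classes < 2 || in_channels < 1)
    stop("invalid model configuration");
  Net* net = new Net();
  net->in_channels = in_channels; net->n_classes = n_classes;
  net->levels = levels; net->filters = filters;
  net->competition = competition;
  net->build(seed);
  XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector cnet_forward(SEXP net_ptr, NumericVector input) {
  XPtr<Net> net(net_ptr);
  fcube X = cube_from_R(input);
  if ((int)X.n_slices != net->in_channels) stop("channel-count mismatch");
  int div = 1 << (net->levels - 1);
  if (X.n_rows % div != 0 || X.n_cols % div != 0)
    stop("slice size must be divisible by 2^(levels-1)");
  fcube P = net->forward(X, false);
  return cube_to_R(P);
}

// [[Rcpp::export]]
double cnet_train_batch(SEXP net_ptr, List inputs, List targets,
                        NumericVector class_weights, double lr,
                        double weight_decay, double dice_weight,
                        double dice_smooth, double max_grad_norm) {
  XPtr<Net> net(net_ptr);
  int B = inputs.size();
  if (B == 0 || targets.size() != B) stop("empty or mismatched batch");
  fvec w(class_weights.size());
  for (int i = 0; i < (int)w.n_elem; ++i) w(i) = class_weights[i];
  if ((int)w.n_elem != net->n_classes) stop("class-weight length mismatch");
  std::vector<fmat> gW(net->layers.size());
  std::vector<fvec> gb(net->layers.size());
  for (size_t k = 0; k < net->layers.size(); ++k) {
    gW[k].zeros(arma::size(net->layers[k].W));
    gb[k].zeros(net->layers[k].raw_out());
  }
  net->skip_grads.assign(net->levels - 1, fcube());
  double loss = 0.0;
  for (int s = 0; s < B; ++s) {
    fcube X = cube_from_R(inputs[s]);
    IntegerVector t = targets[s];
    fcube P = net->forward(X, true);
    fcube dLogits;
    loss += slice_loss_grad(P, t, w, (float)dice_weight, (float)dice_smooth,
                            dLogits);
    net->backward(dLogits, gW, gb);
  }
  // global gradient-norm clipping stabilizes small-batch training
  if (max_grad_norm > 0) {
    double sq = 0.0;
    for (size_t k = 0; k < gW.size(); ++k) {
      sq += arma::accu(arma::square(gW[k] / (float)B));
      sq += arma::accu(arma::square(gb[k] / (float)B));
    }
    double nrm = std::sqrt(sq);
    if (nrm > max_grad_norm) {
      float sc = (float)(max_grad_norm / nrm);
      for (size_t k = 0; k < gW.size(); ++k) { gW[k] *= sc; gb[k] *= sc; }
    }
  }
  net->adamw_step(gW, gb, (float)lr, (float)weight_decay, B);
  return loss / B;
}

// [[Rcpp::export]]
List cnet_get_weights(SEXP net_ptr) {
  XPtr<Net> net(net_ptr);
  List out(net->layers.size());
  for (size_t k = 0; k < net->layers.size(); ++k) {
    const ConvLayer& L = net->layers[k];
    NumericMatrix Wm(L.W.n_rows, L.W.n_cols);
    for (arma::uword i = 0; i < L.W.n_elem; ++i) Wm[i] = L.W(i);
    NumericVector bv(L.b.n_elem);
    for (arma::uword i = 0; i < L.b.n_elem; ++i) bv[i] = L.b(i);
    out[k] = List::create(_["W"] = Wm, _["b"] = bv);
  }
  return out;
}

// [[Rcpp::export]]
void cnet_set_weights(SEXP net_ptr, List weights) {
  XPtr<Net> net(net_ptr);
  if ((size_t)weights.size() != net->layers.size())
    stop("layer-count mismatch");
  for (size_t k = 0; k < net->layers.size(); ++k) {
    List lw = weights[k];
    NumericMatrix Wm = lw["W"];
    NumericVector bv = lw["b"];
    ConvLayer& L = net->layers[k];
    if ((int)L.W.n_rows != Wm.nrow() || (int)L.W.n_cols != Wm.ncol())
      stop("weight-shape mismatch at layer ", k + 1);
    for (arma::uword i = 0; i < L.W.n_elem; ++i) L.W(i) = (float)Wm[i];
    for (arma::uword i = 0; i < L.b.n_elem; ++i) L.b(i) = (float)bv[i];
  }
}

// [[Rcpp::export]]
List cnet_config(SEXP net_ptr) {
  XPtr<Net> net(net_ptr);
  return List::create(_["in_channels"] = net->in_channels,
                      _["n_classes"] = net->n_classes,
                      _["levels"] = net->levels,
                      _["filters"] = net->filters,
                      _["competition"] = net->competition);
}

// ---------------------------------------------------------------------------
// resamplers (backward warping)
// ---------------------------------------------------------------------------

// 2D in-slice warp: M maps output pixel (i, j, 1) [0-based] to source pixel.
// Image bilinear, labels nearest-neighbor, out-of-field -> background.
// [[Rcpp::export]]
List warp_slice_cpp(NumericMatrix image, IntegerMatrix labels,
                    NumericMatrix M) {
  int H = image.nrow(), W = image.ncol();
  NumericMatrix oimg(H, W);
  IntegerMatrix olab(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double si = M(0, 0) * i + M(0, 1) * j + M(0, 2);
      double sj = M(1, 0) * i + M(1, 1) * j + M(1, 2);
      // bilinear
      int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
      double fi = si - i0, fj = sj - j0;
      double v = 0.0;
      for (int q = 0; q < 4; ++q) {
        int ii = i0 + q % 2, jj = j0 + q / 2;
        double wgt = (q % 2 ? fi : 1 - fi) * (q / 2 ? fj : 1 - fj);
        if (ii >= 0 && ii < H && jj >= 0 && jj < W) v += wgt * image(ii, jj);
      }
      oimg(i, j) = v;
      int ni = (int)std::lround(si), nj = (int)std::lround(sj);
      olab(i, j) = (ni >= 0 && ni < H && nj >= 0 && nj < W) ? labels(ni, nj) : 0;
    }
  }
  return List::create(_["image"] = oimg, _["labels"] = olab);
}

// 3D displacement warp; field in voxel units, shape (X, Y, Z, 3)
// [[Rcpp::export]]
List warp_volume_cpp(NumericVector volume, IntegerVector labels,
                     NumericVector field) {
  IntegerVector d = volume.attr("dim");
  int X = d[0], Y = d[1], Z = d[2];
  long n = (long)X * Y * Z;
  NumericVector ovol(n); ovol.attr("dim") = d;
  IntegerVector olab(n); olab.attr("dim") = d;
  const double* V = volume.begin();
  const int* L = labels.begin();
  const double* F = field.begin();
  long stride = n;
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        long idx = i + (long)X * (j + (long)Y * k);
        double si = i + F[idx], sj = j + F[idx + stride],
               sk = k + F[idx + 2 * stride];
        int i0 = (int)std::floor(si), j0 = (int)std::floor(sj),
            k0 = (int)std::floor(sk);
        double fi = si - i0, fj = sj - j0, fk = sk - k0;
        double v = 0.0;
        for (int q = 0; q < 8; ++q) {
          int ii = i0 + q % 2, jj = j0 + (q / 2) % 2, kk = k0 + q / 4;
          double wgt = (q % 2 ? fi : 1 - fi) * ((q / 2) % 2 ? fj : 1 - fj) *
                       (q / 4 ? fk : 1 - fk);
          if (ii >= 0 && ii < X && jj >= 0 && jj < Y && kk >= 0 && kk < Z)
            v += wgt * V[ii + (long)X * (jj + (long)Y * kk)];
        }
        ovol[idx] = v;
        int ni = (int)std::lround(si), nj = (int)std::lround(sj),
            nk = (int)std::lround(sk);
        olab[idx] = (ni >= 0 && ni < X && nj >= 0 && nj < Y && nk >= 0 && nk < Z)
                    ? L[ni + (long)X * (nj + (long)Y * nk)] : 0;
      }
  return List::create(_["volume"] = ovol, _["labels"] = olab);
}

// ---------------------------------------------------------------------------
// geometry kernels
// ---------------------------------------------------------------------------

// for each row of A (n x 3, mm), the minimum Euclidean distance to rows of B
// [[Rcpp::export]]
NumericVector directed_min_dists_cpp(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double a0 = A(i, 0), a1 = A(i, 1), a2 = A(i, 2);
    for (int j = 0; j < m; ++j) {
      double d0 = a0 - B(j, 0), d1 = a1 - B(j, 1), d2 = a2 - B(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// nearest-gray-voxel label for each query point; ties (within 1e-9 mm)
// broken toward the lowest label id
// [[Rcpp::export]]
IntegerVector nearest_label_cpp(NumericMatrix query, NumericMatrix gray,
                                IntegerVector gray_labels) {
  int n = query.nrow(), m = gray.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int lab = 0;
    for (int j = 0; j < m; ++j) {
      double d0 = query(i, 0) - gray(j, 0), d1 = query(i, 1) - gray(j, 1),
             d2 = query(i, 2) - gray(j, 2);
      double d = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
      if (d < best - 1e-9 || (std::abs(d - best) <= 1e-9 && gray_labels[j] < lab)) {
        best = d; lab = gray_labels[j];
      }
    }
    out[i] = lab;
  }
  return out;
}
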