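// Minimal float32 feed-forward / convolutional regression engine.
//
// Layout conventions:
//  * dense activations: fmat (features x batch)
//  * conv feature maps:  fmat (channels x (H*W*batch)), spatial index
//    s = x*H + y (column-major within an image), image blocks contiguous.
//  * conv weights: fmat (out_ch x in_ch*9) for 3x3 kernels, offset index
//    o = (dx+1)*3 + (dy+1), row block o*C + c.
// All computation is single-threaded and deterministic for a fixed seed.

#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

enum LayerType { DENSE, CONV, RELU, DROPOUT, MAXPOOL2, GAVGPOOL, SAVE, ADDFROM };

struct Layer {
  LayerType type;
  int in = 0, out = 0;    // dense/conv sizes (conv: channels)
  double rate = 0.0;      // dropout
  int slot = 0;           // save/addfrom
  int H = 0, W = 0;       // spatial dims at layer INPUT (conv stages)
};

struct Net {
  std::vector<Layer> layers;
  std::vector<fmat> Wt;   // weights per layer (empty if none)
  std::vector<fvec> b;
  int in_dim = 0;
  int img_h = 0, img_w = 0;   // >0 if input is a 1-channel image stack
};

static std::vector<Layer> parse_layers(const List& spec, int img_h, int img_w) {
  std::vector<Layer> L;
  int H = img_h, W = img_w;
  for (int i = 0; i < spec.size(); ++i) {
    List ls = spec[i];
    std::string t = as<std::string>(ls["type"]);
    Layer ly;
    ly.H = H; ly.W = W;
    if (t == "dense")        { ly.type = DENSE; ly.in = as<int>(ls["n_in"]); ly.out = as<int>(ls["n_out"]); }
    else if (t == "conv")    { ly.type = CONV; ly.in = as<int>(ls["n_in"]); ly.out = as<int>(ls["n_out"]); }
    else if (t == "relu")    { ly.type = RELU; }
    else if (t == "dropout") { ly.type = DROPOUT; ly.rate = as<double>(ls["rate"]); }
    else if (t == "maxpool2"){ ly.type = MAXPOOL2; H /= 2; W /= 2; }
    else if (t == "gavgpool"){ ly.type = GAVGPOOL; H = 0; W = 0; }
    else if (t == "save")    { ly.type = SAVE; ly.slot = as<int>(ls["slot"]); }
    else if (t == "addfrom") { ly.type = ADDFROM; ly.slot = as<int>(ls["slot"]); }
    else stop("unknown layer type: " + t);
    L.push_back(ly);
  }
  return L;
}

// Kaiming-uniform initialisation with the bound 1/sqrt(fan_in) used by the
// reference deep-learning framework's linear/conv layers; the small scale
// keeps the first full-batch Adam steps (effectively sign steps) from
// swinging a ReLU-capped head into the dead zone. The output bias starts at
// the training-target mean.
static void init_params(Net& net, std::mt19937& rng, float head_bias) {
  std::uniform_real_distribution<float> unif(-1.0f, 1.0f);
  size_t n = net.layers.size();
  net.Wt.assign(n, fmat());
  net.b.assign(n, fvec());
  for (size_t i = 0; i < n; ++i) {
    Layer& ly = net.layers[i];
    if (ly.type == DENSE || ly.type == CONV) {
      int fan_in = (ly.type == DENSE) ? ly.in : ly.in * 9;
      float bound = 1.0f / std::sqrt((float)fan_in);
      net.Wt[i].set_size(ly.out, fan_in);
      for (arma::uword k = 0; k < net.Wt[i].n_elem; ++k)
        net.Wt[i](k) = bound * unif(rng);
      net.b[i].set_size(ly.out);
      for (arma::uword k = 0; k < (arma::uword)ly.out; ++k)
        net.b[i](k) = bound * unif(rng);
      if (ly.type == DENSE && ly.out == 1) net.b[i].fill(head_bias);
    }
  }
}

// im2col for 3x3 same-padding kernels. F: C x (H*W*n) -> P: 9C x (H*W*n)
static void im2col3(const fmat& F, fmat& P, int C, int H, int W, int n) {
  P.zeros(9 * C, (arma::uword)H * W * n);
  for (int o = 0; o < 9; ++o) {
    int dy = o % 3 - 1, dx = o / 3 - 1;
    int y0 = std::max(0, -dy), y1 = H - 1 - std::max(0, dy);
    if (y1 < y0) continue;
    for (int i = 0; i < n; ++i) {
      arma::uword base = (arma::uword)i * H * W;
      for (int x = 0; x < W; ++x) {
        int xs = x + dx;
        if (xs < 0 || xs >= W) continue;
        arma::uword d0 = base + (arma::uword)x * H + y0;
        arma::uword s0 = base + (arma::uword)xs * H + y0 + dy;
        P.submat(o * C, d0, o * C + C - 1, d0 + (y1 - y0)) =
          F.cols(s0, s0 + (y1 - y0));
      }
    }
  }
}

// transpose of im2col: accumulate dP back into dF
static void col2im3(const fmat& dP, fmat& dF, int C, int H, int W, int n) {
  dF.zeros(C, (arma::uword)H * W * n);
  for (int o = 0; o < 9; ++o) {
    int dy = o % 3 - 1, dx = o / 3 - 1;
    int y0 = std::max(0, -dy), y1 = H - 1 - std::max(0, dy);
    if (y1 < y0) continue;
    for (int i = 0; i < n; ++i) {
      arma::uword base = (arma::uword)i * H * W;
      for (int x = 0; x < W; ++x) {
        int xs = x + dx;
        if (xs < 0 || xs >= W) continue;
        arma::uword d0 = base + (arma::uword)x * H + y0;
        arma::uword s0 = base + (arma::uword)xs * H + y0 + dy;
        dF.cols(s0, s0 + (y1 - y0)) +=
          dP.submat(o * C, d0, o * C + C - 1, d0 + (y1 - y0));
      }
    }
  }
}

struct Tape {
  std::vector<fmat> act;        // output of each layer
  std::vector<fmat> patches;    // im2col per conv layer
  std::vector<arma::umat> amax; // argmax (0..3) per maxpool
  std::vector<fmat> dmask;      // dropout masks
  std::map<int, fmat> slots;    // saved activations for skips
};

// forward pass over one chunk; X is in input layout (in_dim x n or 1 x HWn)
static fmat forward(const Net& net, const fmat& X, int n, bool train,
                    std::mt19937* rng, Tape* tape) {
  fmat cur = X;
  size_t nl = net.layers.size();
  if (tape) {
    tape->act.assign(nl, fmat());
    tape->patches.assign(nl, fmat());
    tape->amax.assign(nl, arma::umat());
    tape->dmask.assign(nl, fmat());
  }
  for (size_t i = 0; i < nl; ++i) {
    const Layer& ly = net.layers[i];
    switch (ly.type) {
    case DENSE: {
      fmat out = net.Wt[i] * cur;
      out.each_col() += net.b[i];
      cur = std::move(out);
      break;
    }
    case CONV: {
      fmat P;
      im2col3(cur, P, ly.in, ly.H, ly.W, n);
      fmat out = net.Wt[i] * P;
      out.each_col() += net.b[i];
      if (tape) tape->patches[i] = std::move(P);
      cur = std::move(out);
      break;
    }
    case RELU:
      cur.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      break;
    case DROPOUT:
      if (train && ly.rate > 0) {
        std::uniform_real_distribution<float> unif(0.0f, 1.0f);
        fmat mask(cur.n_rows, cur.n_cols);
        float keep = 1.0f - (float)ly.rate;
        for (arma::uword k = 0; k < mask.n_elem; ++k)
          mask(k) = (unif(*rng) < keep) ? 1.0f / keep : 0.0f;
        cur %= mask;
        if (tape) tape->dmask[i] = std::move(mask);
      }
      break;
    case MAXPOOL2: {
      int H = ly.H, W = ly.W, H2 = H / 2, W2 = W / 2;
      int C = cur.n_rows;
      fmat out(C, (arma::uword)H2 * W2 * n);
      arma::umat am(C, (arma::uword)H2 * W2 * n);
      for (int im = 0; im < n; ++im) {
        arma::uword bi = (arma::uword)im * H * W, bo = (arma::uword)im * H2 * W2;
        for (int x = 0; x < W2; ++x) for (int y = 0; y < H2; ++y) {
          arma::uword oc = bo + (arma::uword)x * H2 + y;
          arma::uword c00 = bi + (arma::uword)(2 * x) * H + 2 * y;
          arma::uword cand[4] = {c00, c00 + 1, c00 + H, c00 + H + 1};
          for (int c = 0; c < C; ++c) {
            float best = cur(c, cand[0]); int bk = 0;
            for (int k = 1; k < 4; ++k) {
              float v = cur(c, cand[k]);
              if (v > best) { best = v; bk = k; }
            }
            out(c, oc) = best; am(c, oc) = bk;
          }
        }
      }
      if (tape) tape->amax[i] = std::move(am);
      cur = std::move(out);
      break;
    }
    case GAVGPOOL: {
      int HW = ly.H * ly.W, C = cur.n_rows;
      fmat out(C, n);
      for (int im = 0; im < n; ++im)
        out.col(im) = arma::mean(cur.cols((arma::uword)im * HW, (arma::uword)(im + 1) * HW - 1), 1);
      cur = std::move(out);
      break;
    }
    case SAVE:
      if (tape) tape->slots[ly.slot] = cur;
      else if (true) { /* eval also needs slots */ }
      break;
    case ADDFROM:
      if (tape) cur += tape->slots[ly.slot];
      break;
    }
    // eval-mode skip bookkeeping without a tape
    if (!tape && ly.type == SAVE) { /* handled below */ }
    if (tape) tape->act[i] = cur;
  }
  return cur;
}

// eval forward with skip support but no stored tape (memory-light)
static fmat forward_eval(const Net& net, const fmat& X, int n) {
  fmat cur = X;
  std::map<int, fmat> slots;
  for (size_t i = 0; i < net.layers.size(); ++i) {
    const Layer& ly = net.layers[i];
    switch (ly.type) {
    case DENSE: { fmat out = net.Wt[i] * cur; out.each_col() += net.b[i]; cur = std::move(out); break; }
    case CONV: { fmat P; im2col3(cur, P, ly.in, ly.H, ly.W, n); fmat out = net.Wt[i] * P; out.each_col() += net.b[i]; cur = std::move(out); break; }
    case RELU: cur.transform([](float v) { return v > 0.0f ? v : 0.0f; }); break;
    case DROPOUT: break;
    case MAXPOOL2: {
      int H = ly.H, W = ly.W, H2 = H / 2, W2 = W / 2, C = cur.n_rows;
      fmat out(C, (arma::uword)H2 * W2 * n);
      for (int im = 0; im < n; ++im) {
        arma::uword bi = (arma::uword)im * H * W, bo = (arma::uword)im * H2 * W2;
        for (int x = 0; x < W2; ++x) for (int y = 0; y < H2; ++y) {
          arma::uword oc = bo + (arma::uword)x * H2 + y;
          arma::uword c00 = bi + (arma::uword)(2 * x) * H + 2 * y;
          arma::uword cand[4] = {c00, c00 + 1, c00 + H, c00 + H + 1};
          for (int c = 0; c < C; ++c)
            out(c, oc) = std::max(std::max(cur(c, cand[0]), cur(c, cand[1])),
                                  std::max(cur(c, cand[2]), cur(c, cand[3])));
        }
      }
      cur = std::move(out);
      break;
    }
    case GAVGPOOL: {
      int HW = ly.H * ly.W, C = cur.n_rows;
      fmat out(C, n);
      for (int im = 0; im < n; ++im)
        out.col(im) = arma::mean(cur.cols((arma::uword)im * HW, (arma::uword)(im + 1) * HW - 1), 1);
      cur = std::move(out);
      break;
    }
    case SAVE: slots[ly.slot] = cur; break;
    case ADDFROM: cur += slots[ly.slot]; break;
    }
  }
  return cur;
}

// backward pass; dOut is gradient wrt final output; accumulates into gW/gb
static void backward(const Net& net, const fmat& X, int n, const Tape& tape,
                     fmat dOut, std::vector<fmat>& gW, std::vector<fvec>& gb) {
  size_t nl = net.layers.size();
  std::map<int, fmat> slot_grad;
  fmat d = std::move(dOut);
  for (int i = (int)nl - 1; i >= 0; --i) {
    const Layer& ly = net.layers[i];
    const fmat& input = (i == 0) ? X : tape.act[i - 1];
    switch (ly.type) {
    case DENSE:
      gW[i] += d * input.t();
      gb[i] += arma::sum(d, 1);
      d = net.Wt[i].t() * d;
      break;
    case CONV: {
      gW[i] += d * tape.patches[i].t();
      gb[i] += arma::sum(d, 1);
      fmat dP = net.Wt[i].t() * d;
      fmat dF;
      col2im3(dP, dF, ly.in, ly.H, ly.W, n);
      d = std::move(dF);
      break;
    }
    case RELU: {
      const fmat& out = tape.act[i];
      for (arma::uword k = 0; k < d.n_elem; ++k)
        if (out(k) <= 0.0f) d(k) = 0.0f;
      break;
    }
    case DROPOUT:
      if (!tape.dmask[i].is_empty()) d %= tape.dmask[i];
      break;
    case MAXPOOL2: {
      int H = ly.H, W = ly.W, H2 = H / 2, W2 = W / 2, C = d.n_rows;
      const arma::umat& am = tape.amax[i];
      fmat dIn(C, (arma::uword)H * W * n, arma::fill::zeros);
      for (int im = 0; im < n; ++im) {
        arma::uword bi = (arma::uword)im * H * W, bo = (arma::uword)im * H2 * W2;
        for (int x = 0; x < W2; ++x) for (int y = 0; y < H2; ++y) {
          arma::uword oc = bo + (arma::uword)x * H2 + y;
          arma::uword c00 = bi + (arma::uword)(2 * x) * H + 2 * y;
          arma::uword cand[4] = {c00, c00 + 1, c00 + H, c00 + H + 1};
          for (int c = 0; c < C; ++c)
            dIn(c, cand[am(c, oc)]) += d(c, oc);
        }
      }
      d = std::move(dIn);
      break;
    }
    case GAVGPOOL: {
      int HW = ly.H * ly.W, C = d.n_rows;
      fmat dIn(C, (arma::uword)HW * n);
      for (int im = 0; im < n; ++im) {
        fvec g = d.col(im) / (float)HW;
        dIn.cols((arma::uword)im * HW, (arma::uword)(im + 1) * HW - 1) =
          arma::repmat(g, 1, HW);
      }
      d = std::move(dIn);
      break;
    }
    case SAVE:
      if (slot_grad.count(ly.slot)) d += slot_grad[ly.slot];
      break;
    case ADDFROM:
      slot_grad[ly.slot] = d;  // identity branch gradient
      break;
    }
  }
}

static Net build_net(const List& layers, int in_dim, int img_h, int img_w) {
  Net net;
  net.in_dim = in_dim;
  net.img_h = img_h; net.img_w = img_w;
  net.layers = parse_layers(layers, img_h, img_w);
  net.Wt.assign(net.layers.size(), fmat());
  net.b.assign(net.layers.size(), fvec());
  return net;
}

// reinterpret a (784 x n) column block as conv layout (1 x 784n)
static fmat as_conv_input(const fmat& X) {
  return fmat(const_cast<float*>(X.memptr()), 1, X.n_elem, true, true);
}

// random horizontal/vertical flips applied image-wise in place
static void augment_flips(fmat& X, int H, int W, std::mt19937& rng) {
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  arma::uword n = X.n_cols;
  for (arma::uword i = 0; i < n; ++i) {
    bool fh = unif(rng) < 0.5f, fv = unif(rng) < 0.5f;
    if (!fh && !fv) continue;
    fmat img(X.colptr(i), H, W, false, true);  // view
    if (fh) img = arma::fliplr(img);
    if (fv) img = arma::flipud(img);
  }
}

// [[Rcpp::export(name = ".nn_train_cpp")]]
List nn_train_cpp(List layers, arma::mat X, arma::vec y, List config) {
  // X: in_dim x n (samples in columns), y: length n (already target-scaled)
  int n = X.n_cols;
  double lr = as<double>(config["lr"]);
  int epochs = as<int>(config["epochs"]);
  int batch = as<int>(config["batch_size"]);
  int chunk = config.containsElementNamed("chunk") ? as<int>(config["chunk"]) : 32;
  int seed = as<int>(config["seed"]);
  bool augment = as<bool>(config["augment"]);
  bool image_input = as<bool>(config["image_input"]);
  int img_h = image_input ? as<int>(config["img_h"]) : 0;
  int img_w = image_input ? as<int>(config["img_w"]) : 0;

  fmat Xf = arma::conv_to<fmat>::from(X);
  fvec yf = arma::conv_to<fvec>::from(y);

  Net net = build_net(layers, X.n_rows, img_h, img_w);
  bool conv_input = !net.layers.empty() &&
    (net.layers[0].type == CONV || net.layers[0].type == SAVE);
  std::mt19937 rng((unsigned)seed);
  float head_bias = config.containsElementNamed("head_bias") ?
    (float)as<double>(config["head_bias"]) : 0.05f;
  init_params(net, rng, head_bias);

  // Adam state
  size_t nl = net.layers.size();
  std::vector<fmat> mW(nl), vW(nl), gW(nl);
  std::vector<fvec> mb(nl), vb(nl), gb(nl);
  for (size_t i = 0; i < nl; ++i) if (!net.Wt[i].is_empty()) {
    mW[i].zeros(arma::size(net.Wt[i])); vW[i].zeros(arma::size(net.Wt[i]));
    mb[i].zeros(net.b[i].n_elem); vb[i].zeros(net.b[i].n_elem);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long tstep = 0;

  NumericVector loss_series(epochs);
  std::vector<arma::uword> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    if (n > batch) std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    int n_batches = (n + batch - 1) / batch;
    for (int bidx = 0; bidx < n_batches; ++bidx) {
      int lo = bidx * batch, hi = std::min(n, lo + batch);
      int nb = hi - lo;
      fmat Xb(X.n_rows, nb);
      fvec yb(nb);
      for (int j = 0; j < nb; ++j) { Xb.col(j) = Xf.col(order[lo + j]); yb(j) = yf(order[lo + j]); }
      if (augment && image_input) augment_flips(Xb, img_h, img_w, rng);

      for (size_t i = 0; i < nl; ++i) if (!net.Wt[i].is_empty()) {
        gW[i].zeros(arma::size(net.Wt[i])); gb[i].zeros(net.b[i].n_elem);
      }
      double batch_sse = 0.0;
      for (int c0 = 0; c0 < nb; c0 += chunk) {
        int c1 = std::min(nb, c0 + chunk), nc = c1 - c0;
        fmat Xc = Xb.cols(c0, c1 - 1);
        fmat Xin = conv_input ? as_conv_input(Xc) : Xc;
        Tape tape;
        fmat out = forward(net, Xin, nc, true, &rng, &tape);
        // out: 1 x nc
        fmat err = out - yb.subvec(c0, c1 - 1).t();
        batch_sse += arma::accu(arma::square(err));
        fmat dOut = (2.0f / (float)nb) * err;   // grad of batch-mean MSE
        backward(net, Xin, nc, tape, dOut, gW, gb);
      }
      ep_loss += batch_sse;
      // Adam step
      ++tstep;
      float bc1 = 1.0f - std::pow(b1, (float)tstep);
      float bc2 = 1.0f - std::pow(b2, (float)tstep);
      for (size_t i = 0; i < nl; ++i) if (!net.Wt[i].is_empty()) {
        mW[i] = b1 * mW[i] + (1 - b1) * gW[i];
        vW[i] = b2 * vW[i] + (1 - b2) * arma::square(gW[i]);
        net.Wt[i] -= (float)lr * (mW[i] / bc1) / (arma::sqrt(vW[i] / bc2) + eps);
        mb[i] = b1 * mb[i] + (1 - b1) * gb[i];
        vb[i] = b2 * vb[i] + (1 - b2) * arma::square(gb[i]);
        net.b[i] -= (float)lr * (mb[i] / bc1) / (arma::sqrt(vb[i] / bc2) + eps);
      }
    }
    loss_series[ep] = ep_loss / n;
    if (ep % 50 == 0) Rcpp::checkUserInterrupt();
  }

  List Wout(nl), bout(nl);
  for (size_t i = 0; i < nl; ++i) {
    if (!net.Wt[i].is_empty()) {
      Wout[i] = arma::conv_to<arma::mat>::from(net.Wt[i]);
      bout[i] = arma::conv_to<arma::vec>::from(net.b[i]);
    } else { Wout[i] = R_NilValue; bout[i] = R_NilValue; }
  }
  return List::create(_["weights"] = Wout, _["biases"] = bout,
                      _["loss"] = loss_series);
}

// [[Rcpp::export(name = ".nn_predict_cpp")]]
arma::vec nn_predict_cpp(List layers, List weights, List biases,
                         arma::mat X, List config) {
  bool image_input = as<bool>(config["image_input"]);
  int img_h = image_input ? as<int>(config["img_h"]) : 0;
  int img_w = image_input ? as<int>(config["img_w"]) : 0;
  int chunk = config.containsElementNamed("chunk") ? as<int>(config["chunk"]) : 64;
  Net net = build_net(layers, X.n_rows, img_h, img_w);
  bool conv_input = !net.layers.empty() &&
    (net.layers[0].type == CONV || net.layers[0].type == SAVE);
  for (size_t i = 0; i < net.layers.size(); ++i) {
    if (!Rf_isNull(weights[i])) {
      net.Wt[i] = arma::conv_to<fmat>::from(as<arma::mat>(weights[i]));
      net.b[i] = arma::conv_to<fvec>::from(as<arma::vec>(biases[i]));
    }
  }
  int n = X.n_cols;
  fmat Xf = arma::conv_to<fmat>::from(X);
  arma::vec out(n);
  for (int c0 = 0; c0 < n; c0 += chunk) {
    int c1 = std::min(n, c0 + chunk), nc = c1 - c0;
    fmat Xc = Xf.cols(c0, c1 - 1);
    fmat Xin = conv_input ? as_conv_input(Xc) : Xc;
    fmat o = forward_eval(net, Xin, nc);
    for (int j = 0; j < nc; ++j) out(c0 + j) = o(0, j);
  }
  return out;
}

// [[Rcpp::export(name = ".nn_param_count_cpp")]]
double nn_param_count_cpp(List layers, int in_dim, int img_h, int img_w) {
  Net net = build_net(layers, in_dim, img_h, img_w);
  double cnt = 0;
  for (const Layer& ly : net.layers) {
    if (ly.type == DENSE) cnt += (double)ly.in * ly.out + ly.out;
    if (ly.type == CONV) cnt += (double)ly.in * 9 * ly.out + ly.out;
  }
  return cnt;
}
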