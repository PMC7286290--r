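// Compact VGG-style CNN for per-slice nucleus classification.
//
// Fixed topology: [conv3x3(16) relu pool2] [conv3x3(32) relu pool2]
// [conv3x3(64) relu pool2] fc(128) relu fc(C) softmax. Input is a square
// single-channel patch whose side must be divisible by 8.
//
// Implemented with im2col + GEMM (single precision) and Adam updates.
// Inputs are centred from [0,1] to [-0.5,0.5] on the way in. All
// randomness (shuffling, augmentation) is drawn from the R RNG, so
// training is reproducible for a fixed seed and thread count.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uvec;

static const int KC[4] = {1, 16, 32, 64};  // channels entering each conv

struct Net {
  fmat W1, W2, W3, W4, W5;
  fvec b1, b2, b3, b4, b5;
  int P;  // input side
  int C;  // classes
};

static Net net_from_list(List w) {
  Net n;
  n.W1 = as<fmat>(w["W1"]); n.b1 = as<fvec>(w["b1"]);
  n.W2 = as<fmat>(w["W2"]); n.b2 = as<fvec>(w["b2"]);
  n.W3 = as<fmat>(w["W3"]); n.b3 = as<fvec>(w["b3"]);
  n.W4 = as<fmat>(w["W4"]); n.b4 = as<fvec>(w["b4"]);
  n.W5 = as<fmat>(w["W5"]); n.b5 = as<fvec>(w["b5"]);
  n.C = n.W5.n_rows;
  // derive the input side from the fc1 width: W4 cols = 64 * (P/8)^2
  int s = (int)std::round(std::sqrt((double)n.W4.n_cols / 64.0));
  n.P = 8 * s;
  return n;
}

static List net_to_list(const Net &n) {
  return List::create(_["W1"] = n.W1, _["b1"] = n.b1, _["W2"] = n.W2, _["b2"] = n.b2,
                      _["W3"] = n.W3, _["b3"] = n.b3, _["W4"] = n.W4, _["b4"] = n.b4,
                      _["W5"] = n.W5, _["b5"] = n.b5);
}

// im2col for 3x3 same-padding. in: (Cin, HW*B) feature maps, pixel index
// p = y + H*x per sample. out: (Cin*9, HW*B).
static void im2col3(const fmat &in, int H, int W, int B, fmat &col) {
  int HW = H * W;
  int Cin = in.n_rows;
  col.zeros(Cin * 9, (size_t)HW * B);
  for (int b = 0; b < B; ++b) {
    size_t so = (size_t)b * HW;
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        size_t oc = so + y + (size_t)H * x;
        int t = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy, ++t) {
            int yy = y + dy, xx = x + dx;
            if (yy < 0 || xx < 0 || yy >= H || xx >= W) continue;
            size_t ic = so + yy + (size_t)H * xx;
            for (int c = 0; c < Cin; ++c)
              col(c * 9 + t, oc) = in(c, ic);
          }
      }
  }
}

// col2im: scatter-add transpose of im2col3. dcol: (Cin*9, HW*B) -> dx (Cin, HW*B)
static void col2im3(const fmat &dcol, int H, int W, int B, fmat &dx) {
  int HW = H * W;
  int Cin = dcol.n_rows / 9;
  dx.zeros(Cin, (size_t)HW * B);
  for (int b = 0; b < B; ++b) {
    size_t so = (size_t)b * HW;
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        size_t oc = so + y + (size_t)H * x;
        int t = 0;
        for (int dx_ = -1; dx_ <= 1; ++dx_)
          for (int dy = -1; dy <= 1; ++dy, ++t) {
            int yy = y + dy, xx = x + dx_;
            if (yy < 0 || xx < 0 || yy >= H || xx >= W) continue;
            size_t ic = so + yy + (size_t)H * xx;
            for (int c = 0; c < Cin; ++c)
              dx(c, ic) += dcol(c * 9 + t, oc);
          }
      }
  }
}

// 2x2 max pooling; records argmax source columns for backward.
static void pool2(const fmat &in, int H, int W, int B, fmat &out, arma::umat &amax) {
  int Ho = H / 2, Wo = W / 2, HWo = Ho * Wo, HW = H * W;
  int C = in.n_rows;
  out.set_size(C, (size_t)HWo * B);
  amax.set_size(C, (size_t)HWo * B);
  for (int b = 0; b < B; ++b)
    for (int x = 0; x < Wo; ++x)
      for (int y = 0; y < Ho; ++y) {
        size_t oc = (size_t)b * HWo + y + (size_t)Ho * x;
        size_t c00 = (size_t)b * HW + 2 * y + (size_t)H * (2 * x);
        size_t cand[4] = {c00, c00 + 1, c00 + H, c00 + H + 1};
        for (int c = 0; c < C; ++c) {
          float best = in(c, cand[0]); size_t bi = cand[0];
          for (int t = 1; t < 4; ++t)
            if (in(c, cand[t]) > best) { best = in(c, cand[t]); bi = cand[t]; }
          out(c, oc) = best;
          amax(c, oc) = bi;
        }
      }
}

struct Cache {
  fmat col1, col2, col3;      // im2col inputs
  fmat a1, a2, a3;            // post-relu conv activations (pre-pool)
  fmat p1, p2, p3;            // pooled activations
  arma::umat m1, m2, m3;      // pool argmax
  fmat xf, h;                 // fc input and hidden
  fmat probs;
};

static void forward(const Net &n, const fmat &X, int B, Cache &cc, bool train) {
  int P = n.P;
  int H1 = P, H2 = P / 2, H3 = P / 4;
  im2col3(X, H1, H1, B, cc.col1);
  cc.a1 = n.W1 * cc.col1; cc.a1.each_col() += n.b1;
  cc.a1.transform([](float v) { return v > 0 ? v : 0.0f; });
  pool2(cc.a1, H1, H1, B, cc.p1, cc.m1);
  im2col3(cc.p1, H2, H2, B, cc.col2);
  cc.a2 = n.W2 * cc.col2; cc.a2.each_col() += n.b2;
  cc.a2.transform([](float v) { return v > 0 ? v : 0.0f; });
  pool2(cc.a2, H2, H2, B, cc.p2, cc.m2);
  im2col3(cc.p2, H3, H3, B, cc.col3);
  cc.a3 = n.W3 * cc.col3; cc.a3.each_col() += n.b3;
  cc.a3.transform([](float v) { return v > 0 ? v : 0.0f; });
  pool2(cc.a3, H3, H3, B, cc.p3, cc.m3);
  // flatten per sample: (64 * (P/8)^2, B)
  int HW4 = (P / 8) * (P / 8);
  int F = 64 * HW4;
  cc.xf.set_size(F, B);
  for (int b = 0; b < B; ++b) {
    fmat blk = cc.p3.cols((size_t)b * HW4, (size_t)b * HW4 + HW4 - 1);
    cc.xf.col(b) = arma::vectorise(blk);
  }
  cc.h = n.W4 * cc.xf; cc.h.each_col() += n.b4;
  cc.h.transform([](float v) { return v > 0 ? v : 0.0f; });
  fmat logits = n.W5 * cc.h; logits.each_col() += n.b5;
  logits.each_row() -= arma::max(logits, 0);
  cc.probs = arma::exp(logits);
  cc.probs.each_row() /= arma::sum(cc.probs, 0);
  (void)train;
}

struct Grads { fmat W1, W2, W3, W4, W5; fvec b1, b2, b3, b4, b5; };

static void unpool(const fmat &dout, const arma::umat &amax, const fmat &pre, fmat &din) {
  din.zeros(pre.n_rows, pre.n_cols);
  for (size_t j = 0; j < dout.n_cols; ++j)
    for (size_t c = 0; c < dout.n_rows; ++c)
      din(c, amax(c, j)) += dout(c, j);
  // relu gate of the pre-pool activation
  for (size_t q = 0; q < din.n_elem; ++q)
    if (pre[q] <= 0.0f) din[q] = 0.0f;
}

static double backward(const Net &n, Cache &cc, const uvec &y, int B, Grads &g) {
  int P = n.P;
  int H1 = P, H2 = P / 2, H3 = P / 4;
  int HW4 = (P / 8) * (P / 8);
  double loss = 0.0;
  fmat dlogits = cc.probs;
  for (int b = 0; b < B; ++b) {
    loss -= std::log(std::max(1e-12, (double)cc.probs(y[b], b)));
    dlogits(y[b], b) -= 1.0f;
  }
  loss /= B;
  dlogits /= (float)B;

  g.W5 = dlogits * cc.h.t(); g.b5 = arma::sum(dlogits, 1);
  fmat dh = n.W5.t() * dlogits;
  for (size_t q = 0; q < dh.n_elem; ++q) if (cc.h[q] <= 0.0f) dh[q] = 0.0f;
  g.W4 = dh * cc.xf.t(); g.b4 = arma::sum(dh, 1);
  fmat dxf = n.W4.t() * dh;

  // unflatten
  fmat dp3(64, (size_t)HW4 * B);
  for (int b = 0; b < B; ++b)
    dp3.cols((size_t)b * HW4, (size_t)b * HW4 + HW4 - 1) =
      arma::reshape(dxf.col(b), 64, HW4);

  fmat da3; unpool(dp3, cc.m3, cc.a3, da3);
  g.W3 = da3 * cc.col3.t(); g.b3 = arma::sum(da3, 1);
  fmat dcol3 = n.W3.t() * da3;
  fmat dp2; col2im3(dcol3, H3, H3, B, dp2);

  fmat da2; unpool(dp2, cc.m2, cc.a2, da2);
  g.W2 = da2 * cc.col2.t(); g.b2 = arma::sum(da2, 1);
  fmat dcol2 = n.W2.t() * da2;
  fmat dp1; col2im3(dcol2, H2, H2, B, dp1);

  fmat da1; unpool(dp1, cc.m1, cc.a1, da1);
  g.W1 = da1 * cc.col1.t(); g.b1 = arma::sum(da1, 1);
  // no gradient past the input
  return loss;
}

// apply one of the 8 dihedral ops (rotations/flips) to a P x P patch
static void dihedral(const float *src, float *dst, int P, int op) {
  for (int x = 0; x < P; ++x)
    for (int y = 0; y < P; ++y) {
      int u = y, v = x;
      switch (op & 3) {               // rotation
        case 0: break;
        case 1: { int t = u; u = P - 1 - v; v = t; } break;
        case 2: u = P - 1 - u; v = P - 1 - v; break;
        case 3: { int t = u; u = v; v = P - 1 - t; } break;
      }
      if (op & 4) u = P - 1 - u;      // flip
      dst[u + P * v] = src[y + P * x];
    }
}

// Adam state for one parameter tensor
struct AdamState { fmat m, v; fvec mb, vb; };

static void adam_step(fmat &W, fvec &b, const fmat &gW, const fvec &gb,
                      AdamState &st, float lr, float b1, float b2, int t) {
  const float eps = 1e-8f;
  st.m = b1 * st.m + (1 - b1) * gW;
  st.v = b2 * st.v + (1 - b2) * (gW % gW);
  st.mb = b1 * st.mb + (1 - b1) * gb;
  st.vb = b2 * st.vb + (1 - b2) * (gb % gb);
  float c1 = 1.0f - std::pow(b1, (float)t);
  float c2 = 1.0f - std::pow(b2, (float)t);
  W -= lr * (st.m / c1) / (arma::sqrt(st.v / c2) + eps);
  b -= lr * (st.mb / c1) / (arma::sqrt(st.vb / c2) + eps);
}

// [[Rcpp::export]]
List cpp_cnn_train(List weights, NumericVector X, IntegerVector dimX, IntegerVector y,
                   int epochs, int batch, double lr, double momentum, bool augment) {
  Net n = net_from_list(weights);
  int P = dimX[0], N = dimX[2];
  if (P != n.P) stop("patch size does not match the network input size");
  int HW = P * P;
  fmat Xall(HW, N);
  for (int i = 0; i < N; ++i)
    for (int q = 0; q < HW; ++q)
      Xall(q, i) = (float)X[(size_t)i * HW + q] - 0.5f;
  uvec yy(N);
  for (int i = 0; i < N; ++i) yy[i] = (arma::uword)y[i];

  AdamState s1, s2, s3, s4, s5;
  auto initState = [](AdamState &s, const fmat &W, const fvec &b) {
    s.m.zeros(arma::size(W)); s.v.zeros(arma::size(W));
    s.mb.zeros(b.n_elem); s.vb.zeros(b.n_elem);
  };
  initState(s1, n.W1, n.b1); initState(s2, n.W2, n.b2);
  initState(s3, n.W3, n.b3); initState(s4, n.W4, n.b4);
  initState(s5, n.W5, n.b5);
  int tstep = 0;

  RNGScope scope;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  NumericVector epoch_loss(epochs);
  Cache cc; Grads g;
  std::vector<float> tmp(HW), tmp2(HW);

  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates with the R RNG
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double tot = 0.0; int nb = 0;
    for (int s = 0; s < N; s += batch) {
      int B = std::min(batch, N - s);
      fmat Xb(HW, B);
      uvec yb(B);
      for (int b = 0; b < B; ++b) {
        int i = idx[s + b];
        yb[b] = yy[i];
        if (augment) {
          int op = (int)std::floor(unif_rand() * 8);
          if (op > 7) op = 7;
          for (int q = 0; q < HW; ++q) tmp[q] = Xall(q, i);
          dihedral(tmp.data(), tmp2.data(), P, op);
          for (int q = 0; q < HW; ++q) Xb(q, b) = tmp2[q];
        } else {
          Xb.col(b) = Xall.col(i);
        }
      }
      // forward expects (C=1, HW*B)
      fmat Xrow(1, (size_t)HW * B);
      for (int b = 0; b < B; ++b)
        for (int q = 0; q < HW; ++q)
          Xrow(0, (size_t)b * HW + q) = Xb(q, b);
      forward(n, Xrow, B, cc, true);
      tot += backward(n, cc, yb, B, g);
      ++nb;
      ++tstep;
      float flr = (float)lr, fb1 = (float)momentum, fb2 = 0.999f;
      adam_step(n.W1, n.b1, g.W1, g.b1, s1, flr, fb1, fb2, tstep);
      adam_step(n.W2, n.b2, g.W2, g.b2, s2, flr, fb1, fb2, tstep);
      adam_step(n.W3, n.b3, g.W3, g.b3, s3, flr, fb1, fb2, tstep);
      adam_step(n.W4, n.b4, g.W4, g.b4, s4, flr, fb1, fb2, tstep);
      adam_step(n.W5, n.b5, g.W5, g.b5, s5, flr, fb1, fb2, tstep);
    }
    epoch_loss[e] = tot / std::max(1, nb);
  }
  return List::create(_["weights"] = net_to_list(n), _["loss"] = epoch_loss);
}

// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(List weights, NumericVector X, IntegerVector dimX) {
  Net n = net_from_list(weights);
  int P = dimX[0], N = dimX[2];
  if (P != n.P) stop("patch size does not match the network input size");
  int HW = P * P;
  NumericMatrix out(N, n.C);
  Cache cc;
  int step = 256;
  for (int s = 0; s < N; s += step) {
    int B = std::min(step, N - s);
    fmat Xrow(1, (size_t)HW * B);
    for (int b = 0; b < B; ++b)
      for (int q = 0; q < HW; ++q)
        Xrow(0, (size_t)b * HW + q) = (float)X[(size_t)(s + b) * HW + q] - 0.5f;
    forward(n, Xrow, B, cc, false);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < n.C; ++c)
        out(s + b, c) = cc.probs(c, b);
  }
  return out;
}
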