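// Sequential neural-network engine: forward / backward over a mini-batch in
// single precision, convolutions via im2col + GEMM (BLAS sgemm through
// Armadillo). Layer kinds: conv2d (3x3, same padding), maxpool/avgpool (2x2,
// stride 2), dropout (inverted), flatten, dense. The architecture arrives as
// a declarative layer list from R; weights live on the R side as double
// matrices and are cast per call (cheap relative to the GEMMs).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

enum Kind { CONV = 0, MAXPOOL, AVGPOOL, DROPOUT, FLATTEN, DENSE };
enum Act { NONE = 0, RELU, SOFTMAX, SIGMOID };

struct LayerDef {
  int kind;
  int units;     // conv filters or dense units
  double rate;   // dropout rate
  int act;
  int widx;      // index into weight list, -1 if none
};

static int act_code(const std::string& s) {
  if (s == "relu") return RELU;
  if (s == "softmax") return SOFTMAX;
  if (s == "sigmoid") return SIGMOID;
  if (s == "none" || s == "linear") return NONE;
  stop("unknown activation '%s'", s.c_str());
}

static std::vector<LayerDef> parse_arch(List arch) {
  std::vector<LayerDef> defs;
  int widx = 0;
  for (int i = 0; i < arch.size(); ++i) {
    List L = arch[i];
    std::string kind = as<std::string>(L["kind"]);
    LayerDef d;
    d.units = 0; d.rate = 0.0; d.act = NONE; d.widx = -1;
    if (kind == "conv2d") {
      d.kind = CONV;
      d.units = as<int>(L["filters"]);
      d.act = act_code(as<std::string>(L["activation"]));
      d.widx = widx++;
    } else if (kind == "maxpool") {
      d.kind = MAXPOOL;
    } else if (kind == "avgpool") {
      d.kind = AVGPOOL;
    } else if (kind == "dropout") {
      d.kind = DROPOUT;
      d.rate = as<double>(L["rate"]);
    } else if (kind == "flatten") {
      d.kind = FLATTEN;
    } else if (kind == "dense") {
      d.kind = DENSE;
      d.units = as<int>(L["units"]);
      d.act = act_code(as<std::string>(L["activation"]));
      d.widx = widx++;
    } else {
      stop("unknown layer kind '%s'", kind.c_str());
    }
    defs.push_back(d);
  }
  return defs;
}

// im2col for 3x3 kernels, same padding. x: one sample, layout c*H*W + i*W + j.
// col: (H*W) x (C*9), so each kernel-tap column is contiguous and row-copyable.
static void im2col3(const float* x, int C, int H, int W, fmat& col) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)c * HW;
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        float* dst = col.colptr(c * 9 + (di + 1) * 3 + (dj + 1));
        int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int i = 0; i < H; ++i) {
          int ii = i + di;
          float* d = dst + (size_t)i * W;
          if (ii < 0 || ii >= H) {
            std::memset(d, 0, sizeof(float) * W);
          } else {
            const float* src = xc + (size_t)ii * W + dj;
            if (j0 > 0) d[0] = 0.0f;
            std::memcpy(d + j0, src + j0, sizeof(float) * (j1 - j0));
            if (j1 < W) d[W - 1] = 0.0f;
          }
        }
      }
    }
  }
}

// scatter-add of col layout back to image layout (adjoint of im2col3)
static void col2im3(const fmat& col, int C, int H, int W, float* x) {
  const size_t HW = (size_t)H * W;
  std::memset(x, 0, sizeof(float) * (size_t)C * HW);
  for (int c = 0; c < C; ++c) {
    float* xc = x + (size_t)c * HW;
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        const float* src = col.colptr(c * 9 + (di + 1) * 3 + (dj + 1));
        int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int i = 0; i < H; ++i) {
          int ii = i + di;
          if (ii < 0 || ii >= H) continue;
          float* dst = xc + (size_t)ii * W + dj;
          const float* s = src + (size_t)i * W;
          for (int j = j0; j < j1; ++j) dst[j] += s[j];
        }
      }
    }
  }
}

struct Shape { int C, H, W; bool flat; int len() const { return C * H * W; } };

// zero the gradient wherever the stored post-ReLU activation is zero
static void relu_mask(fmat& g, const fmat& act) {
  float* gp = g.memptr();
  const float* ap = act.memptr();
  const size_t n = g.n_elem;
  for (size_t k = 0; k < n; ++k)
    if (ap[k] <= 0.0f) gp[k] = 0.0f;
}

// [[Rcpp::export]]
List nn_run_cpp(NumericVector x, IntegerVector xdim, List arch, List weights,
                bool training, int seed, int upto, SEXP y_, int loss_type) {
  // xdim = (N, C, H, W); x layout: sample-major, then c*H*W + i*W + j
  if (xdim.size() != 4) stop("xdim must be (N, C, H, W)");
  const int N = xdim[0];
  Shape sh{xdim[1], xdim[2], xdim[3], false};
  const size_t in_len = (size_t)sh.len();
  if ((size_t)x.size() != in_len * N) stop("input length does not match dims");

  std::vector<LayerDef> defs = parse_arch(arch);
  const int nl = (int)defs.size();
  int stop_after = (upto >= 1 && upto <= nl) ? upto : nl;

  std::mt19937 rng((unsigned)seed);
  auto runif = [&rng]() { return (float)((rng() >> 8) * (1.0 / 16777216.0)); };

  // forward
  std::vector<fmat> acts(nl + 1);           // post-activation, (features x N)
  std::vector<fmat> masks(nl);              // dropout masks
  std::vector<arma::umat> argmaxes(nl);     // maxpool winner indices
  std::vector<Shape> shapes(nl + 1);
  shapes[0] = sh;
  acts[0].set_size(in_len, N);
  {
    const double* xp = x.begin();
    float* ap = acts[0].memptr();
    for (size_t k = 0; k < in_len * N; ++k) ap[k] = (float)xp[k];
    // x arrives sample-major (sample n occupies a contiguous block) -> that
    // block becomes column n directly.
  }

  std::vector<fmat> Ws(weights.size());
  std::vector<fvec> bs(weights.size());
  for (int i = 0; i < weights.size(); ++i) {
    List wl = weights[i];
    NumericMatrix W = wl["W"];
    NumericVector b = wl["b"];
    Ws[i] = arma::conv_to<fmat>::from(as<arma::mat>(W));
    bs[i] = arma::conv_to<fvec>::from(as<arma::vec>(b));
  }

  fmat col;  // im2col scratch
  for (int l = 0; l < stop_after; ++l) {
    const LayerDef& d = defs[l];
    Shape s = shapes[l];
    switch (d.kind) {
      case CONV: {
        if (s.flat) stop("conv2d applied to flattened input (layer %d)", l + 1);
        int Cout = d.units, HW = s.H * s.W;
        const fmat& W = Ws[d.widx];  // (Cout x C*9)
        if ((int)W.n_rows != Cout || (int)W.n_cols != s.C * 9)
          stop("conv weight shape mismatch at layer %d", l + 1);
        // planar output layout (channel-major): view each sample's block as
        // (HW x Cout) so column c is channel c's spatial map
        fmat Wt = W.t();  // (C*9 x Cout)
        acts[l + 1].set_size((size_t)Cout * HW, N);
        col.set_size(HW, (size_t)s.C * 9);
        for (int n = 0; n < N; ++n) {
          im2col3(acts[l].colptr(n), s.C, s.H, s.W, col);
          fmat out(acts[l + 1].colptr(n), HW, Cout, false, true);
          out = col * Wt;
          out.each_row() += bs[d.widx].t();
        }
        if (d.act == RELU) acts[l + 1].transform([](float v) { return v > 0 ? v : 0.0f; });
        shapes[l + 1] = {Cout, s.H, s.W, false};
        break;
      }
      case MAXPOOL:
      case AVGPOOL: {
        if (s.flat) stop("pooling applied to flattened input (layer %d)", l + 1);
        if (s.H % 2 || s.W % 2)
          stop("2x2 pooling needs even spatial dims, got %dx%d (layer %d)", s.H, s.W, l + 1);
        int Ho = s.H / 2, Wo = s.W / 2;
        acts[l + 1].set_size((size_t)s.C * Ho * Wo, N);
        if (d.kind == MAXPOOL) argmaxes[l].set_size((size_t)s.C * Ho * Wo, N);
        for (int n = 0; n < N; ++n) {
          const float* in = acts[l].colptr(n);
          float* out = acts[l + 1].colptr(n);
          for (int c = 0; c < s.C; ++c) {
            const float* ic = in + (size_t)c * s.H * s.W;
            float* oc = out + (size_t)c * Ho * Wo;
            for (int i = 0; i < Ho; ++i) {
              for (int j = 0; j < Wo; ++j) {
                size_t p00 = (size_t)(2 * i) * s.W + 2 * j;
                size_t idx4[4] = {p00, p00 + 1, p00 + s.W, p00 + s.W + 1};
                if (d.kind == MAXPOOL) {
                  int best = 0;
                  float bv = ic[idx4[0]];
                  for (int t = 1; t < 4; ++t)
                    if (ic[idx4[t]] > bv) { bv = ic[idx4[t]]; best = t; }
                  oc[(size_t)i * Wo + j] = bv;
                  argmaxes[l]((size_t)c * Ho * Wo + (size_t)i * Wo + j, n) =
                      (arma::uword)idx4[best];
                } else {
                  oc[(size_t)i * Wo + j] =
                      0.25f * (ic[idx4[0]] + ic[idx4[1]] + ic[idx4[2]] + ic[idx4[3]]);
                }
              }
            }
          }
        }
        shapes[l + 1] = {s.C, Ho, Wo, false};
        break;
      }
      case DROPOUT: {
        if (training && d.rate > 0) {
          float keep = (float)(1.0 - d.rate), inv = 1.0f / keep;
          masks[l].set_size(acts[l].n_rows, N);
          float* mp = masks[l].memptr();
          for (size_t k = 0; k < masks[l].n_elem; ++k)
            mp[k] = (runif() < (float)d.rate) ? 0.0f : inv;
          acts[l + 1] = acts[l] % masks[l];
        } else {
          acts[l + 1] = acts[l];
        }
        shapes[l + 1] = s;
        break;
      }
      case FLATTEN: {
        acts[l + 1] = acts[l];
        shapes[l + 1] = {s.len(), 1, 1, true};
        break;
      }
      case DENSE: {
        const fmat& W = Ws[d.widx];  // (Fin x units)
        if ((int)W.n_rows != s.len())
          stop("dense weight shape mismatch at layer %d: expected %d inputs, weights have %d",
               l + 1, s.len(), (int)W.n_rows);
        acts[l + 1] = W.t() * acts[l];
        acts[l + 1].each_col() += bs[d.widx];
        if (d.act == RELU) {
          acts[l + 1].transform([](float v) { return v > 0 ? v : 0.0f; });
        } else if (d.act == SOFTMAX) {
          for (int n = 0; n < N; ++n) {
            fvec cvec = acts[l + 1].col(n);
            cvec -= cvec.max();
            cvec = arma::exp(cvec);
            acts[l + 1].col(n) = cvec / arma::accu(cvec);
          }
        } else if (d.act == SIGMOID) {
          acts[l + 1].transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
        }
        shapes[l + 1] = {d.units, 1, 1, true};
        break;
      }
    }
  }

  List res;
  {
    // output as (N x features) double matrix
    arma::mat out = arma::conv_to<arma::mat>::from(acts[stop_after].t());
    res["output"] = wrap(out);
  }
  if (Rf_isNull(y_) || stop_after != nl) return res;

  // ---- loss + backward ----
  NumericMatrix yR(y_);
  if (yR.nrow() != N) stop("label matrix must have one row per sample");
  fmat Y = arma::conv_to<fmat>::from(as<arma::mat>(yR)).t();  // (k x N)
  const fmat& P = acts[nl];
  if (Y.n_rows != P.n_rows) stop("label width does not match network output");
  const float eps = 1e-12f;
  double loss = 0.0;
  if (loss_type == 1) {  // categorical cross-entropy, mean over samples
    loss = -arma::accu(Y % arma::log(arma::clamp(P, eps, 1.0f))) / N;
  } else if (loss_type == 2) {  // binary cross-entropy
    loss = -arma::accu(Y % arma::log(arma::clamp(P, eps, 1.0f)) +
                       (1.0f - Y) % arma::log(arma::clamp(1.0f - P, eps, 1.0f))) /
           (double)(N * P.n_rows);
  } else {
    stop("unknown loss type");
  }
  res["loss"] = loss;
  if (!training) return res;

  // gradient at pre-activation of final layer (softmax+CCE and sigmoid+BCE
  // share the same form)
  fmat g = (P - Y) / (float)N;
  if (loss_type == 2) g /= (float)P.n_rows;

  List grads(weights.size());
  bool have_pre = true;  // g is already a pre-activation gradient at entry
  for (int l = nl - 1; l >= 0; --l) {
    const LayerDef& d = defs[l];
    Shape s = shapes[l];
    switch (d.kind) {
      case DENSE: {
        if (!have_pre && d.act == RELU) {
          relu_mask(g, acts[l + 1]);
        } else if (!have_pre && d.act != NONE) {
          stop("internal: non-final nonlinear dense activation not supported in backward");
        }
        fmat dW = acts[l] * g.t();                 // (Fin x units)
        fvec db = arma::sum(g, 1);
        grads[d.widx] = List::create(
            _["W"] = wrap(arma::conv_to<arma::mat>::from(dW)),
            _["b"] = wrap(arma::conv_to<arma::vec>::from(db)));
        g = Ws[d.widx] * g;                        // (Fin x N)
        have_pre = false;
        break;
      }
      case FLATTEN:
        break;
      case DROPOUT:
        if (training && d.rate > 0) g %= masks[l];
        break;
      case MAXPOOL: {
        Shape so = shapes[l + 1];
        fmat gin((size_t)s.len(), N, arma::fill::zeros);
        for (int n = 0; n < N; ++n) {
          float* gi = gin.colptr(n);
          const float* go = g.colptr(n);
          for (int c = 0; c < so.C; ++c) {
            size_t obase = (size_t)c * so.H * so.W, ibase = (size_t)c * s.H * s.W;
            for (size_t p = 0; p < (size_t)so.H * so.W; ++p)
              gi[ibase + argmaxes[l](obase + p, n)] += go[obase + p];
          }
        }
        g = std::move(gin);
        break;
      }
      case AVGPOOL: {
        Shape so = shapes[l + 1];
        fmat gin((size_t)s.len(), N, arma::fill::zeros);
        for (int n = 0; n < N; ++n) {
          float* gi = gin.colptr(n);
          const float* go = g.colptr(n);
          for (int c = 0; c < so.C; ++c) {
            const float* gc = go + (size_t)c * so.H * so.W;
            float* ic = gi + (size_t)c * s.H * s.W;
            for (int i = 0; i < so.H; ++i)
              for (int j = 0; j < so.W; ++j) {
                float v = 0.25f * gc[(size_t)i * so.W + j];
                size_t p00 = (size_t)(2 * i) * s.W + 2 * j;
                ic[p00] += v; ic[p00 + 1] += v;
                ic[p00 + s.W] += v; ic[p00 + s.W + 1] += v;
              }
          }
        }
        g = std::move(gin);
        break;
      }
      case CONV: {
        if (d.act == RELU) relu_mask(g, acts[l + 1]);
        int Cout = d.units, HW = s.H * s.W;
        const fmat& W = Ws[d.widx];  // (Cout x C*9)
        fmat dWt((size_t)s.C * 9, (size_t)Cout, arma::fill::zeros);
        fvec db((size_t)Cout, arma::fill::zeros);
        fmat gin((size_t)s.len(), N);
        col.set_size(HW, (size_t)s.C * 9);
        fmat dcol(HW, (size_t)s.C * 9);
        for (int n = 0; n < N; ++n) {
          fmat gv(g.colptr(n), HW, Cout, false, true);  // planar view
          im2col3(acts[l].colptr(n), s.C, s.H, s.W, col);
          dWt += col.t() * gv;
          db += arma::sum(gv, 0).t();
          dcol = gv * W;
          col2im3(dcol, s.C, s.H, s.W, gin.colptr(n));
        }
        grads[d.widx] = List::create(
            _["W"] = wrap(arma::conv_to<arma::mat>::from(dWt.t())),
            _["b"] = wrap(arma::conv_to<arma::vec>::from(db)));
        g = std::move(gin);
        break;
      }
    }
  }
  res["grads"] = grads;
  return res;
}
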