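// 1D convolutional network for FM demodulation of the sonified ECG stream.
// Four conv layers with linear activations, non-overlapping max pooling and
// dropout; trained by Adam on mean-squared error. Single precision
// throughout (the usual deep-learning arithmetic); convolutions are im2col +
// BLAS GEMM. All randomness (shuffling, dropout) comes from an mt19937
// seeded from R, so fixed-seed runs are reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::IntegerVector;
using Rcpp::stop;

struct Layer {
  int k, cin, cout, pool;
  fmat W;    // (k * cin) x cout, row index = cin_channel * k + kernel_pos
  frowvec b; // 1 x cout
};

// 'same' padding, less on the left for even kernels (floor((k-1)/2)).
static fmat im2col_same(const fmat& x, int k) {
  const int len = x.n_rows, cin = x.n_cols, pad = (k - 1) / 2;
  fmat cols(len, k * cin, fill::zeros);
  for (int c = 0; c < cin; ++c)
    for (int j = 0; j < k; ++j) {
      const int off = j - pad;
      const int lo = std::max(0, -off), hi = std::min(len, len - off);
      if (lo < hi)
        cols.submat(lo, c * k + j, hi - 1, c * k + j) =
          x.submat(lo + off, c, hi + off - 1, c);
    }
  return cols;
}

static fmat col2im_same(const fmat& dcols, int k, int cin) {
  const int len = dcols.n_rows, pad = (k - 1) / 2;
  fmat dx(len, cin, fill::zeros);
  for (int c = 0; c < cin; ++c)
    for (int j = 0; j < k; ++j) {
      const int off = j - pad;
      const int lo = std::max(0, -off), hi = std::min(len, len - off);
      if (lo < hi)
        dx.submat(lo + off, c, hi + off - 1, c) +=
          dcols.submat(lo, c * k + j, hi - 1, c * k + j);
    }
  return dx;
}

static std::vector<Layer> unpack(const List& weights, const List& arch) {
  IntegerVector kk = arch["kernel"], ci = arch["cin"], co = arch["cout"],
                pp = arch["pool"];
  std::vector<Layer> layers(kk.size());
  for (int l = 0; l < kk.size(); ++l) {
    List wl = weights[l];
    NumericMatrix W = wl["W"];
    Rcpp::NumericVector b = wl["b"];
    Layer& L = layers[l];
    L.k = kk[l]; L.cin = ci[l]; L.cout = co[l]; L.pool = pp[l];
    if (W.nrow() != L.k * L.cin || W.ncol() != L.cout)
      stop("weight matrix of layer %d has the wrong shape", l + 1);
    L.W = conv_to<fmat>::from(mat(W.begin(), W.nrow(), W.ncol(), false));
    L.b = conv_to<frowvec>::from(rowvec(b.begin(), b.size(), false));
  }
  return layers;
}

static List pack(const std::vector<Layer>& layers) {
  List out(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) {
    mat W = conv_to<mat>::from(layers[l].W);
    rowvec b = conv_to<rowvec>::from(layers[l].b);
    out[l] = List::create(Rcpp::Named("W") = W,
                          Rcpp::Named("b") = Rcpp::NumericVector(b.begin(), b.end()));
  }
  return out;
}

struct Cache {
  fmat cols;      // im2col of the layer input
  umat argmax;    // row index of each pooled maximum
  fmat mask;      // dropout mask (already scaled), empty when inactive
  int len_in;
};

// Forward through all layers; caches are filled only when train == true.
static fmat forward(const std::vector<Layer>& layers, const fmat& x,
                    bool train, float dropout, std::mt19937* rng,
                    std::vector<Cache>* caches) {
  fmat cur = x;
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  for (size_t l = 0; l < layers.size(); ++l) {
    const Layer& L = layers[l];
    if ((int)cur.n_cols != L.cin)
      stop("layer %d expects %d channels, got %d", (int)l + 1, L.cin,
           (int)cur.n_cols);
    if (cur.n_rows % L.pool != 0)
      stop("layer %d: input length %d not divisible by pool %d", (int)l + 1,
           (int)cur.n_rows, L.pool);
    fmat cols = im2col_same(cur, L.k);
    fmat z = cols * L.W;
    z.each_row() += L.b;
    fmat pooled;
    umat amax;
    if (L.pool > 1) {
      const int n_out = z.n_rows / L.pool;
      pooled.set_size(n_out, z.n_cols);
      amax.set_size(n_out, z.n_cols);
      for (uword c = 0; c < z.n_cols; ++c)
        for (int i = 0; i < n_out; ++i) {
          uword rel;
          pooled(i, c) = z.col(c).subvec(i * L.pool, (i + 1) * L.pool - 1)
                           .max(rel);
          amax(i, c) = i * L.pool + rel;
        }
    } else {
      pooled = z;
    }
    fmat mask;
    if (train && dropout > 0.0f) {
      mask.set_size(pooled.n_rows, pooled.n_cols);
      const float scale = 1.0f / (1.0f - dropout);
      for (uword i = 0; i < mask.n_elem; ++i)
        mask(i) = (unif(*rng) < dropout) ? 0.0f : scale;
      pooled %= mask;
    }
    if (caches) {
      Cache& C = (*caches)[l];
      C.cols = std::move(cols);
      C.argmax = std::move(amax);
      C.mask = std::move(mask);
      C.len_in = cur.n_rows;
    }
    cur = std::move(pooled);
  }
  return cur;
}

// Backward pass for one sample; accumulates gradients into gW/gb.
static void backward(const std::vector<Layer>& layers,
                     const std::vector<Cache>& caches, const fmat& dout,
                     std::vector<fmat>& gW, std::vector<frowvec>& gb) {
  fmat d = dout;
  for (int l = (int)layers.size() - 1; l >= 0; --l) {
    const Layer& L = layers[l];
    const Cache& C = caches[l];
    if (!C.mask.is_empty()) d %= C.mask;
    fmat dz;
    if (L.pool > 1) {
      dz.zeros(C.cols.n_rows, L.cout);
      for (uword c = 0; c < d.n_cols; ++c)
        for (uword i = 0; i < d.n_rows; ++i)
          dz(C.argmax(i, c), c) += d(i, c);
    } else {
      dz = std::move(d);
    }
    gW[l] += C.cols.t() * dz;
    gb[l] += sum(dz, 0);
    if (l > 0) d = col2im_same(dz * L.W.t(), L.k, L.cin);
  }
}

static double eval_rmse(const std::vector<Layer>& layers,
                        const std::vector<fmat>& xs,
                        const std::vector<fmat>& ys) {
  double sse = 0.0, n = 0.0;
  for (size_t i = 0; i < xs.size(); ++i) {
    fmat pred = forward(layers, xs[i], false, 0.0f, nullptr, nullptr);
    sse += accu(square(conv_to<mat>::from(pred) - conv_to<mat>::from(ys[i])));
    n += ys[i].n_elem;
  }
  return std::sqrt(sse / n);
}

static std::vector<fmat> as_fmats(const List& lst) {
  std::vector<fmat> out(lst.size());
  for (int i = 0; i < lst.size(); ++i) {
    NumericMatrix m = lst[i];
    out[i] = conv_to<fmat>::from(mat(m.begin(), m.nrow(), m.ncol(), false));
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(List weights, List arch, NumericMatrix x) {
  std::vector<Layer> layers = unpack(weights, arch);
  fmat xin = conv_to<fmat>::from(mat(x.begin(), x.nrow(), x.ncol(), false));
  fmat out = forward(layers, xin, false, 0.0f, nullptr, nullptr);
  mat outd = conv_to<mat>::from(out);
  return Rcpp::wrap(outd);
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, List arch, List x_train, List y_train,
                   List x_val, List y_val, int epochs, int batch_size,
                   double lr, double dropout, int patience, int seed,
                   bool shuffle) {
  std::vector<Layer> layers = unpack(weights, arch);
  std::vector<fmat> xtr = as_fmats(x_train), ytr = as_fmats(y_train);
  std::vector<fmat> xva = as_fmats(x_val), yva = as_fmats(y_val);
  const int n = xtr.size(), L = layers.size();
  if (n == 0) stop("empty training dataset");

  // Adam state
  std::vector<fmat> mW(L), vW(L), gW(L);
  std::vector<frowvec> mb(L), vb(L), gb(L);
  for (int l = 0; l < L; ++l) {
    mW[l].zeros(size(layers[l].W)); vW[l].zeros(size(layers[l].W));
    mb[l].zeros(layers[l].cout);    vb[l].zeros(layers[l].cout);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  long step = 0;

  std::mt19937 rng(seed);
  std::vector<Cache> caches(L);
  std::vector<double> train_hist, val_hist;
  std::vector<Layer> best = layers;
  double best_val = datum::inf;
  int best_epoch = 0, since_best = 0, epochs_run = 0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    if (shuffle) std::shuffle(order.begin(), order.end(), rng);
    double epoch_sse = 0.0, epoch_n = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int bend = std::min(n, start + batch_size);
      const int bn = bend - start;
      for (int l = 0; l < L; ++l) {
        gW[l].zeros(size(layers[l].W));
        gb[l].zeros(layers[l].cout);
      }
      double batch_elems = 0.0;
      for (int bi = start; bi < bend; ++bi)
        batch_elems += ytr[order[bi]].n_elem;
      for (int bi = start; bi < bend; ++bi) {
        const fmat& x = xtr[order[bi]];
        const fmat& y = ytr[order[bi]];
        fmat pred = forward(layers, x, true, (float)dropout, &rng, &caches);
        fmat diff = pred - y;
        epoch_sse += accu(square(conv_to<mat>::from(diff)));
        epoch_n += y.n_elem;
        fmat dout = diff * (2.0f / (float)batch_elems);
        backward(layers, caches, dout, gW, gb);
      }
      (void)bn;
      // Adam update
      ++step;
      const float c1 = 1.0f - std::pow(b1, (float)step);
      const float c2 = 1.0f - std::pow(b2, (float)step);
      for (int l = 0; l < L; ++l) {
        mW[l] = b1 * mW[l] + (1.0f - b1) * gW[l];
        vW[l] = b2 * vW[l] + (1.0f - b2) * square(gW[l]);
        layers[l].W -= (float)lr * (mW[l] / c1) / (sqrt(vW[l] / c2) + eps);
        mb[l] = b1 * mb[l] + (1.0f - b1) * gb[l];
        vb[l] = b2 * vb[l] + (1.0f - b2) * square(gb[l]);
        layers[l].b -= (float)lr * (mb[l] / c1) / (sqrt(vb[l] / c2) + eps);
      }
    }
    ++epochs_run;
    train_hist.push_back(std::sqrt(epoch_sse / epoch_n));
    if (!xva.empty()) {
      const double vr = eval_rmse(layers, xva, yva);
      val_hist.push_back(vr);
      if (vr < best_val) {
        best_val = vr;
        best = layers;
        best_epoch = epoch + 1;
        since_best = 0;
      } else if (++since_best >= patience) {
        break;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  if (xva.empty()) { best = layers; best_epoch = epochs_run; }
  return List::create(
    Rcpp::Named("weights") = pack(best),
    Rcpp::Named("final_weights") = pack(layers),
    Rcpp::Named("train_rmse") = train_hist,
    Rcpp::Named("val_rmse") = val_hist,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("epochs_run") = epochs_run);
}
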