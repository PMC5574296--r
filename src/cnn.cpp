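// Minimal CNN engine for the 227x227 window classifier.
// Single-image forward/backward with im2col + GEMM convolutions; all
// randomness (weight init, shuffling) is supplied from R so training is
// bit-reproducible under a fixed seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Layer {
  std::string type;      // conv, relu, maxpool, dense, softmax
  int filters = 0, kernel = 0, stride = 1, pad = 0, units = 0;
  // parameters (conv: W is filters x (k*k*in_c); dense: units x in)
  mat W; vec b;
  mat vW; vec vb;        // momentum buffers
  // caches for backward
  mat cols;              // conv: im2col of padded input
  mat in_mat;            // dense: input column
  umat pool_argmax;      // maxpool: flat index into padded-less input, per out px
  mat relu_mask;
  int in_h = 0, in_w = 0, in_c = 0, out_h = 0, out_w = 0;
  bool flatten_before = false;   // dense layer fed by a cube
};

struct Net {
  std::vector<Layer> layers;
  int in_h = 227, in_w = 227, in_c = 3;
};

static void conv_geom(int in, int k, int s, int p, int &out) {
  out = (in + 2 * p - k) / s + 1;
}

// im2col for a HxWxC cube -> (k*k*C) x (out_h*out_w)
static void im2col(const cube &x, int k, int s, int p, mat &cols,
                   int out_h, int out_w) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cols.set_size(k * k * C, out_h * out_w);
  for (int oy = 0; oy < out_h; ++oy) {
    for (int ox = 0; ox < out_w; ++ox) {
      const int cidx = oy * out_w + ox;
      double *dst = cols.colptr(cidx);
      for (int c = 0; c < C; ++c) {
        const mat &sl = x.slice(c);
        for (int kx = 0; kx < k; ++kx) {
          const int px = ox * s - p + kx;
          for (int ky = 0; ky < k; ++ky) {
            const int py = oy * s - p + ky;
            dst[c * k * k + kx * k + ky] =
              (px >= 0 && px < W && py >= 0 && py < H) ? sl(py, px) : 0.0;
          }
        }
      }
    }
  }
}

// scatter-add columns back into image gradient (inverse of im2col)
static void col2im(const mat &dcols, int k, int s, int p, cube &dx,
                   int H, int W, int C, int out_h, int out_w) {
  dx.zeros(H, W, C);
  for (int oy = 0; oy < out_h; ++oy) {
    for (int ox = 0; ox < out_w; ++ox) {
      const int cidx = oy * out_w + ox;
      const double *src = dcols.colptr(cidx);
      for (int c = 0; c < C; ++c) {
        mat &sl = dx.slice(c);
        for (int kx = 0; kx < k; ++kx) {
          const int px = ox * s - p + kx;
          if (px < 0 || px >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int py = oy * s - p + ky;
            if (py < 0 || py >= H) continue;
            sl(py, px) += src[c * k * k + kx * k + ky];
          }
        }
      }
    }
  }
}

static Net *as_net(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  return p.get();
}

// Forward pass. If train, caches are kept for backward.
// Returns the final activation vector (softmax probabilities if the last
// layer is softmax). fc_tap: 1-based index (into dense layers) whose
// post-activation output to record in tap_out (0 = none).
static vec forward(Net *net, const cube &img, bool train, int fc_tap,
                   vec &tap_out, std::vector<ivec> *shapes = nullptr) {
  cube x = img;
  vec v;                 // vector signal once flattened
  bool vectorized = false;
  int dense_seen = 0;
  for (size_t li = 0; li < net->layers.size(); ++li) {
    Layer &L = net->layers[li];
    if (L.type == "conv") {
      L.in_h = x.n_rows; L.in_w = x.n_cols; L.in_c = x.n_slices;
      conv_geom(L.in_h, L.kernel, L.stride, L.pad, L.out_h);
      conv_geom(L.in_w, L.kernel, L.stride, L.pad, L.out_w);
      mat cols;
      im2col(x, L.kernel, L.stride, L.pad, cols, L.out_h, L.out_w);
      mat out = L.W * cols;              // filters x (out_h*out_w)
      out.each_col() += L.b;
      if (train) L.cols = std::move(cols);
      cube y(L.out_h, L.out_w, L.filters);
      for (int f = 0; f < L.filters; ++f)
        y.slice(f) = reshape(out.row(f), L.out_w, L.out_h).t();
      x = std::move(y);
    } else if (L.type == "maxpool") {
      L.in_h = x.n_rows; L.in_w = x.n_cols; L.in_c = x.n_slices;
      conv_geom(L.in_h, L.kernel, L.stride, 0, L.out_h);
      conv_geom(L.in_w, L.kernel, L.stride, 0, L.out_w);
      cube y(L.out_h, L.out_w, L.in_c);
      if (train) L.pool_argmax.set_size(L.out_h * L.out_w, L.in_c);
      for (int c = 0; c < L.in_c; ++c) {
        const mat &sl = x.slice(c);
        for (int oy = 0; oy < L.out_h; ++oy) {
          for (int ox = 0; ox < L.out_w; ++ox) {
            double best = -datum::inf; int bi = 0;
            for (int kx = 0; kx < L.kernel; ++kx) {
              const int px = ox * L.stride + kx;
              if (px >= L.in_w) continue;
              for (int ky = 0; ky < L.kernel; ++ky) {
                const int py = oy * L.stride + ky;
                if (py >= L.in_h) continue;
                const double val = sl(py, px);
                if (val > best) { best = val; bi = py + px * L.in_h; }
              }
            }
            y(oy, ox, c) = best;
            if (train) L.pool_argmax(oy * L.out_w + ox, c) = bi;
          }
        }
      }
      x = std::move(y);
    } else if (L.type == "relu") {
      if (vectorized) {
        if (train) { L.relu_mask = conv_to<mat>::from(v > 0); }
        v = clamp(v, 0.0, datum::inf);
      } else {
        if (train) {
          L.relu_mask = mat(x.memptr(), x.n_elem, 1);
          L.relu_mask.transform([](double z) { return z > 0 ? 1.0 : 0.0; });
        }
        x.transform([](double z) { return z > 0 ? z : 0.0; });
      }
      if (vectorized && fc_tap > 0 && dense_seen == fc_tap) {
        tap_out = v;
        if (!train && shapes == nullptr) return v;   // early exit for feature taps
      }
    } else if (L.type == "dense") {
      if (!vectorized) {
        L.flatten_before = true;
        L.in_h = x.n_rows; L.in_w = x.n_cols; L.in_c = x.n_slices;
        v = vectorise(x);
        vectorized = true;
      }
      if (train) L.in_mat = v;
      v = L.W * v + L.b;
      ++dense_seen;
    } else if (L.type == "softmax") {
      const double m = v.max();
      vec e = exp(v - m);
      v = e / accu(e);
    }
    if (shapes) {
      if (vectorized) shapes->push_back(ivec{(sword)v.n_elem});
      else shapes->push_back(ivec{(sword)x.n_rows, (sword)x.n_cols,
                                  (sword)x.n_slices});
    }
  }
  return v;
}

// Backward from softmax cross-entropy; accumulates parameter grads into gW/gb.
static void backward(Net *net, const vec &probs, int label,
                     std::vector<mat> &gW, std::vector<vec> &gb) {
  vec dv = probs;
  dv(label) -= 1.0;      // d loss / d logits
  cube dx;
  bool vectorized = true;
  for (int li = (int)net->layers.size() - 1; li >= 0; --li) {
    Layer &L = net->layers[li];
    if (L.type == "softmax") {
      continue;          // folded into the cross-entropy gradient
    } else if (L.type == "dense") {
      gW[li] += dv * L.in_mat.t();
      gb[li] += dv;
      vec din = L.W.t() * dv;
      if (L.flatten_before) {
        dx = cube(din.memptr(), L.in_h, L.in_w, L.in_c);
        vectorized = false;
      } else {
        dv = std::move(din);
      }
    } else if (L.type == "relu") {
      if (vectorized) {
        dv %= L.relu_mask.col(0).head(dv.n_elem);
      } else {
        vec m = L.relu_mask.col(0);
        cube mk(m.memptr(), dx.n_rows, dx.n_cols, dx.n_slices);
        dx %= mk;
      }
    } else if (L.type == "maxpool") {
      cube din(L.in_h, L.in_w, L.in_c, fill::zeros);
      for (int c = 0; c < L.in_c; ++c) {
        mat &sl = din.slice(c);
        for (int o = 0; o < L.out_h * L.out_w; ++o) {
          const int oy = o / L.out_w, ox = o % L.out_w;
          sl(L.pool_argmax(o, c)) += dx(oy, ox, c);
        }
      }
      dx = std::move(din);
    } else if (L.type == "conv") {
      mat dout(L.filters, L.out_h * L.out_w);
      for (int f = 0; f < L.filters; ++f)
        dout.row(f) = vectorise(dx.slice(f).t()).t();
      gW[li] += dout * L.cols.t();
      gb[li] += sum(dout, 1);
      if (li > 0) {
        mat dcols = L.W.t() * dout;
        col2im(dcols, L.kernel, L.stride, L.pad, dx,
               L.in_h, L.in_w, L.in_c, L.out_h, L.out_w);
      }
    }
  }
}

static cube img_from_sexp(SEXP s) {
  Rcpp::NumericVector a(s);
  Rcpp::IntegerVector d = a.attr("dim");
  cube x(a.begin(), d[0], d[1], d[2]);   // copies; R arrays are column-major
  return x;
}

// [[Rcpp::export]]
SEXP cnn_create(Rcpp::List spec, Rcpp::List weights) {
  Net *net = new Net();
  for (int i = 0; i < spec.size(); ++i) {
    Rcpp::List ls = spec[i];
    Layer L;
    L.type = Rcpp::as<std::string>(ls["type"]);
    if (L.type == "conv") {
      L.filters = ls["filters"]; L.kernel = ls["kernel"];
      L.stride = ls["stride"]; L.pad = ls["pad"];
    } else if (L.type == "maxpool") {
      L.kernel = ls["kernel"]; L.stride = ls["stride"];
    } else if (L.type == "dense") {
      L.units = ls["units"];
    }
    net->layers.push_back(std::move(L));
  }
  for (size_t li = 0; li < net->layers.size(); ++li) {
    Layer &L = net->layers[li];
    if (L.type != "conv" && L.type != "dense") continue;
    Rcpp::List wl = weights[li];
    Rcpp::NumericMatrix Wm = wl["W"];
    Rcpp::NumericVector bv = wl["b"];
    L.W = mat(Wm.begin(), Wm.nrow(), Wm.ncol());
    L.b = vec(bv.begin(), bv.size());
    // momentum buffers are allocated lazily by cnn_train_cpp so that
    // inference-only networks cost one copy of the weights
  }
  Rcpp::XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
Rcpp::List cnn_forward_cpp(SEXP ptr, SEXP img, int fc_tap = 2) {
  Net *net = as_net(ptr);
  cube x = img_from_sexp(img);
  vec tap;
  std::vector<ivec> shapes;
  vec out = forward(net, x, false, fc_tap, tap, &shapes);
  Rcpp::List sh(shapes.size());
  for (size_t i = 0; i < shapes.size(); ++i)
    sh[i] = Rcpp::IntegerVector(shapes[i].begin(), shapes[i].end());
  return Rcpp::List::create(
    Rcpp::Named("output") = Rcpp::NumericVector(out.begin(), out.end()),
    Rcpp::Named("tap") = Rcpp::NumericVector(tap.begin(), tap.end()),
    Rcpp::Named("shapes") = sh);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cnn_features_cpp(SEXP ptr, Rcpp::List imgs, int fc_tap = 2) {
  Net *net = as_net(ptr);
  const int n = imgs.size();
  Rcpp::NumericMatrix out;
  for (int i = 0; i < n; ++i) {
    cube x = img_from_sexp(imgs[i]);
    vec tap;
    forward(net, x, false, fc_tap, tap);
    if (i == 0) out = Rcpp::NumericMatrix(n, tap.n_elem);
    for (size_t j = 0; j < tap.n_elem; ++j) out(i, j) = tap(j);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cnn_train_cpp(SEXP ptr, Rcpp::List imgs,
                                  Rcpp::IntegerVector labels,
                                  Rcpp::IntegerMatrix order,
                                  double lr, double momentum, int batch) {
  Net *net = as_net(ptr);
  const int n = imgs.size(), epochs = order.ncol();
  std::vector<mat> gW(net->layers.size());
  std::vector<vec> gb(net->layers.size());
  Rcpp::NumericVector epoch_loss(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    for (int start = 0; start < n; start += batch) {
      const int bsz = std::min(batch, n - start);
      for (size_t li = 0; li < net->layers.size(); ++li) {
        Layer &L = net->layers[li];
        if (L.type == "conv" || L.type == "dense") {
          gW[li] = zeros<mat>(L.W.n_rows, L.W.n_cols);
          gb[li] = zeros<vec>(L.b.n_elem);
        }
      }
      for (int bi = 0; bi < bsz; ++bi) {
        const int idx = order(start + bi, ep) - 1;   // 1-based from R
        cube x = img_from_sexp(imgs[idx]);
        vec tap;
        vec probs = forward(net, x, true, 0, tap);
        const int y = labels[idx];
        loss_sum += -std::log(std::max(probs(y), 1e-12));
        backward(net, probs, y, gW, gb);
        Rcpp::checkUserInterrupt();
      }
      for (size_t li = 0; li < net->layers.size(); ++li) {
        Layer &L = net->layers[li];
        if (L.type != "conv" && L.type != "dense") continue;
        if (L.vW.n_elem == 0) {
          L.vW = zeros<mat>(L.W.n_rows, L.W.n_cols);
          L.vb = zeros<vec>(L.b.n_elem);
        }
        L.vW = momentum * L.vW - lr * (gW[li] / bsz);
        L.vb = momentum * L.vb - lr * (gb[li] / bsz);
        L.W += L.vW;
        L.b += L.vb;
      }
    }
    epoch_loss[ep] = loss_sum / n;
  }
  // release training-only state (activation caches, momentum); the network
  // keeps only its weights for inference
  for (auto &L : net->layers) {
    L.cols.reset(); L.in_mat.reset(); L.relu_mask.reset();
    L.pool_argmax.reset(); L.vW.reset(); L.vb.reset();
  }
  return epoch_loss;
}

// [[Rcpp::export]]
Rcpp::List cnn_get_weights_cpp(SEXP ptr) {
  Net *net = as_net(ptr);
  Rcpp::List out(net->layers.size());
  for (size_t li = 0; li < net->layers.size(); ++li) {
    Layer &L = net->layers[li];
    if (L.type != "conv" && L.type != "dense") continue;
    Rcpp::NumericMatrix Wm(L.W.n_rows, L.W.n_cols);
    std::copy(L.W.begin(), L.W.end(), Wm.begin());
    Rcpp::NumericVector bv(L.b.begin(), L.b.end());
    out[li] = Rcpp::List::create(Rcpp::Named("W") = Wm, Rcpp::Named("b") = bv);
  }
  return out;
}

// [[Rcpp::export]]
bool ptr_is_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != nullptr;
}
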