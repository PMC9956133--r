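// Desk-scale convolutional stand-ins for the two pipeline models:
//  * a 3-level nested-U heatmap regressor (dense skip aggregation),
//    trained with mean-squared error on the saliency maps;
//  * a single-scale grid detector (S x S cells, one box slot per cell),
//    trained with GIoU + confidence BCE + class BCE.
// Feature maps are arma::cube (rows = y, cols = x, slices = channels);
// convolutions are im2col + GEMM, 3x3 same-padding or 1x1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// ---------------------------------------------------------------- conv ops
// im2col uses a transposed layout (H*W rows, C*9 columns) so every
// (channel, kernel-offset) pair fills one contiguous column via memcpy,
// and the GEMMs run on tall-skinny matrices.

static mat im2col3T(const cube& in) {
  const uword H = in.n_rows, W = in.n_cols, C = in.n_slices;
  mat col(H * W, C * 9, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& sl = in.slice(c);
    for (int ky = 0; ky < 3; ++ky) {
      const uword ylo = (ky == 0) ? 1 : 0;
      const uword yhi = (ky == 2) ? H - 1 : H;
      for (int kx = 0; kx < 3; ++kx) {
        const uword r = c * 9 + ky * 3 + kx;
        double* dst = col.colptr(r);
        for (uword x = 0; x < W; ++x) {
          const long sx = (long)x + kx - 1;
          if (sx < 0 || sx >= (long)W) continue;
          const double* src = sl.colptr(sx) + (ylo + ky - 1);
          std::memcpy(dst + x * H + ylo, src, (yhi - ylo) * sizeof(double));
        }
      }
    }
  }
  return col;
}

static cube col2im3T(const mat& dcol, uword H, uword W, uword C) {
  cube din(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& sl = din.slice(c);
    for (int ky = 0; ky < 3; ++ky) {
      const uword ylo = (ky == 0) ? 1 : 0;
      const uword yhi = (ky == 2) ? H - 1 : H;
      for (int kx = 0; kx < 3; ++kx) {
        const uword r = c * 9 + ky * 3 + kx;
        const double* src = dcol.colptr(r);
        for (uword x = 0; x < W; ++x) {
          const long sx = (long)x + kx - 1;
          if (sx < 0 || sx >= (long)W) continue;
          double* dst = sl.colptr(sx) + (ylo + ky - 1);
          const double* s = src + x * H + ylo;
          for (uword y = 0; y < yhi - ylo; ++y) dst[y] += s[y];
        }
      }
    }
  }
  return din;
}

// flat (H*W, C) view of a cube's memory (no copy; layouts coincide)
static mat flat_view(const cube& x) {
  return mat(const_cast<double*>(x.memptr()),
             x.n_rows * x.n_cols, x.n_slices, false, true);
}

// 3x3 same conv; caches the im2col matrix for the backward pass
static cube conv3_fwd(const mat& W, const vec& b, const cube& in, mat& colT) {
  colT = im2col3T(in);
  mat outT = colT * W.t();
  outT.each_row() += b.t();
  return cube(outT.memptr(), in.n_rows, in.n_cols, W.n_rows);
}

static void conv3_bwd(const mat& W, const mat& colT, const cube& dout,
                      uword C_in, mat& dW, vec& db, cube& din,
                      bool need_din) {
  const mat doutT = flat_view(dout);
  dW = doutT.t() * colT;
  db = vectorise(sum(doutT, 0));
  if (need_din) {
    mat dcolT = doutT * W;
    din = col2im3T(dcolT, dout.n_rows, dout.n_cols, C_in);
  }
}

static cube conv1_fwd(const mat& W, const vec& b, const cube& in, mat& inT) {
  // deep copy: cached for backward while `in`'s storage may be reused
  inT = mat(const_cast<double*>(in.memptr()),
            in.n_rows * in.n_cols, in.n_slices);
  mat outT = inT * W.t();
  outT.each_row() += b.t();
  return cube(outT.memptr(), in.n_rows, in.n_cols, W.n_rows);
}

static void conv1_bwd(const mat& W, const mat& inT, const cube& dout,
                      mat& dW, vec& db, cube& din) {
  const mat doutT = flat_view(dout);
  dW = doutT.t() * inT;
  db = vectorise(sum(doutT, 0));
  mat dinT = doutT * W;
  din = cube(dinT.memptr(), dout.n_rows, dout.n_cols, W.n_cols);
}

// leaky ReLU (slope 0.1 for negative inputs): keeps gradient flowing
// through units pushed negative early in training, which a sparse-well
// MSE target otherwise kills off wholesale
static const double LRELU = 0.1;

static void relu_inplace(cube& x) {
  x.transform([](double v) { return v > 0 ? v : LRELU * v; });
}

static cube relu_bwd(const cube& post, const cube& dout) {
  cube d = dout;
  for (uword i = 0; i < d.n_elem; ++i) if (post(i) <= 0) d(i) *= LRELU;
  return d;
}

static cube pool2_fwd(const cube& in, ucube& amax) {
  const uword H = in.n_rows / 2, W = in.n_cols / 2, C = in.n_slices;
  cube out(H, W, C);
  amax.set_size(H, W, C);
  for (uword c = 0; c < C; ++c) {
    for (uword x = 0; x < W; ++x) {
      for (uword y = 0; y < H; ++y) {
        double best = -datum::inf; uword bi = 0;
        for (int dx = 0; dx < 2; ++dx) {
          for (int dy = 0; dy < 2; ++dy) {
            const uword sy = 2 * y + dy, sx = 2 * x + dx;
            const double v = in(sy, sx, c);
            if (v > best) { best = v; bi = sx * in.n_rows + sy; }
          }
        }
        out(y, x, c) = best;
        amax(y, x, c) = bi;
      }
    }
  }
  return out;
}

static cube pool2_bwd(const cube& dout, const ucube& amax,
                      uword H_in, uword W_in) {
  cube din(H_in, W_in, dout.n_slices, fill::zeros);
  for (uword c = 0; c < dout.n_slices; ++c) {
    for (uword x = 0; x < dout.n_cols; ++x)
      for (uword y = 0; y < dout.n_rows; ++y)
        din.slice(c)(amax(y, x, c)) += dout(y, x, c);
  }
  return din;
}

static cube up2_fwd(const cube& in) {
  cube out(2 * in.n_rows, 2 * in.n_cols, in.n_slices);
  for (uword c = 0; c < in.n_slices; ++c)
    for (uword x = 0; x < out.n_cols; ++x)
      for (uword y = 0; y < out.n_rows; ++y)
        out(y, x, c) = in(y / 2, x / 2, c);
  return out;
}

static cube up2_bwd(const cube& dout) {
  cube din(dout.n_rows / 2, dout.n_cols / 2, dout.n_slices, fill::zeros);
  for (uword c = 0; c < dout.n_slices; ++c)
    for (uword x = 0; x < dout.n_cols; ++x)
      for (uword y = 0; y < dout.n_rows; ++y)
        din(y / 2, x / 2, c) += dout(y, x, c);
  return din;
}

static cube concat2(const cube& a, const cube& b) { return join_slices(a, b); }

// ---------------------------------------------------------------- weights

struct Param {
  mat W; vec b;
  mat mW, vW; vec mb, vb;          // Adam state
  mat gW; vec gb;                  // gradient accumulators
  void init_opt() {
    mW.zeros(W.n_rows, W.n_cols); vW.zeros(W.n_rows, W.n_cols);
    mb.zeros(b.n_elem); vb.zeros(b.n_elem);
    gW.zeros(W.n_rows, W.n_cols); gb.zeros(b.n_elem);
  }
  void zero_grad() { gW.zeros(); gb.zeros(); }
  void adam_step(double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    mW = b1 * mW + (1 - b1) * gW; vW = b2 * vW + (1 - b2) * square(gW);
    mb = b1 * mb + (1 - b1) * gb; vb = b2 * vb + (1 - b2) * square(gb);
    const double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
    W -= lr * (mW / c1) / (sqrt(vW / c2) + eps);
    b -= lr * (mb / c1) / (sqrt(vb / c2) + eps);
  }
};

static std::vector<Param> weights_from_list(const List& wl) {
  std::vector<Param> ps(wl.size() / 2);
  for (size_t i = 0; i < ps.size(); ++i) {
    ps[i].W = Rcpp::as<mat>(wl[2 * i]);
    ps[i].b = Rcpp::as<vec>(wl[2 * i + 1]);
    ps[i].init_opt();
  }
  return ps;
}

static List weights_to_list(const std::vector<Param>& ps,
                            const Rcpp::CharacterVector& names) {
  List out(2 * ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    out[2 * i] = ps[i].W;
    out[2 * i + 1] = Rcpp::NumericVector(ps[i].b.begin(), ps[i].b.end());
  }
  out.attr("names") = names;
  return out;
}

// ------------------------------------------------------------- heatmap net
// Generic nested-U of depth D (D+1 levels): encoder column X[i][0]
// (i = level, spatial side halves per level), dense skip stages
//   X[i][j] = relu(conv3([X[i][0], ..., X[i][j-1], up(X[i+1][j-1])]))
// and a linear 1x1 output head on X[0][D].  The depth and channel widths
// are implied by the weight list (one conv per node, row-major in j).

struct HmNet {
  int D;
  std::vector<Param>* ps;
  // idx of node (i, j) in the weight vector
  int idx(int i, int j) const {
    int off = 0;
    for (int t = 0; t < j; ++t) off += D + 1 - t;
    return off + i;
  }
  Param& p(int i, int j) { return (*ps)[idx(i, j)]; }
  Param& pout() { return ps->back(); }
  int width(int i, int j) { return p(i, j).W.n_rows; }
};

struct HmCache {
  std::vector<mat> col;      // per node, im2col cache
  std::vector<cube> X;       // per node, post-activation
  std::vector<ucube> am;     // per level i >= 1, pool argmax
  mat inm_out;
  cube out;
};

static HmNet hm_net(std::vector<Param>& ps) {
  // n conv nodes = (D+1)(D+2)/2, plus the output head
  int nodes = (int)ps.size() - 1;
  int D = (int)std::lround((std::sqrt(8.0 * nodes + 1) - 3) / 2);
  return HmNet{D, &ps};
}

static void hm_forward_one(HmNet& net, const cube& in, HmCache& c) {
  const int D = net.D;
  const int nodes = (D + 1) * (D + 2) / 2;
  c.col.resize(nodes); c.X.resize(nodes); c.am.resize(D + 1);
  // encoder column
  for (int i = 0; i <= D; ++i) {
    const cube& src = (i == 0) ? in : c.X[net.idx(i - 1, 0)];
    cube x = (i == 0) ? in : pool2_fwd(src, c.am[i]);
    c.X[net.idx(i, 0)] =
      conv3_fwd(net.p(i, 0).W, net.p(i, 0).b, x, c.col[net.idx(i, 0)]);
    relu_inplace(c.X[net.idx(i, 0)]);
  }
  // dense skip stages
  for (int j = 1; j <= D; ++j) {
    for (int i = 0; i <= D - j; ++i) {
      cube cat = c.X[net.idx(i, 0)];
      for (int t = 1; t < j; ++t) cat = join_slices(cat, c.X[net.idx(i, t)]);
      cat = join_slices(cat, up2_fwd(c.X[net.idx(i + 1, j - 1)]));
      c.X[net.idx(i, j)] =
        conv3_fwd(net.p(i, j).W, net.p(i, j).b, cat, c.col[net.idx(i, j)]);
      relu_inplace(c.X[net.idx(i, j)]);
    }
  }
  c.out = conv1_fwd(net.pout().W, net.pout().b, c.X[net.idx(0, D)], c.inm_out);
}

// accumulates gradients into the net's params; dout = dL/d(out)
static void hm_backward_one(HmNet& net, const cube& in, HmCache& c,
                            const cube& dout) {
  const int D = net.D;
  const int nodes = (D + 1) * (D + 2) / 2;
  std::vector<cube> G(nodes);   // gradient accumulators per node
  auto add_grad = [&](int k, const cube& g) {
    if (G[k].n_elem == 0) G[k] = g; else G[k] += g;
  };
  mat dW; vec db; cube dtop;
  conv1_bwd(net.pout().W, c.inm_out, dout, dW, db, dtop);
  net.pout().gW += dW; net.pout().gb += db;
  add_grad(net.idx(0, D), dtop);
  // skip stages in reverse creation order
  for (int j = D; j >= 1; --j) {
    for (int i = D - j; i >= 0; --i) {
      const int k = net.idx(i, j);
      cube d = relu_bwd(c.X[k], G[k]);
      const int wi = net.width(i, 0), wup = net.width(i + 1, j - 1);
      cube dcat;
      conv3_bwd(net.p(i, j).W, c.col[k], d, j * wi + wup, dW, db, dcat, true);
      net.p(i, j).gW += dW; net.p(i, j).gb += db;
      for (int t = 0; t < j; ++t)
        add_grad(net.idx(i, t), dcat.slices(t * wi, (t + 1) * wi - 1));
      add_grad(net.idx(i + 1, j - 1),
               up2_bwd(dcat.slices(j * wi, j * wi + wup - 1)));
    }
  }
  // encoder column
  for (int i = D; i >= 0; --i) {
    const int k = net.idx(i, 0);
    cube d = relu_bwd(c.X[k], G[k]);
    const uword cin = (i == 0) ? in.n_slices : net.p(i - 1, 0).W.n_rows;
    cube dp;
    conv3_bwd(net.p(i, 0).W, c.col[k], d, cin, dW, db, dp, i > 0);
    net.p(i, 0).gW += dW; net.p(i, 0).gb += db;
    if (i > 0) {
      const cube& below = c.X[net.idx(i - 1, 0)];
      add_grad(net.idx(i - 1, 0),
               pool2_bwd(dp, c.am[i], below.n_rows, below.n_cols));
    }
  }
}

// x: (H, W, N) inputs in [0,1]; returns (H, W, 2, N)
// [[Rcpp::export]]
Rcpp::NumericVector hm_forward_cpp(List weights, Rcpp::NumericVector x) {
  std::vector<Param> ps = weights_from_list(weights);
  Rcpp::IntegerVector dim = x.attr("dim");
  const uword H = dim[0], W = dim[1], N = dim[2];
  cube xs(x.begin(), H, W, N, false);
  Rcpp::NumericVector out(H * W * 2 * N);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, 2, N);
  HmNet net = hm_net(ps);
  HmCache c;
  for (uword n = 0; n < N; ++n) {
    cube in(H, W, 1); in.slice(0) = xs.slice(n);
    hm_forward_one(net, in, c);
    std::copy(c.out.begin(), c.out.end(), out.begin() + n * H * W * 2);
  }
  return out;
}

// MSE loss and analytic weight gradient on one input; used by the
// finite-difference gradient tests.
// [[Rcpp::export]]
List hm_lossgrad_cpp(List weights, Rcpp::NumericVector x,
                     Rcpp::NumericVector y) {
  std::vector<Param> ps = weights_from_list(weights);
  Rcpp::IntegerVector dim = x.attr("dim");
  const uword H = dim[0], W = dim[1];
  cube in(x.begin(), H, W, 1);
  cube target(y.begin(), H, W, 2);
  HmNet net = hm_net(ps);
  HmCache c;
  hm_forward_one(net, in, c);
  cube diff = c.out - target;
  const double loss = accu(square(diff)) / diff.n_elem;
  cube dout = (2.0 / diff.n_elem) * diff;
  hm_backward_one(net, in, c, dout);
  List grads(2 * ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    grads[2 * i] = ps[i].gW;
    grads[2 * i + 1] = Rcpp::NumericVector(ps[i].gb.begin(), ps[i].gb.end());
  }
  grads.attr("names") = weights.names();
  return List::create(Named("loss") = loss, Named("grads") = grads);
}

// x: (H, W, N); y: (H, W, 2, N); orders: N x epochs (0-based sample order);
// lrs: per-epoch learning rates (length = epochs)
// [[Rcpp::export]]
List hm_train_cpp(List weights, Rcpp::NumericVector x, Rcpp::NumericVector y,
                  int epochs, int batch_size, Rcpp::NumericVector lrs,
                  Rcpp::IntegerMatrix orders) {
  std::vector<Param> ps = weights_from_list(weights);
  Rcpp::CharacterVector wnames = weights.names();
  Rcpp::IntegerVector dim = x.attr("dim");
  const uword H = dim[0], W = dim[1], N = dim[2];
  cube xs(x.begin(), H, W, N, false);
  const double* yp = y.begin();
  vec trace(epochs, fill::zeros);
  double best_loss = datum::inf;
  List best;
  double t_adam = 0;
  HmNet net = hm_net(ps);
  HmCache c;
  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0;
    uword done = 0;
    while (done < N) {
      const uword bs = std::min<uword>(batch_size, N - done);
      for (auto& p : ps) p.zero_grad();
      double bl = 0;
      for (uword k = 0; k < bs; ++k) {
        const uword n = orders(done + k, e);
        cube in(H, W, 1); in.slice(0) = xs.slice(n);
        hm_forward_one(net, in, c);
        cube target(const_cast<double*>(yp) + n * H * W * 2, H, W, 2, false);
        cube diff = c.out - target;
        bl += accu(square(diff)) / diff.n_elem;
        cube dout = (2.0 / (diff.n_elem * bs)) * diff;
        hm_backward_one(net, in, c, dout);
      }
      t_adam += 1;
      for (auto& p : ps) p.adam_step(lrs[e], t_adam);
      epoch_loss += bl;
      done += bs;
    }
    trace(e) = epoch_loss / N;  // mean per-sample loss
    if (trace(e) < best_loss) {
      best_loss = trace(e);
      best = weights_to_list(ps, wnames);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("best_weights") = best,
                      Named("final_weights") = weights_to_list(ps, wnames),
                      Named("trace") = Rcpp::NumericVector(trace.begin(), trace.end()));
}

// ------------------------------------------------------------ detector net

struct DetCache {
  mat col1, col2, col3, col4, col5, inm_head;
  cube X1, X2, X3, X4, X5, P1, P2, P3, P4, raw;
  ucube a1, a2, a3, a4;
};

static void det_forward_one(std::vector<Param>& ps, const cube& in, DetCache& c) {
  Param &w1 = ps[0], &w2 = ps[1], &w3 = ps[2], &w4 = ps[3], &w5 = ps[4],
        &wh = ps[5];
  c.X1 = conv3_fwd(w1.W, w1.b, in, c.col1); relu_inplace(c.X1);
  c.P1 = pool2_fwd(c.X1, c.a1);
  c.X2 = conv3_fwd(w2.W, w2.b, c.P1, c.col2); relu_inplace(c.X2);
  c.P2 = pool2_fwd(c.X2, c.a2);
  c.X3 = conv3_fwd(w3.W, w3.b, c.P2, c.col3); relu_inplace(c.X3);
  c.P3 = pool2_fwd(c.X3, c.a3);
  c.X4 = conv3_fwd(w4.W, w4.b, c.P3, c.col4); relu_inplace(c.X4);
  c.P4 = pool2_fwd(c.X4, c.a4);
  // extra grid-resolution conv: widens the receptive field past the
  // largest cyst without another pool
  c.X5 = conv3_fwd(w5.W, w5.b, c.P4, c.col5); relu_inplace(c.X5);
  c.raw = conv1_fwd(wh.W, wh.b, c.X5, c.inm_head);
}

static void det_backward_one(std::vector<Param>& ps, const cube& in,
                             DetCache& c, const cube& draw) {
  Param &w1 = ps[0], &w2 = ps[1], &w3 = ps[2], &w4 = ps[3], &w5 = ps[4],
        &wh = ps[5];
  mat dW; vec db; cube dX5;
  conv1_bwd(wh.W, c.inm_head, draw, dW, db, dX5);
  wh.gW += dW; wh.gb += db;
  cube d = relu_bwd(c.X5, dX5);
  cube dP4;
  conv3_bwd(w5.W, c.col5, d, w4.W.n_rows, dW, db, dP4, true);
  w5.gW += dW; w5.gb += db;
  d = pool2_bwd(dP4, c.a4, c.X4.n_rows, c.X4.n_cols);
  d = relu_bwd(c.X4, d);
  cube dP3;
  conv3_bwd(w4.W, c.col4, d, w3.W.n_rows, dW, db, dP3, true);
  w4.gW += dW; w4.gb += db;
  d = pool2_bwd(dP3, c.a3, c.X3.n_rows, c.X3.n_cols);
  d = relu_bwd(c.X3, d);
  cube dP2;
  conv3_bwd(w3.W, c.col3, d, w2.W.n_rows, dW, db, dP2, true);
  w3.gW += dW; w3.gb += db;
  d = pool2_bwd(dP2, c.a2, c.X2.n_rows, c.X2.n_cols);
  d = relu_bwd(c.X2, d);
  cube dP1;
  conv3_bwd(w2.W, c.col2, d, w1.W.n_rows, dW, db, dP1, true);
  w2.gW += dW; w2.gb += db;
  d = pool2_bwd(dP1, c.a1, c.X1.n_rows, c.X1.n_cols);
  d = relu_bwd(c.X1, d);
  cube dIn;
  conv3_bwd(w1.W, c.col1, d, in.n_slices, dW, db, dIn, false);
  w1.gW += dW; w1.gb += db;
}

static double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// GIoU loss (1 - IoU + (AC - U)/AC) and gradient w.r.t. predicted
// (cx, cy, w, h); truth fixed.
static double giou_loss_grad(const double p[4], const double g[4],
                             double grad[4]) {
  const double ax1 = p[0] - p[2] / 2, ax2 = p[0] + p[2] / 2;
  const double ay1 = p[1] - p[3] / 2, ay2 = p[1] + p[3] / 2;
  const double bx1 = g[0] - g[2] / 2, bx2 = g[0] + g[2] / 2;
  const double by1 = g[1] - g[3] / 2, by2 = g[1] + g[3] / 2;
  const double iw = std::max(0.0, std::min(ax2, bx2) - std::max(ax1, bx1));
  const double ih = std::max(0.0, std::min(ay2, by2) - std::max(ay1, by1));
  const double I = iw * ih;
  const double Aa = p[2] * p[3], Ab = g[2] * g[3];
  const double U = Aa + Ab - I;
  const double cw = std::max(ax2, bx2) - std::min(ax1, bx1);
  const double ch = std::max(ay2, by2) - std::min(ay1, by1);
  const double AC = cw * ch;
  const double iou = I / U;
  const double loss = 1.0 - iou + (AC - U) / AC;

  // partials of I, U, AC w.r.t. corners (subgradients at ties)
  double dI[4] = {0, 0, 0, 0};   // d/d{ax1, ax2, ay1, ay2}
  if (I > 0) {
    dI[0] = (ax1 > bx1 ? -ih : 0);
    dI[1] = (ax2 < bx2 ? ih : 0);
    dI[2] = (ay1 > by1 ? -iw : 0);
    dI[3] = (ay2 < by2 ? iw : 0);
  }
  // dAa: ax-extent = ax2 - ax1, area = (ax2-ax1)(ay2-ay1)
  double dAa[4] = {-(ay2 - ay1), (ay2 - ay1), -(ax2 - ax1), (ax2 - ax1)};
  double dAC[4] = {(ax1 < bx1 ? -ch : 0), (ax2 > bx2 ? ch : 0),
                   (ay1 < by1 ? -cw : 0), (ay2 > by2 ? cw : 0)};
  double dcorner[4];
  for (int i = 0; i < 4; ++i) {
    const double dU = dAa[i] - dI[i];
    const double diou = (dI[i] * U - I * dU) / (U * U);
    // (AC - U)/AC = 1 - U/AC
    const double dpen = -(dU * AC - U * dAC[i]) / (AC * AC);
    dcorner[i] = -diou + dpen;
  }
  // chain to (cx, cy, w, h)
  grad[0] = dcorner[0] + dcorner[1];
  grad[1] = dcorner[2] + dcorner[3];
  grad[2] = (-dcorner[0] + dcorner[1]) / 2;
  grad[3] = (-dcorner[2] + dcorner[3]) / 2;
  return loss;
}

// [[Rcpp::export]]
List giou_grad_cpp(Rcpp::NumericVector pred, Rcpp::NumericVector truth) {
  double grad[4];
  double p[4] = {pred[0], pred[1], pred[2], pred[3]};
  double g[4] = {truth[0], truth[1], truth[2], truth[3]};
  double loss = giou_loss_grad(p, g, grad);
  return List::create(Named("loss") = loss,
                      Named("grad") = Rcpp::NumericVector(grad, grad + 4));
}

// Loss of one image's raw grid output against its ground-truth boxes;
// fills draw (same shape as raw) with the gradient if requested.
// raw channels: 0 tx, 1 ty, 2 tw, 3 th, 4 conf logit, 5 class logit.
static double det_loss_one(const cube& raw, const mat& boxes, double stride,
                           double anchor, double lambda, cube* draw) {
  const uword S = raw.n_rows;
  // cell occupancy: one box per cell (row i = y cell, col j = x cell)
  imat occ(S, S, fill::ones); occ *= -1;
  for (uword r = 0; r < boxes.n_rows; ++r) {
    int j = std::min<int>(S - 1, std::max(0, (int)std::floor(boxes(r, 0) / stride)));
    int i = std::min<int>(S - 1, std::max(0, (int)std::floor(boxes(r, 1) / stride)));
    occ(i, j) = r;
  }
  double loss = 0;
  if (draw) draw->zeros(S, S, 6);
  for (uword i = 0; i < S; ++i) {
    for (uword j = 0; j < S; ++j) {
      const double conf = sigmoid(raw(i, j, 4));
      const double cc = std::min(1 - 1e-7, std::max(1e-7, conf));
      if (occ(i, j) >= 0) {
        const mat& tb = boxes;
        const uword r = occ(i, j);
        const double sx = sigmoid(raw(i, j, 0)), sy = sigmoid(raw(i, j, 1));
        double tw = std::min(3.0, std::max(-3.0, raw(i, j, 2)));
        double th = std::min(3.0, std::max(-3.0, raw(i, j, 3)));
        const double p[4] = {(j + sx) * stride, (i + sy) * stride,
                             anchor * std::exp(tw), anchor * std::exp(th)};
        const double g[4] = {tb(r, 0), tb(r, 1), tb(r, 2), tb(r, 3)};
        double gr[4];
        loss += giou_loss_grad(p, g, gr);
        // confidence BCE, target 1
        loss += -std::log(cc);
        // class BCE, target 1
        const double cls = sigmoid(raw(i, j, 5));
        const double cl = std::min(1 - 1e-7, std::max(1e-7, cls));
        loss += -std::log(cl);
        if (draw) {
          (*draw)(i, j, 0) = gr[0] * stride * sx * (1 - sx);
          (*draw)(i, j, 1) = gr[1] * stride * sy * (1 - sy);
          const bool wclamped = raw(i, j, 2) <= -3.0 || raw(i, j, 2) >= 3.0;
          const bool hclamped = raw(i, j, 3) <= -3.0 || raw(i, j, 3) >= 3.0;
          (*draw)(i, j, 2) = wclamped ? 0 : gr[2] * p[2];
          (*draw)(i, j, 3) = hclamped ? 0 : gr[3] * p[3];
          (*draw)(i, j, 4) = conf - 1;
          (*draw)(i, j, 5) = cls - 1;
        }
      } else {
        loss += lambda * (-std::log(std::min(1 - 1e-7,
                                             std::max(1e-7, 1 - conf))));
        if (draw) (*draw)(i, j, 4) = lambda * conf;
      }
    }
  }
  return loss;
}

// [[Rcpp::export]]
Rcpp::NumericVector det_batch_loss_cpp(Rcpp::NumericVector raw, List boxes,
                                       double stride, double anchor,
                                       double lambda) {
  Rcpp::IntegerVector dim = raw.attr("dim");
  const uword S = dim[0], N = dim[3];
  Rcpp::NumericVector out(N);
  for (uword n = 0; n < N; ++n) {
    cube r(const_cast<double*>(raw.begin()) + n * S * S * 6, S, S, 6, false);
    mat b = Rcpp::as<mat>(boxes[n]);
    out[n] = det_loss_one(r, b, stride, anchor, lambda, nullptr);
  }
  return out;
}

// x: (H, W, N) in [0,1]; returns raw grid outputs (S, S, 6, N)
// [[Rcpp::export]]
Rcpp::NumericVector det_forward_cpp(List weights, Rcpp::NumericVector x) {
  std::vector<Param> ps = weights_from_list(weights);
  Rcpp::IntegerVector dim = x.attr("dim");
  const uword H = dim[0], W = dim[1], N = dim[2];
  cube xs(x.begin(), H, W, N, false);
  DetCache c;
  const uword S = H / 16;
  Rcpp::NumericVector out(S * S * 6 * N);
  out.attr("dim") = Rcpp::IntegerVector::create(S, S, 6, N);
  for (uword n = 0; n < N; ++n) {
    cube in(H, W, 1); in.slice(0) = xs.slice(n);
    det_forward_one(ps, in, c);
    std::copy(c.raw.begin(), c.raw.end(), out.begin() + n * S * S * 6);
  }
  return out;
}

// [[Rcpp::export]]
List det_train_cpp(List weights, Rcpp::NumericVector x, List boxes,
                   double stride, double anchor, double lambda,
                   int epochs, int batch_size, Rcpp::NumericVector lrs,
                   Rcpp::IntegerMatrix orders) {
  std::vector<Param> ps = weights_from_list(weights);
  Rcpp::CharacterVector wnames = weights.names();
  Rcpp::IntegerVector dim = x.attr("dim");
  const uword H = dim[0], W = dim[1], N = dim[2];
  cube xs(x.begin(), H, W, N, false);
  std::vector<mat> bxs(N);
  for (uword n = 0; n < N; ++n) bxs[n] = Rcpp::as<mat>(boxes[n]);
  vec trace(epochs, fill::zeros);
  double best_loss = datum::inf;
  List best;
  double t_adam = 0;
  DetCache c;
  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0;
    uword done = 0;
    while (done < N) {
      const uword bs = std::min<uword>(batch_size, N - done);
      for (auto& p : ps) p.zero_grad();
      for (uword k = 0; k < bs; ++k) {
        const uword n = orders(done + k, e);
        cube in(H, W, 1); in.slice(0) = xs.slice(n);
        det_forward_one(ps, in, c);
        cube draw;
        epoch_loss += det_loss_one(c.raw, bxs[n], stride, anchor, lambda, &draw);
        draw /= (double)bs;
        det_backward_one(ps, in, c, draw);
      }
      t_adam += 1;
      for (auto& p : ps) p.adam_step(lrs[e], t_adam);
      done += bs;
    }
    trace(e) = epoch_loss / N;
    if (trace(e) < best_loss) {
      best_loss = trace(e);
      best = weights_to_list(ps, wnames);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("best_weights") = best,
                      Named("final_weights") = weights_to_list(ps, wnames),
                      Named("trace") = Rcpp::NumericVector(trace.begin(), trace.end()));
}
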