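// Compact feed-forward CNN engine: conv-conv-maxpool-flatten-dense-output.
// Convolutions are realised as im2col + GEMM; training is minibatch Adam on
// softmax cross-entropy with per-group freeze masks (conv1, conv2, dense,
// output). All randomness (initial weights, batch permutations) is supplied
// from R so that every run is a pure function of its inputs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::uword;
using arma::vec;

namespace {

struct Arch {
  int H, W, D;
  int k1h, k1w, s1, K1;
  int k2h, k2w, s2, K2;
  int ph, pw;
  int dense, ncls;
  // derived map sizes
  int c1h, c1w, c2h, c2w, p2h, p2w, flat;
};

Arch parse_arch(const IntegerVector& a) {
  if (a.size() != 15) stop("arch vector must have 15 entries");
  Arch s;
  s.H = a[0]; s.W = a[1]; s.D = a[2];
  s.k1h = a[3]; s.k1w = a[4]; s.s1 = a[5]; s.K1 = a[6];
  s.k2h = a[7]; s.k2w = a[8]; s.s2 = a[9]; s.K2 = a[10];
  s.ph = a[11]; s.pw = a[12];
  s.dense = a[13]; s.ncls = a[14];
  if ((s.H - s.k1h) % s.s1 || (s.W - s.k1w) % s.s1)
    stop("conv1 output size is not an integer");
  s.c1h = (s.H - s.k1h) / s.s1 + 1;
  s.c1w = (s.W - s.k1w) / s.s1 + 1;
  if ((s.c1h - s.k2h) % s.s2 || (s.c1w - s.k2w) % s.s2)
    stop("conv2 output size is not an integer");
  s.c2h = (s.c1h - s.k2h) / s.s2 + 1;
  s.c2w = (s.c1w - s.k2w) / s.s2 + 1;
  if (s.c2h % s.ph || s.c2w % s.pw)
    stop("max-pool does not tile the conv2 map exactly");
  s.p2h = s.c2h / s.ph;
  s.p2w = s.c2w / s.pw;
  s.flat = s.p2h * s.p2w * s.K2;
  if (s.c1h < 1 || s.c1w < 1 || s.c2h < 1 || s.c2w < 1)
    stop("non-positive activation map size");
  return s;
}

struct Net {
  mat W1, W2, Wd, Wo;
  vec b1, b2, bd, bo;
};

Net parse_params(const List& p, const Arch& a) {
  Net n;
  n.W1 = as<mat>(p["conv1_W"]); n.b1 = as<vec>(p["conv1_b"]);
  n.W2 = as<mat>(p["conv2_W"]); n.b2 = as<vec>(p["conv2_b"]);
  n.Wd = as<mat>(p["dense_W"]); n.bd = as<vec>(p["dense_b"]);
  n.Wo = as<mat>(p["out_W"]);   n.bo = as<vec>(p["out_b"]);
  if ((int)n.W1.n_rows != a.k1h * a.k1w * a.D || (int)n.W1.n_cols != a.K1)
    stop("conv1_W has wrong shape");
  if ((int)n.W2.n_rows != a.k2h * a.k2w * a.K1 || (int)n.W2.n_cols != a.K2)
    stop("conv2_W has wrong shape");
  if ((int)n.Wd.n_rows != a.flat || (int)n.Wd.n_cols != a.dense)
    stop("dense_W has wrong shape");
  if ((int)n.Wo.n_rows != a.dense || (int)n.Wo.n_cols != a.ncls)
    stop("out_W has wrong shape");
  return n;
}

List wrap_params(const Net& n) {
  return List::create(
    Named("conv1_W") = n.W1, Named("conv1_b") = n.b1,
    Named("conv2_W") = n.W2, Named("conv2_b") = n.b2,
    Named("dense_W") = n.Wd, Named("dense_b") = n.bd,
    Named("out_W") = n.Wo,   Named("out_b") = n.bo);
}

// Patch matrix for one example: row = output position (i + j*out_h),
// column = kernel offset (di + dj*kh + dd*kh*kw).
void im2col_into(mat& M, uword row0, const cube& x,
                 int kh, int kw, int stride, int out_h, int out_w) {
  for (int dd = 0; dd < (int)x.n_slices; ++dd)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const uword c = di + dj * kh + (uword)dd * kh * kw;
        for (int j = 0; j < out_w; ++j)
          for (int i = 0; i < out_h; ++i)
            M(row0 + i + (uword)j * out_h, c) =
              x(i * stride + di, j * stride + dj, dd);
      }
}

// Adjoint of im2col: scatter patch-gradients back onto the input map.
void col2im_add(cube& g, const mat& dM, uword row0,
                int kh, int kw, int stride, int out_h, int out_w) {
  for (int dd = 0; dd < (int)g.n_slices; ++dd)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const uword c = di + dj * kh + (uword)dd * kh * kw;
        for (int j = 0; j < out_w; ++j)
          for (int i = 0; i < out_h; ++i)
            g(i * stride + di, j * stride + dj, dd) +=
              dM(row0 + i + (uword)j * out_h, c);
      }
}

// Cached forward pass over a batch (examples indexed into the full array).
struct Fwd {
  mat IC1, Z1, A1;   // (B*c1hw) x ...
  mat IC2, Z2, A2;   // (B*c2hw) x ...
  mat P;             // B x flat
  arma::umat argrow; // B x flat: row into A2 of the max element
  arma::uvec argk;   // flat: channel of each flat position (fixed layout)
  mat Zd, Ad, Zo, probs; // B x ...
};

void forward_batch(const Arch& a, const Net& n, const double* xptr,
                   const std::vector<int>& idx, Fwd& f) {
  const int B = idx.size();
  const uword c1hw = (uword)a.c1h * a.c1w, c2hw = (uword)a.c2h * a.c2w;
  const uword exsz = (uword)a.H * a.W * a.D;
  f.IC1.set_size(B * c1hw, (uword)a.k1h * a.k1w * a.D);
  for (int b = 0; b < B; ++b) {
    const cube x(const_cast<double*>(xptr) + (uword)idx[b] * exsz,
                 a.H, a.W, a.D, false, true);
    im2col_into(f.IC1, b * c1hw, x, a.k1h, a.k1w, a.s1, a.c1h, a.c1w);
  }
  f.Z1 = f.IC1 * n.W1;
  f.Z1.each_row() += n.b1.t();
  f.A1 = arma::clamp(f.Z1, 0.0, arma::datum::inf);

  f.IC2.set_size(B * c2hw, (uword)a.k2h * a.k2w * a.K1);
  for (int b = 0; b < B; ++b) {
    // column k of the example's A1 block is slice k of its conv1 map;
    // copy the block out to get a contiguous (c1h, c1w, K1) cube
    mat blk = f.A1.rows(b * c1hw, (b + 1) * c1hw - 1); // c1hw x K1
    const cube xc(blk.memptr(), a.c1h, a.c1w, a.K1, false, true);
    im2col_into(f.IC2, b * c2hw, xc, a.k2h, a.k2w, a.s2, a.c2h, a.c2w);
  }
  f.Z2 = f.IC2 * n.W2;
  f.Z2.each_row() += n.b2.t();
  f.A2 = arma::clamp(f.Z2, 0.0, arma::datum::inf);

  // max-pool: pooled position (pi, pj, k) -> flat index pi + pj*p2h + k*p2h*p2w
  f.P.set_size(B, a.flat);
  f.argrow.set_size(B, a.flat);
  f.argk.set_size(a.flat);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < a.K2; ++k)
      for (int pj = 0; pj < a.p2w; ++pj)
        for (int pi = 0; pi < a.p2h; ++pi) {
          double best = -arma::datum::inf;
          uword bestrow = 0;
          for (int oj = 0; oj < a.pw; ++oj)
            for (int oi = 0; oi < a.ph; ++oi) {
              const int i = pi * a.ph + oi, j = pj * a.pw + oj;
              const uword r = b * c2hw + i + (uword)j * a.c2h;
              const double v = f.A2(r, k);
              if (v > best) { best = v; bestrow = r; }
            }
          const uword fl = pi + (uword)pj * a.p2h + (uword)k * a.p2h * a.p2w;
          f.P(b, fl) = best;
          f.argrow(b, fl) = bestrow;
          f.argk(fl) = k;
        }
  }

  f.Zd = f.P * n.Wd;
  f.Zd.each_row() += n.bd.t();
  f.Ad = arma::clamp(f.Zd, 0.0, arma::datum::inf);
  f.Zo = f.Ad * n.Wo;
  f.Zo.each_row() += n.bo.t();
  mat sh = f.Zo.each_col() - arma::max(f.Zo, 1);
  f.probs = arma::exp(sh);
  f.probs.each_col() /= arma::sum(f.probs, 1);
}

void backward_batch(const Arch& a, const Net& n, const Fwd& f,
                    const std::vector<int>& yb, Net& g) {
  const int B = yb.size();
  const uword c1hw = (uword)a.c1h * a.c1w, c2hw = (uword)a.c2h * a.c2w;
  mat dZo = f.probs;
  for (int b = 0; b < B; ++b) dZo(b, yb[b]) -= 1.0;
  dZo /= (double)B;

  g.Wo = f.Ad.t() * dZo;
  g.bo = arma::sum(dZo, 0).t();
  mat dAd = dZo * n.Wo.t();
  mat dZd = dAd % (f.Zd > 0);
  g.Wd = f.P.t() * dZd;
  g.bd = arma::sum(dZd, 0).t();
  mat dP = dZd * n.Wd.t();

  mat dA2(f.A2.n_rows, f.A2.n_cols, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int fl = 0; fl < a.flat; ++fl)
      dA2(f.argrow(b, fl), f.argk(fl)) += dP(b, fl);

  mat dZ2 = dA2 % (f.Z2 > 0);
  g.W2 = f.IC2.t() * dZ2;
  g.b2 = arma::sum(dZ2, 0).t();
  mat dIC2 = dZ2 * n.W2.t();

  mat dA1(f.A1.n_rows, f.A1.n_cols, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    cube gx(a.c1h, a.c1w, a.K1, arma::fill::zeros);
    col2im_add(gx, dIC2, b * c2hw, a.k2h, a.k2w, a.s2, a.c2h, a.c2w);
    for (int k = 0; k < a.K1; ++k)
      dA1.submat(b * c1hw, k, (b + 1) * c1hw - 1, k) =
        arma::vectorise(gx.slice(k));
  }
  mat dZ1 = dA1 % (f.Z1 > 0);
  g.W1 = f.IC1.t() * dZ1;
  g.b1 = arma::sum(dZ1, 0).t();
}

double batch_loss(const Fwd& f, const std::vector<int>& yb) {
  double loss = 0.0;
  for (size_t b = 0; b < yb.size(); ++b)
    loss -= std::log(std::max(f.probs(b, yb[b]), 1e-300));
  return loss / yb.size();
}

struct Adam {
  Net m, v;
  long t = 0;
  void init(const Net& n) {
    m.W1.zeros(arma::size(n.W1)); v.W1.zeros(arma::size(n.W1));
    m.b1.zeros(arma::size(n.b1)); v.b1.zeros(arma::size(n.b1));
    m.W2.zeros(arma::size(n.W2)); v.W2.zeros(arma::size(n.W2));
    m.b2.zeros(arma::size(n.b2)); v.b2.zeros(arma::size(n.b2));
    m.Wd.zeros(arma::size(n.Wd)); v.Wd.zeros(arma::size(n.Wd));
    m.bd.zeros(arma::size(n.bd)); v.bd.zeros(arma::size(n.bd));
    m.Wo.zeros(arma::size(n.Wo)); v.Wo.zeros(arma::size(n.Wo));
    m.bo.zeros(arma::size(n.bo)); v.bo.zeros(arma::size(n.bo));
  }
  template <typename T>
  void step1(T& w, const T& gw, T& mw, T& vw, double lr,
             double b1, double b2, double eps, double bc1, double bc2) {
    mw = b1 * mw + (1.0 - b1) * gw;
    vw = b2 * vw + (1.0 - b2) * (gw % gw);
    w -= lr * (mw / bc1) / (arma::sqrt(vw / bc2) + eps);
  }
  void step(Net& n, const Net& g, const std::vector<bool>& trainable,
            double lr, double b1, double b2, double eps) {
    ++t;
    const double bc1 = 1.0 - std::pow(b1, (double)t);
    const double bc2 = 1.0 - std::pow(b2, (double)t);
    if (trainable[0]) {
      step1(n.W1, g.W1, m.W1, v.W1, lr, b1, b2, eps, bc1, bc2);
      step1(n.b1, g.b1, m.b1, v.b1, lr, b1, b2, eps, bc1, bc2);
    }
    if (trainable[1]) {
      step1(n.W2, g.W2, m.W2, v.W2, lr, b1, b2, eps, bc1, bc2);
      step1(n.b2, g.b2, m.b2, v.b2, lr, b1, b2, eps, bc1, bc2);
    }
    if (trainable[2]) {
      step1(n.Wd, g.Wd, m.Wd, v.Wd, lr, b1, b2, eps, bc1, bc2);
      step1(n.bd, g.bd, m.bd, v.bd, lr, b1, b2, eps, bc1, bc2);
    }
    if (trainable[3]) {
      step1(n.Wo, g.Wo, m.Wo, v.Wo, lr, b1, b2, eps, bc1, bc2);
      step1(n.bo, g.bo, m.bo, v.bo, lr, b1, b2, eps, bc1, bc2);
    }
  }
};

IntegerVector predict_labels(const Arch& a, const Net& n, const double* xptr,
                             int nx, mat* probs_out = nullptr) {
  IntegerVector out(nx);
  const int chunk = 256;
  mat probs;
  if (probs_out) probs_out->set_size(nx, a.ncls);
  Fwd f;
  for (int s = 0; s < nx; s += chunk) {
    const int e = std::min(nx, s + chunk);
    std::vector<int> idx(e - s);
    for (int i = s; i < e; ++i) idx[i - s] = i;
    forward_batch(a, n, xptr, idx, f);
    for (int i = s; i < e; ++i) {
      out[i] = (int)f.probs.row(i - s).index_max(); // first max wins ties
      if (probs_out) probs_out->row(i) = f.probs.row(i - s);
    }
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cnn_forward_cpp(List params, IntegerVector arch,
                              NumericVector x, int n_examples) {
  const Arch a = parse_arch(arch);
  const Net n = parse_params(params, a);
  if ((int)x.size() != n_examples * a.H * a.W * a.D)
    stop("input array size does not match arch");
  mat probs;
  predict_labels(a, n, x.begin(), n_examples, &probs);
  return wrap(probs);
}

// [[Rcpp::export]]
List cnn_loss_grad_cpp(List params, IntegerVector arch,
                       NumericVector x, IntegerVector y) {
  const Arch a = parse_arch(arch);
  const Net n = parse_params(params, a);
  const int B = y.size();
  if ((int)x.size() != B * a.H * a.W * a.D) stop("input size mismatch");
  std::vector<int> idx(B), yb(B);
  for (int i = 0; i < B; ++i) { idx[i] = i; yb[i] = y[i]; }
  Fwd f;
  forward_batch(a, n, x.begin(), idx, f);
  Net g;
  backward_batch(a, n, f, yb, g);
  return List::create(Named("loss") = batch_loss(f, yb),
                      Named("grads") = wrap_params(g));
}

// [[Rcpp::export]]
List cnn_fit_cpp(List params, IntegerVector arch,
                 NumericVector xtr, IntegerVector ytr,
                 NumericVector xte, IntegerVector yte,
                 int epochs, IntegerVector record_at,
                 double lr, int batch_size, IntegerMatrix perms,
                 LogicalVector trainable,
                 double beta1, double beta2, double eps) {
  const Arch a = parse_arch(arch);
  Net n = parse_params(params, a);
  const int ntr = ytr.size(), nte = yte.size();
  if ((int)xtr.size() != ntr * a.H * a.W * a.D) stop("training array mismatch");
  if (nte > 0 && (int)xte.size() != nte * a.H * a.W * a.D)
    stop("test array mismatch");
  if (epochs > 0 && (perms.nrow() != ntr || perms.ncol() < epochs))
    stop("perms must be ntr x epochs");
  std::vector<bool> tr(4);
  for (int i = 0; i < 4; ++i) tr[i] = trainable[i];

  Adam opt;
  opt.init(n);
  vec losses(std::max(epochs, 0), arma::fill::zeros);
  const int nrec = record_at.size();
  vec accs(nrec); accs.fill(NA_REAL);
  IntegerMatrix preds(nte, nrec);

  auto eval_at = [&](int slot) {
    if (nte == 0) return;
    IntegerVector ph = predict_labels(a, n, xte.begin(), nte);
    int ok = 0;
    for (int i = 0; i < nte; ++i) {
      preds(i, slot) = ph[i];
      if (ph[i] == yte[i]) ++ok;
    }
    accs[slot] = 100.0 * ok / nte;
  };
  for (int r = 0; r < nrec; ++r) if (record_at[r] == 0) eval_at(r);

  Fwd f;
  Net g;
  for (int ep = 0; ep < epochs; ++ep) {
    double eploss = 0.0;
    int nb = 0;
    for (int s = 0; s < ntr; s += batch_size) {
      const int e = std::min(ntr, s + batch_size);
      std::vector<int> idx(e - s), yb(e - s);
      for (int i = s; i < e; ++i) {
        idx[i - s] = perms(i, ep);
        yb[i - s] = ytr[perms(i, ep)];
      }
      forward_batch(a, n, xtr.begin(), idx, f);
      eploss += batch_loss(f, yb);
      ++nb;
      backward_batch(a, n, f, yb, g);
      opt.step(n, g, tr, lr, beta1, beta2, eps);
    }
    losses[ep] = eploss / std::max(nb, 1);
    for (int r = 0; r < nrec; ++r) if (record_at[r] == ep + 1) eval_at(r);
  }

  return List::create(Named("params") = wrap_params(n),
                      Named("loss") = losses,
                      Named("test_acc") = accs,
                      Named("test_pred") = preds);
}
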