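// Compiled training/inference backend for the residual 1-D convolutional
// classifier. Mirrors the reference R implementation (R/nn-layers.R,
// R/model.R) layer for layer; the two are cross-checked in the test suite.
//
// Tensor layout: batches are N x T x C cubes (N fastest), so the memory of
// a cube equals a (N*T) x C matrix whose column c is feature map c. A time
// shift by d samples is then a row shift by d*N, which lets the stride-1
// kernel-3 convolution run as three shifted-row GEMMs without an im2col
// buffer. Arithmetic is single precision (the usual choice for this kind
// of network); parameters cross the R boundary in double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace arma;

static const float BN_EPS = 1e-5f;
static const float INV_SQRT_2PI = 0.3989422804014327f;

struct Params {
  fmat W1;            // C x F1 (pointwise)
  fvec g1, be1;       // F1
  fmat W2;            // (k*F1) x C
  fvec g2, be2;       // C
  fmat W3;            // (k*C) x F3
  fvec b3;            // F3
  fmat Wf1, Wf2, Wf3;
  fvec bf1, bf2, bf3;
};

static fmat getm(const Rcpp::List& p, const char* nm) {
  return conv_to<fmat>::from(Rcpp::as<mat>(p[nm]));
}
static fvec getv(const Rcpp::List& p, const char* nm) {
  return conv_to<fvec>::from(Rcpp::as<vec>(p[nm]));
}

static Params params_from_list(const Rcpp::List& p) {
  Params q;
  q.W1 = getm(p, "W1"); q.g1 = getv(p, "g1"); q.be1 = getv(p, "be1");
  q.W2 = getm(p, "W2"); q.g2 = getv(p, "g2"); q.be2 = getv(p, "be2");
  q.W3 = getm(p, "W3"); q.b3 = getv(p, "b3");
  q.Wf1 = getm(p, "Wf1"); q.bf1 = getv(p, "bf1");
  q.Wf2 = getm(p, "Wf2"); q.bf2 = getv(p, "bf2");
  q.Wf3 = getm(p, "Wf3"); q.bf3 = getv(p, "bf3");
  return q;
}

static Rcpp::List params_to_list(const Params& q) {
  auto M = [](const fmat& x) { return conv_to<mat>::from(x); };
  auto V = [](const fvec& x) { return conv_to<vec>::from(x); };
  return Rcpp::List::create(
    Rcpp::Named("W1") = M(q.W1), Rcpp::Named("g1") = V(q.g1),
    Rcpp::Named("be1") = V(q.be1),
    Rcpp::Named("W2") = M(q.W2), Rcpp::Named("g2") = V(q.g2),
    Rcpp::Named("be2") = V(q.be2),
    Rcpp::Named("W3") = M(q.W3), Rcpp::Named("b3") = V(q.b3),
    Rcpp::Named("Wf1") = M(q.Wf1), Rcpp::Named("bf1") = V(q.bf1),
    Rcpp::Named("Wf2") = M(q.Wf2), Rcpp::Named("bf2") = V(q.bf2),
    Rcpp::Named("Wf3") = M(q.Wf3), Rcpp::Named("bf3") = V(q.bf3));
}

struct BNState { fvec rm1, rv1, rm2, rv2; };

static BNState state_from_list(const Rcpp::List& s) {
  BNState t;
  t.rm1 = getv(s, "rm1"); t.rv1 = getv(s, "rv1");
  t.rm2 = getv(s, "rm2"); t.rv2 = getv(s, "rv2");
  return t;
}

static Rcpp::List state_to_list(const BNState& t) {
  auto V = [](const fvec& x) { return conv_to<vec>::from(x); };
  return Rcpp::List::create(
    Rcpp::Named("rm1") = V(t.rm1), Rcpp::Named("rv1") = V(t.rv1),
    Rcpp::Named("rm2") = V(t.rm2), Rcpp::Named("rv2") = V(t.rv2));
}

static int out_len(int T, int k, int stride, int& pad_left) {
  int t_out = (T + stride - 1) / stride;
  int pad_total = std::max((t_out - 1) * stride + k - T, 0);
  pad_left = pad_total / 2;
  return t_out;
}

// stride-1 "same" convolution as k shifted-row GEMMs.
// X: (N*T) x Cin, W: (k*Cin) x Cout with rows ordered (cin, j) -> cin*k+j.
static fmat conv_s1(const fmat& X, const fmat& W, int N, int T, int k,
                    int pad_left) {
  int Cin = X.n_cols, Cout = W.n_cols;
  fmat Y(X.n_rows, Cout, fill::zeros);
  for (int j = 0; j < k; ++j) {
    int d = j - pad_left;                 // source time = t + d
    int t_lo = std::max(0, -d), t_hi = std::min(T, T - d);
    if (t_lo >= t_hi) continue;
    fmat Wj(Cin, Cout);
    for (int c = 0; c < Cin; ++c) Wj.row(c) = W.row(c * k + j);
    Y.rows(static_cast<uword>(t_lo) * N,
           static_cast<uword>(t_hi) * N - 1) +=
      X.rows(static_cast<uword>(t_lo + d) * N,
             static_cast<uword>(t_hi + d) * N - 1) * Wj;
  }
  return Y;
}

// gradients of conv_s1: dW (optional) and dX accumulated.
static void conv_s1_bwd(const fmat& X, const fmat& W, const fmat& dY,
                        int N, int T, int k, int pad_left,
                        fmat* dW, fmat* dX) {
  int Cin = X.n_cols, Cout = W.n_cols;
  for (int j = 0; j < k; ++j) {
    int d = j - pad_left;
    int t_lo = std::max(0, -d), t_hi = std::min(T, T - d);
    if (t_lo >= t_hi) continue;
    uword ya = static_cast<uword>(t_lo) * N, yb = static_cast<uword>(t_hi) * N - 1;
    uword xa = static_cast<uword>(t_lo + d) * N, xb = static_cast<uword>(t_hi + d) * N - 1;
    if (dW) {
      fmat dWj = X.rows(xa, xb).t() * dY.rows(ya, yb);   // Cin x Cout
      for (int c = 0; c < Cin; ++c) dW->row(c * k + j) = dWj.row(c);
    }
    if (dX) {
      fmat Wj(Cin, Cout);
      for (int c = 0; c < Cin; ++c) Wj.row(c) = W.row(c * k + j);
      dX->rows(xa, xb) += dY.rows(ya, yb) * Wj.t();
    }
  }
}

// im2col gather for the strided head convolution (small column count).
static fmat gather(const fmat& Xm, int N, int T, int k, int stride,
                   int pad_left, int t_out) {
  int Cin = Xm.n_cols;
  fmat out(static_cast<uword>(N) * t_out, static_cast<uword>(k) * Cin,
           fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const float* src = Xm.colptr(c);
    for (int j = 0; j < k; ++j) {
      float* dst = out.colptr(static_cast<uword>(c) * k + j);
      for (int t = 0; t < t_out; ++t) {
        int s = t * stride + j - pad_left;
        if (s >= 0 && s < T)
          std::memcpy(dst + static_cast<size_t>(t) * N,
                      src + static_cast<size_t>(s) * N,
                      sizeof(float) * N);
      }
    }
  }
  return out;
}

static void scatter_add(fmat& dXm, const fmat& dXcol, int N, int T, int k,
                        int stride, int pad_left, int t_out) {
  int Cin = dXm.n_cols;
  for (int c = 0; c < Cin; ++c) {
    float* dst = dXm.colptr(c);
    for (int j = 0; j < k; ++j) {
      const float* src = dXcol.colptr(static_cast<uword>(c) * k + j);
      for (int t = 0; t < t_out; ++t) {
        int s = t * stride + j - pad_left;
        if (s >= 0 && s < T) {
          float* d = dst + static_cast<size_t>(s) * N;
          const float* q = src + static_cast<size_t>(t) * N;
          for (int n = 0; n < N; ++n) d[n] += q[n];
        }
      }
    }
  }
}

// GELU x * Phi(x). The normal CDF is evaluated from a polynomial exp and
// the Abramowitz-Stegun 7.1.26 rational erf form (absolute error ~1.5e-7,
// far below the single-precision training noise floor); the shared
// exponential exp(-x^2/2) is cached so the backward derivative
// Phi(x) + x * pdf(x) needs no further transcendentals.

static inline float fast_exp(float x) {
  if (x < -80.f) return 0.f;
  if (x > 80.f) x = 80.f;
  float z = x * 1.44269504089f;
  int ki = (int)(z + (z >= 0.f ? 0.5f : -0.5f));
  float r = x - (float)ki * 0.69314718056f;
  float p = 1.f + r * (1.f + r * (0.5f + r * (0.1666666667f +
            r * (0.0416666667f + r * (0.0083333333f + r * 0.0013888889f)))));
  union { int32_t i; float f; } u;
  u.i = (ki + 127) << 23;
  return p * u.f;
}

static inline float phi_from_exp(float x, float E) {
  // E = exp(-x^2/2) = exp(-z^2) with z = |x|/sqrt(2)
  float z = std::fabs(x) * 0.70710678119f;
  float t = 1.f / (1.f + 0.3275911f * z);
  float y = t * (0.254829592f + t * (-0.284496736f + t * (1.421413741f +
            t * (-1.453152027f + t * 1.061405429f))));
  float phi_pos = 1.f - 0.5f * y * E;
  return x >= 0.f ? phi_pos : 1.f - phi_pos;
}

// fused forward: phi = Phi(x), a = x * phi, E = exp(-x^2/2)
static void gelu_fwd(const fmat& x, fmat& phi, fmat& a, fmat& E) {
  uword n = x.n_elem;
  phi.set_size(x.n_rows, x.n_cols);
  a.set_size(x.n_rows, x.n_cols);
  E.set_size(x.n_rows, x.n_cols);
  const float* p = x.memptr();
  float* f = phi.memptr(); float* q = a.memptr(); float* e = E.memptr();
  for (uword i = 0; i < n; ++i) {
    float xe = fast_exp(-0.5f * p[i] * p[i]);
    float ph = phi_from_exp(p[i], xe);
    e[i] = xe; f[i] = ph; q[i] = p[i] * ph;
  }
}

static void gelu_grad_inplace(fmat& d, const fmat& pre, const fmat& phi,
                              const fmat& E) {
  const float* p = pre.memptr(); const float* f = phi.memptr();
  const float* e = E.memptr();
  float* q = d.memptr();
  uword n = d.n_elem;
  for (uword i = 0; i < n; ++i)
    q[i] *= f[i] + p[i] * INV_SQRT_2PI * e[i];
}

struct FwdCache {
  fmat M0;
  fmat Xcol3;
  fmat pre1, phi1, a1, E1;
  fmat pre2, phi2, E2;
  fmat radd, phi3, a3, E3;
  fmat pre3h, phi4, E4;
  fmat xhat1, xhat2;
  fvec inv1, inv2;
  fmat flat, d1y, pre4, phi5, E5, d2y, pre5, phi6, E6, d3y;
  fmat mask1, mask2, mask3;
  fmat logits;
  int N, T, C, t_out3, pad3;
};

static void bn_fwd(fmat&& X, const fvec& g, const fvec& be, bool training,
                   fvec& rm, fvec& rv, float momentum, fmat& xhat,
                   fvec& inv, fmat& out) {
  uword m = X.n_rows, Cf = X.n_cols;
  fvec mu(Cf), v(Cf);
  if (training) {
    for (uword c = 0; c < Cf; ++c) {
      const float* x = X.colptr(c);
      double s = 0, s2 = 0;
      for (uword i = 0; i < m; ++i) { s += x[i]; s2 += double(x[i]) * x[i]; }
      mu[c] = s / m;
      v[c] = std::max(s2 / m - double(mu[c]) * mu[c], 0.0);
    }
    rm = momentum * rm + (1 - momentum) * mu;
    rv = momentum * rv + (1 - momentum) * v;
  } else {
    mu = rm; v = rv;
  }
  inv = 1.0f / sqrt(v + BN_EPS);
  xhat.set_size(m, Cf);
  out.set_size(m, Cf);
  for (uword c = 0; c < Cf; ++c) {
    const float* x = X.colptr(c);
    float* xh = xhat.colptr(c);
    float* o = out.colptr(c);
    float mc = mu[c], ic = inv[c], gc = g[c], bc = be[c];
    for (uword i = 0; i < m; ++i) {
      float z = (x[i] - mc) * ic;
      xh[i] = z;
      o[i] = z * gc + bc;
    }
  }
}

static fmat bn_bwd(fmat&& dY, const fmat& xhat, const fvec& inv,
                   const fvec& g, bool training, fvec& dg, fvec& dbe) {
  if (!training) {
    dY.each_row() %= (g % inv).t();
    return std::move(dY);
  }
  float m = static_cast<float>(dY.n_rows);
  dg = sum(dY % xhat, 0).t();
  dbe = sum(dY, 0).t();
  dY.each_row() %= g.t();                 // now dxhat
  frowvec s1 = sum(dY, 0);
  frowvec s2 = sum(dY % xhat, 0);
  fmat t2 = xhat;
  t2.each_row() %= (s2 / m);
  dY -= t2;
  dY.each_row() -= s1 / m;
  dY.each_row() %= inv.t();
  return std::move(dY);
}

static void forward(const Params& p, BNState& st, const fmat& M0,
                    int N, int T, bool training, float dropout,
                    std::mt19937* rng, FwdCache& f) {
  int C = M0.n_cols;
  f.N = N; f.T = T; f.C = C;
  f.M0 = M0;
  int F1 = p.W1.n_cols;
  int k2 = p.W2.n_rows / F1;
  int F3 = p.W3.n_cols;
  int k3 = p.W3.n_rows / C;
  bn_fwd(f.M0 * p.W1, p.g1, p.be1, training, st.rm1, st.rv1, 0.99f,
         f.xhat1, f.inv1, f.pre1);
  gelu_fwd(f.pre1, f.phi1, f.a1, f.E1);
  int padl2; out_len(T, k2, 1, padl2);
  bn_fwd(conv_s1(f.a1, p.W2, N, T, k2, padl2), p.g2, p.be2, training,
         st.rm2, st.rv2, 0.99f, f.xhat2, f.inv2, f.pre2);
  fmat a2;
  gelu_fwd(f.pre2, f.phi2, a2, f.E2);
  f.radd = a2 + f.M0;
  gelu_fwd(f.radd, f.phi3, f.a3, f.E3);
  f.t_out3 = out_len(T, k3, 2, f.pad3);
  f.Xcol3 = gather(f.a3, N, T, k3, 2, f.pad3, f.t_out3);
  f.pre3h = f.Xcol3 * p.W3;
  f.pre3h.each_row() += p.b3.t();
  fmat a4;
  gelu_fwd(f.pre3h, f.phi4, a4, f.E4);
  f.flat = fmat(a4.memptr(), N, static_cast<uword>(f.t_out3) * F3);
  auto make_mask = [&](uword nr, uword nc) {
    fmat msk(nr, nc);
    std::uniform_real_distribution<double> u(0.0, 1.0);
    float keep = 1.0f - dropout;
    for (uword i = 0; i < msk.n_elem; ++i)
      msk(i) = (u(*rng) >= dropout) ? 1.0f / keep : 0.0f;
    return msk;
  };
  bool drop = training && dropout > 0 && rng != nullptr;
  if (drop) { f.mask1 = make_mask(f.flat.n_rows, f.flat.n_cols);
    f.d1y = f.flat % f.mask1; } else { f.mask1.reset(); f.d1y = f.flat; }
  f.pre4 = f.d1y * p.Wf1; f.pre4.each_row() += p.bf1.t();
  fmat a5;
  gelu_fwd(f.pre4, f.phi5, a5, f.E5);
  if (drop) { f.mask2 = make_mask(a5.n_rows, a5.n_cols);
    f.d2y = a5 % f.mask2; } else { f.mask2.reset(); f.d2y = a5; }
  f.pre5 = f.d2y * p.Wf2; f.pre5.each_row() += p.bf2.t();
  fmat a6;
  gelu_fwd(f.pre5, f.phi6, a6, f.E6);
  if (drop) { f.mask3 = make_mask(a6.n_rows, a6.n_cols);
    f.d3y = a6 % f.mask3; } else { f.mask3.reset(); f.d3y = a6; }
  f.logits = f.d3y * p.Wf3; f.logits.each_row() += p.bf3.t();
}

// softmax cross-entropy in double for the reduction.
static double xent(const fmat& logits, const Rcpp::IntegerVector& y,
                   bool mean_reduce, fmat& dlogits) {
  fmat z = logits;
  z.each_col() -= max(logits, 1);
  fmat e = exp(z);
  fmat p = e;
  p.each_col() /= sum(e, 1);
  double loss = 0;
  int N = logits.n_rows;
  for (int i = 0; i < N; ++i)
    loss += -std::log(std::max(static_cast<double>(p(i, y[i] - 1)), 1e-30));
  dlogits = p;
  for (int i = 0; i < N; ++i) dlogits(i, y[i] - 1) -= 1.0f;
  if (mean_reduce) { loss /= N; dlogits /= static_cast<float>(N); }
  return loss;
}

struct Grads {
  fmat W1, W2, W3, Wf1, Wf2, Wf3;
  fvec g1, be1, g2, be2, b3, bf1, bf2, bf3;
};

static void backward(const Params& p, FwdCache& f, const fmat& dlogits,
                     bool training, bool need_param, bool need_dX,
                     Grads& g, fmat& dX) {
  fmat d = dlogits;
  if (need_param) { g.Wf3 = f.d3y.t() * d; g.bf3 = sum(d, 0).t(); }
  d = d * p.Wf3.t();
  if (!f.mask3.is_empty()) d %= f.mask3;
  gelu_grad_inplace(d, f.pre5, f.phi6, f.E6);
  if (need_param) { g.Wf2 = f.d2y.t() * d; g.bf2 = sum(d, 0).t(); }
  d = d * p.Wf2.t();
  if (!f.mask2.is_empty()) d %= f.mask2;
  gelu_grad_inplace(d, f.pre4, f.phi5, f.E5);
  if (need_param) { g.Wf1 = f.d1y.t() * d; g.bf1 = sum(d, 0).t(); }
  d = d * p.Wf1.t();
  if (!f.mask1.is_empty()) d %= f.mask1;
  int F3 = p.W3.n_cols;
  fmat d4(d.memptr(), static_cast<uword>(f.N) * f.t_out3, F3);
  gelu_grad_inplace(d4, f.pre3h, f.phi4, f.E4);
  if (need_param) { g.W3 = f.Xcol3.t() * d4; g.b3 = sum(d4, 0).t(); }
  fmat dXcol3 = d4 * p.W3.t();
  int k3 = p.W3.n_rows / f.C;
  fmat da3(static_cast<uword>(f.N) * f.T, f.C, fill::zeros);
  scatter_add(da3, dXcol3, f.N, f.T, k3, 2, f.pad3, f.t_out3);
  gelu_grad_inplace(da3, f.radd, f.phi3, f.E3);   // da3 is now dradd
  fmat da2 = da3;
  gelu_grad_inplace(da2, f.pre2, f.phi2, f.E2);
  fmat dc2 = bn_bwd(std::move(da2), f.xhat2, f.inv2, p.g2, training,
                    g.g2, g.be2);
  int F1 = p.W1.n_cols;
  int k2 = p.W2.n_rows / F1;
  int padl2; out_len(f.T, k2, 1, padl2);
  fmat da1(static_cast<uword>(f.N) * f.T, F1, fill::zeros);
  if (need_param) g.W2.zeros(p.W2.n_rows, p.W2.n_cols);
  conv_s1_bwd(f.a1, p.W2, dc2, f.N, f.T, k2, padl2,
              need_param ? &g.W2 : nullptr, &da1);
  gelu_grad_inplace(da1, f.pre1, f.phi1, f.E1);
  fmat dc1 = bn_bwd(std::move(da1), f.xhat1, f.inv1, p.g1, training,
                    g.g1, g.be1);
  if (need_param) g.W1 = f.M0.t() * dc1;
  if (need_dX) dX = dc1 * p.W1.t() + da3;  // residual skip adds directly
}

template <typename T1>
static void adam_one(T1& w, const T1& g, T1& m, T1& v, float lr,
                     float b1, float b2, float bc1, float bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8f);
}

// [[Rcpp::export]]
Rcpp::List nn_cpp_train(Rcpp::List params, Rcpp::List state,
                        const arma::cube& X, Rcpp::IntegerVector y,
                        int epochs, int batch_size, double lr,
                        double beta1, double beta2, double dropout,
                        int seed) {
  Params p = params_from_list(params);
  BNState st = state_from_list(state);
  int N = X.n_rows, T = X.n_cols, C = X.n_slices;
  fmat Xall = conv_to<fmat>::from(
    mat(const_cast<double*>(X.memptr()), static_cast<uword>(N) * T, C,
        false));
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> ord(N);
  std::vector<fmat*> wm = { &p.W1, &p.W2, &p.W3, &p.Wf1, &p.Wf2, &p.Wf3 };
  std::vector<fvec*> wv = { &p.g1, &p.be1, &p.g2, &p.be2, &p.b3,
                            &p.bf1, &p.bf2, &p.bf3 };
  std::vector<fmat> am(wm.size()), av(wm.size());
  std::vector<fvec> amv(wv.size()), avv(wv.size());
  for (size_t i = 0; i < wm.size(); ++i) {
    am[i] = zeros<fmat>(wm[i]->n_rows, wm[i]->n_cols);
    av[i] = am[i];
  }
  for (size_t i = 0; i < wv.size(); ++i) {
    amv[i] = zeros<fvec>(wv[i]->n_elem);
    avv[i] = amv[i];
  }
  int tstep = 0;
  Rcpp::NumericVector loss_curve(epochs);
  FwdCache f;
  Grads g;
  fmat dlogits, dX_unused;
  float flr = lr, fb1 = beta1, fb2 = beta2;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < N; ++i) ord[i] = i;
    std::shuffle(ord.begin(), ord.end(), rng);
    double ep_loss = 0; int seen = 0;
    for (int start = 0; start < N; start += batch_size) {
      int nb = std::min(batch_size, N - start);
      fmat Mb(static_cast<uword>(nb) * T, C);
      Rcpp::IntegerVector yb(nb);
      for (int i = 0; i < nb; ++i) {
        int r = ord[start + i];
        yb[i] = y[r];
        for (int c = 0; c < C; ++c) {
          const float* src = Xall.colptr(c);
          float* dst = Mb.colptr(c);
          for (int t = 0; t < T; ++t)
            dst[static_cast<size_t>(t) * nb + i] =
              src[static_cast<size_t>(t) * N + r];
        }
      }
      forward(p, st, Mb, nb, T, true, dropout, &rng, f);
      double loss = xent(f.logits, yb, true, dlogits);
      if (!std::isfinite(loss))
        Rcpp::stop("NaN/Inf loss at epoch %d (training diverged)", ep + 1);
      backward(p, f, dlogits, true, true, false, g, dX_unused);
      ++tstep;
      float bc1 = 1 - std::pow(fb1, tstep);
      float bc2 = 1 - std::pow(fb2, tstep);
      fmat* gm[6] = { &g.W1, &g.W2, &g.W3, &g.Wf1, &g.Wf2, &g.Wf3 };
      fvec* gv[8] = { &g.g1, &g.be1, &g.g2, &g.be2, &g.b3,
                      &g.bf1, &g.bf2, &g.bf3 };
      for (size_t i = 0; i < wm.size(); ++i)
        adam_one(*wm[i], *gm[i], am[i], av[i], flr, fb1, fb2, bc1, bc2);
      for (size_t i = 0; i < wv.size(); ++i)
        adam_one(*wv[i], *gv[i], amv[i], avv[i], flr, fb1, fb2, bc1, bc2);
      ep_loss += loss * nb; seen += nb;
    }
    loss_curve[ep] = ep_loss / seen;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = params_to_list(p),
    Rcpp::Named("state") = state_to_list(st),
    Rcpp::Named("loss_curve") = loss_curve);
}

static fmat cube_to_fmat(const arma::cube& X) {
  return conv_to<fmat>::from(
    mat(const_cast<double*>(X.memptr()),
        static_cast<uword>(X.n_rows) * X.n_cols, X.n_slices, false));
}

// [[Rcpp::export]]
arma::mat nn_cpp_logits(Rcpp::List params, Rcpp::List state,
                        const arma::cube& X) {
  Params p = params_from_list(params);
  BNState st = state_from_list(state);
  FwdCache f;
  forward(p, st, cube_to_fmat(X), X.n_rows, X.n_cols, false, 0.0f,
          nullptr, f);
  return conv_to<mat>::from(f.logits);
}

// [[Rcpp::export]]
arma::cube nn_cpp_input_grad(Rcpp::List params, Rcpp::List state,
                             const arma::cube& X, Rcpp::IntegerVector y) {
  Params p = params_from_list(params);
  BNState st = state_from_list(state);
  FwdCache f;
  forward(p, st, cube_to_fmat(X), X.n_rows, X.n_cols, false, 0.0f,
          nullptr, f);
  fmat dlogits;
  xent(f.logits, y, false, dlogits);
  Grads g;
  fmat dXm;
  backward(p, f, dlogits, false, false, true, g, dXm);
  cube dX(X.n_rows, X.n_cols, X.n_slices);
  mat dd = conv_to<mat>::from(dXm);
  std::memcpy(dX.memptr(), dd.memptr(), sizeof(double) * dd.n_elem);
  return dX;
}
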