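// Recurrent state constructors (vanilla RNN, LSTM, GRU) with a linear
// value head, trained fully online on semi-gradient TD(0) targets by
// truncated backprop through time (overlapping windows, stale boundary
// state) or real-time recurrent learning (forward-propagated influence
// matrix, stale Jacobian across parameter updates).
//
// Parameter vector layout (flat):
//   [vec(W) column-major, b, w_v, b_v]
// where W stacks the gate blocks row-wise ((gates*n) x (d+n)):
//   rnn:  1 block (tanh)
//   lstm: 4 blocks, rows [i; f; g; o], cell state tracked alongside h
//   gru:  3 blocks, rows [z; r; n], candidate input [o_t; r % h_prev]
// Only the recurrent part (W, b) is covered by the RTRL influence matrix;
// the value head's gradient is direct.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

struct ParamView {
  int arch, d, n, m, gates, gn, Prec, P;
  mat W;
  vec b, wv;
  double* bv;
  ParamView(vec& theta, int arch_, int d_, int n_)
      : arch(arch_), d(d_), n(n_), m(d_ + n_),
        gates(arch_ == 1 ? 4 : (arch_ == 2 ? 3 : 1)), gn(gates * n_),
        Prec(gn * (d_ + n_) + gn), P(Prec + n_ + 1),
        W(theta.memptr(), gates * n_, d_ + n_, false, true),
        b(theta.memptr() + gates * n_ * (d_ + n_), gates * n_, false, true),
        wv(theta.memptr() + gn * (d_ + n_) + gn, n_, false, true),
        bv(theta.memptr() + Prec + n_) {
    if ((int)theta.n_elem != P) Rcpp::stop("parameter vector has wrong length");
  }
  int state_dim() const { return arch == 1 ? 2 * n : n; }
};

int n_params(int arch, int d, int n) {
  int gates = arch == 1 ? 4 : (arch == 2 ? 3 : 1);
  return gates * n * (d + n) + gates * n + n + 1;
}

struct Cache {
  vec zin, zn, i, f, g, o, z, r, nc, cpre, tc, hprev, h, c;
};

void forward_step(const ParamView& p, const vec& x_in, const vec& h_prev,
                  const vec& c_prev, Cache& C) {
  const int n = p.n;
  C.zin = join_cols(x_in, h_prev);
  C.hprev = h_prev;
  if (p.arch == 0) {
    C.h = tanh(p.W * C.zin + p.b);
  } else if (p.arch == 1) {
    vec a = p.W * C.zin + p.b;
    C.i = sigmoid(a.subvec(0, n - 1));
    C.f = sigmoid(a.subvec(n, 2 * n - 1));
    C.g = tanh(a.subvec(2 * n, 3 * n - 1));
    C.o = sigmoid(a.subvec(3 * n, 4 * n - 1));
    C.cpre = c_prev;
    C.c = C.f % c_prev + C.i % C.g;
    C.tc = tanh(C.c);
    C.h = C.o % C.tc;
  } else {
    C.z = sigmoid(p.W.rows(0, n - 1) * C.zin + p.b.subvec(0, n - 1));
    C.r = sigmoid(p.W.rows(n, 2 * n - 1) * C.zin + p.b.subvec(n, 2 * n - 1));
    C.zn = join_cols(x_in, C.r % h_prev);
    C.nc = tanh(p.W.rows(2 * n, 3 * n - 1) * C.zn +
                p.b.subvec(2 * n, 3 * n - 1));
    C.h = (1.0 - C.z) % C.nc + C.z % h_prev;
  }
}

// Backward through one step: consumes dL/dh (and dL/dc for LSTM) at this
// step, accumulates parameter gradients, leaves dh/dc for the previous step.
void backward_step(const ParamView& p, const Cache& C, vec& dh, vec& dc,
                   mat& gW, vec& gb) {
  const int n = p.n, d = p.d, m = p.m;
  if (p.arch == 0) {
    vec da = dh % (1.0 - C.h % C.h);
    gW += da * C.zin.t();
    gb += da;
    dh = p.W.cols(d, m - 1).t() * da;
  } else if (p.arch == 1) {
    vec dtc = 1.0 - C.tc % C.tc;
    vec da_o = (dh % C.tc) % C.o % (1.0 - C.o);
    dc += dh % C.o % dtc;
    vec da_i = (dc % C.g) % C.i % (1.0 - C.i);
    vec da_f = (dc % C.cpre) % C.f % (1.0 - C.f);
    vec da_g = (dc % C.i) % (1.0 - C.g % C.g);
    vec dc_prev = dc % C.f;
    vec da = join_cols(join_cols(da_i, da_f), join_cols(da_g, da_o));
    gW += da * C.zin.t();
    gb += da;
    dh = p.W.cols(d, m - 1).t() * da;
    dc = dc_prev;
  } else {
    vec dz = dh % (C.hprev - C.nc);
    vec dn = dh % (1.0 - C.z);
    vec dh_prev = dh % C.z;
    vec da_n = dn % (1.0 - C.nc % C.nc);
    gW.rows(2 * n, 3 * n - 1) += da_n * C.zn.t();
    gb.subvec(2 * n, 3 * n - 1) += da_n;
    vec d_rh = p.W.rows(2 * n, 3 * n - 1).cols(d, m - 1).t() * da_n;
    vec dr = d_rh % C.hprev;
    dh_prev += d_rh % C.r;
    vec da_r = dr % C.r % (1.0 - C.r);
    gW.rows(n, 2 * n - 1) += da_r * C.zin.t();
    gb.subvec(n, 2 * n - 1) += da_r;
    dh_prev += p.W.rows(n, 2 * n - 1).cols(d, m - 1).t() * da_r;
    vec da_z = dz % C.z % (1.0 - C.z);
    gW.rows(0, n - 1) += da_z * C.zin.t();
    gb.subvec(0, n - 1) += da_z;
    dh_prev += p.W.rows(0, n - 1).cols(d, m - 1).t() * da_z;
    dh = dh_prev;
  }
}

// Unroll over the rows of `obs` from (h0, c0); fills caches and values.
void unroll(const ParamView& p, const mat& obs, vec h, vec c,
            std::vector<Cache>& caches, vec& V) {
  const int T = obs.n_rows;
  caches.resize(T);
  V.set_size(T);
  for (int k = 0; k < T; ++k) {
    forward_step(p, obs.row(k).t(), h, c, caches[k]);
    h = caches[k].h;
    if (p.arch == 1) c = caches[k].c;
    V[k] = dot(p.wv, h) + *p.bv;
  }
}

// Gradient of sum_k dLdV[k] * V_k through the unrolled window.
vec window_backward(const ParamView& p, const std::vector<Cache>& caches,
                    const vec& dLdV) {
  vec g(p.P, fill::zeros);
  mat gW(g.memptr(), p.gn, p.m, false, true);
  vec gb(g.memptr() + p.gn * p.m, p.gn, false, true);
  vec gwv(g.memptr() + p.Prec, p.n, false, true);
  double* gbv = g.memptr() + p.P - 1;
  vec dh(p.n, fill::zeros), dc(p.n, fill::zeros);
  for (int k = (int)caches.size() - 1; k >= 0; --k) {
    dh += p.wv * dLdV[k];
    gwv += caches[k].h * dLdV[k];
    *gbv += dLdV[k];
    backward_step(p, caches[k], dh, dc, gW, gb);
  }
  return g;
}

// TD(0) window targets: us[k] + gamma * V_{k+1} (bootstrap stopgrad),
// with the newest loss bootstrapping on v_boot (the online prediction).
void window_dLdV(const vec& V, const vec& us, double v_boot, double gamma,
                 vec& dLdV, double* loss) {
  const int T = V.n_elem;
  dLdV.set_size(T);
  if (loss) *loss = 0.0;
  for (int k = 0; k < T; ++k) {
    double target = us[k] + gamma * (k < T - 1 ? V[k + 1] : v_boot);
    dLdV[k] = V[k] - target;
    if (loss) *loss += 0.5 * (V[k] - target) * (V[k] - target);
  }
}

// Influence-matrix propagation: J <- A J + B with A = d s_t / d s_{t-1}
// and B = d s_t / d theta_rec, both evaluated at the parameters used for
// the forward pass at this step. State s is h (rnn, gru) or [h; c] (lstm).
void rtrl_propagate(const ParamView& p, const Cache& C, mat& J) {
  const int n = p.n, d = p.d, m = p.m, gn = p.gn;
  if (p.arch == 0) {
    vec dact = 1.0 - C.h % C.h;
    mat A = p.W.cols(d, m - 1);
    A.each_col() %= dact;
    J = A * J;
    for (int u = 0; u < n; ++u) {
      for (int j = 0; j < m; ++j) J(u, j * gn + u) += dact[u] * C.zin[j];
      J(u, gn * m + u) += dact[u];
    }
  } else if (p.arch == 1) {
    vec di = C.i % (1.0 - C.i), df = C.f % (1.0 - C.f),
        do_ = C.o % (1.0 - C.o), dg = 1.0 - C.g % C.g,
        dtc = 1.0 - C.tc % C.tc;
    vec cC[4] = {C.g % di, C.cpre % df, C.i % dg, vec(n, fill::zeros)};
    vec odtc = C.o % dtc;
    vec cH[4] = {odtc % cC[0], odtc % cC[1], odtc % cC[2], C.tc % do_};
    mat Wh = p.W.cols(d, m - 1);
    mat Ch(n, n, fill::zeros);
    for (int gidx = 0; gidx < 3; ++gidx) {
      mat t = Wh.rows(gidx * n, (gidx + 1) * n - 1);
      t.each_col() %= cC[gidx];
      Ch += t;
    }
    mat A(2 * n, 2 * n, fill::zeros);
    {
      mat Ahh = Wh.rows(3 * n, 4 * n - 1);
      Ahh.each_col() %= (C.tc % do_);
      mat t2 = Ch;
      t2.each_col() %= odtc;
      Ahh += t2;
      A.submat(0, 0, n - 1, n - 1) = Ahh;
      A.submat(0, n, n - 1, 2 * n - 1) = diagmat(odtc % C.f);
      A.submat(n, 0, 2 * n - 1, n - 1) = Ch;
      A.submat(n, n, 2 * n - 1, 2 * n - 1) = diagmat(C.f);
    }
    J = A * J;
    for (int gidx = 0; gidx < 4; ++gidx) {
      for (int u = 0; u < n; ++u) {
        int r = gidx * n + u;
        double ch = cH[gidx][u], cc = cC[gidx][u];
        for (int j = 0; j < m; ++j) {
          J(u, j * gn + r) += ch * C.zin[j];
          J(n + u, j * gn + r) += cc * C.zin[j];
        }
        J(u, gn * m + r) += ch;
        J(n + u, gn * m + r) += cc;
      }
    }
  } else {
    vec dzs = C.z % (1.0 - C.z), drs = C.r % (1.0 - C.r),
        dnc = 1.0 - C.nc % C.nc;
    mat Wz_h = p.W.rows(0, n - 1).cols(d, m - 1);
    mat Wr_h = p.W.rows(n, 2 * n - 1).cols(d, m - 1);
    mat Wn_h = p.W.rows(2 * n, 3 * n - 1).cols(d, m - 1);
    mat part1 = Wn_h;
    part1.each_row() %= C.r.t();
    mat tmp = Wn_h;
    tmp.each_row() %= (C.hprev % drs).t();
    mat An = part1 + tmp * Wr_h;
    mat t1 = Wz_h;
    t1.each_col() %= ((C.hprev - C.nc) % dzs);
    mat t2 = An;
    t2.each_col() %= ((1.0 - C.z) % dnc);
    mat A = diagmat(C.z) + t1 + t2;
    J = A * J;
    vec coef_z = (C.hprev - C.nc) % dzs;
    vec coef_n = (1.0 - C.z) % dnc;
    for (int u = 0; u < n; ++u) {
      int rz = u, rn = 2 * n + u, rr = n + u;
      for (int j = 0; j < m; ++j) {
        J(u, j * gn + rz) += coef_z[u] * C.zin[j];
        J(u, j * gn + rn) += coef_n[u] * C.zn[j];
      }
      J(u, gn * m + rz) += coef_z[u];
      J(u, gn * m + rn) += coef_n[u];
      vec vcol = coef_n % Wn_h.col(u) * (C.hprev[u] * drs[u]);
      for (int j = 0; j < m; ++j) J.col(j * gn + rr) += vcol * C.zin[j];
      J.col(gn * m + rr) += vcol;
    }
  }
}

struct AdamState {
  vec m1, m2;
  double b1, b2, eps, alpha;
  long t;
  AdamState(int nparam, double alpha_, double b1_, double b2_, double eps_)
      : m1(nparam, fill::zeros), m2(nparam, fill::zeros),
        b1(b1_), b2(b2_), eps(eps_), alpha(alpha_), t(0) {}
  void step(vec& theta, const vec& g) {
    ++t;
    m1 = b1 * m1 + (1 - b1) * g;
    m2 = b2 * m2 + (1 - b2) * square(g);
    vec m1h = m1 / (1 - std::pow(b1, (double)t));
    vec m2h = m2 / (1 - std::pow(b2, (double)t));
    theta -= alpha * (m1h / (sqrt(m2h) + eps));
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cell_forward_seq_cpp(arma::vec theta, int arch, int d, int n,
                                const arma::mat& obs, arma::vec h0,
                                arma::vec c0) {
  ParamView p(theta, arch, d, n);
  std::vector<Cache> caches;
  vec V;
  // re-run manually to honor supplied initial state
  const int T = obs.n_rows;
  mat H(T, n), C(T, n, fill::zeros);
  V.set_size(T);
  vec h = h0, c = c0;
  Cache cache;
  for (int k = 0; k < T; ++k) {
    forward_step(p, obs.row(k).t(), h, c, cache);
    h = cache.h;
    if (arch == 1) c = cache.c;
    H.row(k) = h.t();
    if (arch == 1) C.row(k) = c.t();
    V[k] = dot(p.wv, h) + *p.bv;
  }
  return Rcpp::List::create(Rcpp::Named("V") = V, Rcpp::Named("H") = H,
                            Rcpp::Named("C") = C);
}

// [[Rcpp::export]]
double window_loss_cpp(arma::vec theta, int arch, int d, int n,
                       arma::vec h0, arma::vec c0, const arma::mat& obs,
                       const arma::vec& us, double v_boot, double gamma) {
  ParamView p(theta, arch, d, n);
  std::vector<Cache> caches;
  vec V;
  // start from supplied state
  const int T = obs.n_rows;
  caches.resize(T);
  V.set_size(T);
  vec h = h0, c = c0;
  for (int k = 0; k < T; ++k) {
    forward_step(p, obs.row(k).t(), h, c, caches[k]);
    h = caches[k].h;
    if (arch == 1) c = caches[k].c;
    V[k] = dot(p.wv, h) + *p.bv;
  }
  vec dLdV;
  double loss;
  window_dLdV(V, us, v_boot, gamma, dLdV, &loss);
  return loss;
}

// Loss with externally fixed targets: 0.5 * sum_k (V_k - target_k)^2.
// Finite differences of this function (targets computed once at the base
// parameters) give exactly the semi-gradient that window_backward returns,
// since the bootstrap term carries no gradient.
// [[Rcpp::export]]
double window_fixed_target_loss_cpp(arma::vec theta, int arch, int d, int n,
                                    arma::vec h0, arma::vec c0,
                                    const arma::mat& obs,
                                    const arma::vec& targets) {
  ParamView p(theta, arch, d, n);
  const int T = obs.n_rows;
  vec h = h0, c = c0;
  Cache cache;
  double loss = 0.0;
  for (int k = 0; k < T; ++k) {
    forward_step(p, obs.row(k).t(), h, c, cache);
    h = cache.h;
    if (arch == 1) c = cache.c;
    double V = dot(p.wv, h) + *p.bv;
    loss += 0.5 * (V - targets[k]) * (V - targets[k]);
  }
  return loss;
}

// [[Rcpp::export]]
arma::vec tbptt_window_grad_cpp(arma::vec theta, int arch, int d, int n,
                                arma::vec h0, arma::vec c0,
                                const arma::mat& obs, const arma::vec& us,
                                double v_boot, double gamma) {
  ParamView p(theta, arch, d, n);
  const int T = obs.n_rows;
  std::vector<Cache> caches(T);
  vec V(T);
  vec h = h0, c = c0;
  for (int k = 0; k < T; ++k) {
    forward_step(p, obs.row(k).t(), h, c, caches[k]);
    h = caches[k].h;
    if (arch == 1) c = caches[k].c;
    V[k] = dot(p.wv, h) + *p.bv;
  }
  vec dLdV;
  window_dLdV(V, us, v_boot, gamma, dLdV, nullptr);
  return window_backward(p, caches, dLdV);
}

// Full-unroll backprop-from-origin gradient of the summed TD(0) losses
// sum_{t=1..T-1} 0.5 (us_{t+1} + gamma stopgrad(V_{t+1}) - V_t)^2 over a
// frozen-parameter sequence, zero initial state.
// [[Rcpp::export]]
arma::vec full_unroll_grad_cpp(arma::vec theta, int arch, int d, int n,
                               const arma::mat& obs, const arma::vec& us,
                               double gamma) {
  ParamView p(theta, arch, d, n);
  std::vector<Cache> caches;
  vec V;
  unroll(p, obs, vec(n, fill::zeros), vec(n, fill::zeros), caches, V);
  const int T = obs.n_rows;
  vec dLdV(T, fill::zeros);
  for (int t = 0; t < T - 1; ++t)
    dLdV[t] = V[t] - (us[t + 1] + gamma * V[t + 1]);
  return window_backward(p, caches, dLdV);
}

// Frozen-parameter RTRL accumulation of the same gradient, via the
// influence matrix (independent code path from window_backward).
// [[Rcpp::export]]
arma::vec rtrl_accum_grad_cpp(arma::vec theta, int arch, int d, int n,
                              const arma::mat& obs, const arma::vec& us,
                              double gamma) {
  ParamView p(theta, arch, d, n);
  const int T = obs.n_rows;
  const int S = p.state_dim();
  mat J(S, p.Prec, fill::zeros);
  vec g(p.P, fill::zeros);
  vec h(n, fill::zeros), c(n, fill::zeros);
  Cache cache;
  double Vprev = 0.0;
  vec gradVprev;  // d V_{t-1} / d theta
  vec hprev_store;
  for (int t = 0; t < T; ++t) {
    forward_step(p, obs.row(t).t(), h, c, cache);
    h = cache.h;
    if (arch == 1) c = cache.c;
    double V = dot(p.wv, h) + *p.bv;
    rtrl_propagate(p, cache, J);
    vec gradV(p.P, fill::zeros);
    gradV.subvec(0, p.Prec - 1) = J.rows(0, n - 1).t() * p.wv;
    gradV.subvec(p.Prec, p.Prec + n - 1) = h;
    gradV[p.P - 1] = 1.0;
    if (t > 0) {
      double delta = us[t] + gamma * V - Vprev;
      g += -delta * gradVprev;
    }
    Vprev = V;
    gradVprev = gradV;
  }
  return g;
}

// [[Rcpp::export]]
Rcpp::List recurrent_agent_cpp(const arma::mat& obs, const arma::vec& us,
                               int arch, int trainer, arma::vec theta,
                               int n_hidden, const Rcpp::List& hyper,
                               int T, int stride) {
  const int d = obs.n_cols;
  ParamView p(theta, arch, d, n_hidden);
  const int n = n_hidden;
  const double alpha = Rcpp::as<double>(hyper["alpha"]);
  const double gamma = Rcpp::as<double>(hyper["gamma"]);
  AdamState opt(p.P, alpha, Rcpp::as<double>(hyper["beta1"]),
                Rcpp::as<double>(hyper["beta2"]),
                Rcpp::as<double>(hyper["epsilon"]));
  const int nsteps = obs.n_rows;
  vec pred(nsteps, fill::zeros);

  if (trainer == 0) {
    // T-BPTT with overlapping windows, update every `stride` steps once
    // the buffer holds T transitions; boundary state stored stale.
    const int ring = T + 2;
    mat hbuf(n, ring, fill::zeros), cbuf(n, ring, fill::zeros);
    vec h(n, fill::zeros), c(n, fill::zeros);
    Cache cache;
    std::vector<Cache> caches;
    vec V, dLdV;
    for (int t = 0; t < nsteps; ++t) {
      forward_step(p, obs.row(t).t(), h, c, cache);
      h = cache.h;
      if (arch == 1) c = cache.c;
      double Vt = dot(p.wv, h) + *p.bv;
      if (!std::isfinite(Vt))
        Rcpp::stop("non-finite prediction at step %d: run aborted", t + 1);
      pred[t] = Vt;
      hbuf.col(t % ring) = h;
      if (arch == 1) cbuf.col(t % ring) = c;
      if (t >= T && ((t - T) % stride == 0)) {
        int tb = t - T - 1;
        vec hb(n, fill::zeros), cb(n, fill::zeros);
        if (tb >= 0) {
          hb = hbuf.col(tb % ring);
          if (arch == 1) cb = cbuf.col(tb % ring);
        }
        caches.resize(T);
        V.set_size(T);
        vec hw = hb, cw = cb;
        for (int k = 0; k < T; ++k) {
          forward_step(p, obs.row(t - T + k).t(), hw, cw, caches[k]);
          hw = caches[k].h;
          if (arch == 1) cw = caches[k].c;
          V[k] = dot(p.wv, hw) + *p.bv;
        }
        vec usw = us.subvec(t - T + 1, t);
        window_dLdV(V, usw, Vt, gamma, dLdV, nullptr);
        vec g = window_backward(p, caches, dLdV);
        opt.step(theta, g);
      }
    }
  } else {
    // RTRL: per-step TD(0) update with a stale Jacobian (J is never reset
    // after a parameter update).
    const int S = p.state_dim();
    mat J(S, p.Prec, fill::zeros);
    vec h(n, fill::zeros), c(n, fill::zeros);
    Cache cache;
    double Vprev = 0.0;
    vec hprev(n, fill::zeros);
    vec gradVprev_rec(p.Prec, fill::zeros);
    for (int t = 0; t < nsteps; ++t) {
      forward_step(p, obs.row(t).t(), h, c, cache);
      h = cache.h;
      if (arch == 1) c = cache.c;
      double Vt = dot(p.wv, h) + *p.bv;
      if (!std::isfinite(Vt))
        Rcpp::stop("non-finite prediction at step %d: run aborted", t + 1);
      pred[t] = Vt;
      vec g(p.P, fill::zeros);
      bool do_update = t > 0;
      if (do_update) {
        double delta = us[t] + gamma * Vt - Vprev;
        g.subvec(0, p.Prec - 1) = -delta * gradVprev_rec;
        g.subvec(p.Prec, p.Prec + n - 1) = -delta * hprev;
        g[p.P - 1] = -delta;
      }
      // propagate with the parameters used for this forward pass,
      // before the optimizer modifies them
      rtrl_propagate(p, cache, J);
      vec gradV_rec = J.rows(0, n - 1).t() * p.wv;
      if (do_update) opt.step(theta, g);
      Vprev = Vt;
      hprev = h;
      gradVprev_rec = gradV_rec;
    }
  }
  return Rcpp::List::create(Rcpp::Named("pred") = pred,
                            Rcpp::Named("theta") = theta);
}

// [[Rcpp::export]]
int n_params_cpp(int arch, int d, int n) { return n_params(arch, d, n); }
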