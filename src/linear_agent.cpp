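// Online linear TD(lambda) agent over a fixed representation.
// Feature layouts match the one-step R reference functions exactly
// (channel-major, bias last); the R engine / C++ engine equivalence is
// asserted in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

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

// Tabular TD(lambda), plain SGD, with a per-step step-size schedule and
// optional tail averaging of the weight iterates. One-hot features over
// `n_states`; exactly the td_update() rule specialized to indicators.
// [[Rcpp::export]]
Rcpp::List td_tabular_cpp(const arma::ivec& states, const arma::vec& cumulant,
                          const arma::vec& alpha, double gamma, double lambda,
                          int n_states, int avg_from, double alpha_pow,
                          double alpha_c) {
  const long n = states.n_elem;
  const bool state_cumulant = (long)cumulant.n_elem == (long)n_states;
  const bool scheduled = alpha_pow > 0;
  vec w(n_states, fill::zeros), z(n_states, fill::zeros);
  vec wsum(n_states, fill::zeros);
  std::vector<long> visits(n_states, 0);
  long navg = 0;
  for (long t = 0; t < n - 1; ++t) {
    int s = states[t] - 1, s2 = states[t + 1] - 1;
    double cum = state_cumulant ? cumulant[s2] : cumulant[t + 1];
    double delta = cum + gamma * w[s2] - w[s];
    double a;
    if (scheduled) {
      ++visits[s];
      a = 1.0 / std::pow(alpha_c + (double)visits[s], alpha_pow);
    } else {
      a = alpha[t];
    }
    if (lambda == 0.0) {
      w[s] += a * delta;
    } else {
      z *= gamma * lambda;
      z[s] += 1.0;
      w += a * delta * z;
    }
    if (t + 1 >= avg_from) {
      wsum += w;
      ++navg;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("w") = w,
      Rcpp::Named("w_avg") = navg > 0 ? vec(wsum / navg) : w);
}

// [[Rcpp::export]]
Rcpp::List linear_agent_cpp(const arma::mat& obs, const arma::vec& us,
                            const Rcpp::List& rep, const Rcpp::List& hyper) {
  const int type = Rcpp::as<int>(rep["type"]);
  const double tau = Rcpp::as<double>(rep["tau"]);
  const int n_tilings = Rcpp::as<int>(rep["n_tilings"]);
  const int n_tiles = Rcpp::as<int>(rep["n_tiles"]);
  const int n_rbfs = Rcpp::as<int>(rep["n_rbfs"]);
  const double sigma = Rcpp::as<double>(rep["sigma"]);

  mat W_in, W;
  vec W_fb;
  if (type == 4) {
    W_in = Rcpp::as<mat>(rep["W_in"]);
    W = Rcpp::as<mat>(rep["W"]);
    W_fb = Rcpp::as<vec>(rep["W_fb"]);
  }

  const double alpha = Rcpp::as<double>(hyper["alpha"]);
  const double lambda = Rcpp::as<double>(hyper["lambda"]);
  const double gamma = Rcpp::as<double>(hyper["gamma"]);
  const bool adam = Rcpp::as<int>(hyper["adam"]) == 1;
  const double beta1 = Rcpp::as<double>(hyper["beta1"]);
  const double beta2 = Rcpp::as<double>(hyper["beta2"]);
  const double eps = Rcpp::as<double>(hyper["epsilon"]);

  const int n = obs.n_rows, d = obs.n_cols;
  int nf;
  switch (type) {
    case 0: case 1: nf = d + 1; break;
    case 2: nf = d * n_tilings * n_tiles + 1; break;
    case 3: nf = d * n_rbfs + 1; break;
    case 4: nf = (int)W.n_rows + 1; break;
    default: Rcpp::stop("unknown representation code");
  }

  vec w(nf, fill::zeros), z(nf, fill::zeros);
  AdamState opt(nf, alpha, beta1, beta2, eps);
  vec xcur(nf, fill::zeros), xprev(nf, fill::zeros);
  vec y(d, fill::zeros), oprev(d, fill::zeros), h;
  if (type == 4) h = vec(W.n_rows, fill::zeros);
  vec pred(n, fill::zeros);
  double v_prev = 0.0;

  for (int t = 0; t < n; ++t) {
    vec o = obs.row(t).t();
    if (type == 1 || type == 2 || type == 3) {
      for (int j = 0; j < d; ++j)
        y[j] = (o[j] == 1.0 && oprev[j] == 0.0) ? 1.0 : tau * y[j];
    }
    xcur.zeros();
    if (type == 0) {
      xcur.subvec(0, d - 1) = o;
      xcur[nf - 1] = 1.0;
    } else if (type == 1) {
      xcur.subvec(0, d - 1) = y;
      xcur[nf - 1] = 1.0;
    } else if (type == 2) {
      for (int c = 0; c < d; ++c)
        for (int j = 0; j < n_tilings; ++j) {
          double offset = (double)j / (n_tilings * n_tiles);
          int idx = (int)std::floor((y[c] + offset) * n_tiles);
          if (idx > n_tiles - 1) idx = n_tiles - 1;
          xcur[(c * n_tilings + j) * n_tiles + idx] = 1.0;
        }
      xcur[nf - 1] = 1.0;
    } else if (type == 3) {
      for (int c = 0; c < d; ++c)
        for (int i = 0; i < n_rbfs; ++i) {
          double ci = (double)(i + 1) / n_rbfs;
          xcur[c * n_rbfs + i] =
              y[c] * std::exp(-(y[c] - ci) * (y[c] - ci) / (2 * sigma * sigma));
        }
      xcur[nf - 1] = 1.0;
    } else {
      h = tanh(W_in * o + W * h + W_fb * v_prev);
      xcur.subvec(0, nf - 2) = h;
      xcur[nf - 1] = 1.0;
    }

    double v = dot(w, xcur);
    pred[t] = v;
    if (t > 0) {
      double v_t = dot(w, xprev);
      double delta = us[t] + gamma * v - v_t;
      if (!std::isfinite(delta))
        Rcpp::stop("non-finite TD error at step %d: run aborted", t + 1);
      z = gamma * lambda * z + xprev;
      if (adam) {
        opt.step(w, vec(-delta * z));
      } else {
        w += alpha * delta * z;
      }
    }
    v_prev = v;
    xprev = xcur;
    oprev = o;
  }

  return Rcpp::List::create(Rcpp::Named("pred") = pred,
                            Rcpp::Named("w") = w);
}
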