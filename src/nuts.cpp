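// Hierarchical Bernoulli log-posterior (non-centered, unconstrained
// scale) with analytic gradient, and a multinomial no-U-turn sampler
// with dual-averaging step-size adaptation and windowed diagonal mass
// adaptation. All randomness comes from R's RNG, so chains are
// reproducible from set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ModelData {
  arma::vec y;
  arma::mat X;
  std::vector<int> type;            // 0 = index (random intercepts), 1 = dense
  std::vector<arma::ivec> idx;      // 0-based level index per row
  std::vector<arma::mat> Z;         // dense basis per group
  std::vector<int> K;
  double coef_sd, sd_rate;
  int n, p, G, npar;
};

ModelData unpack(const List& data) {
  ModelData m;
  m.y = as<arma::vec>(data["y"]);
  m.X = as<arma::mat>(data["X"]);
  IntegerVector gt = data["group_type"];
  List gi = data["group_idx"], gz = data["group_Z"];
  IntegerVector gk = data["group_K"];
  m.G = gt.size();
  for (int g = 0; g < m.G; ++g) {
    m.type.push_back(gt[g]);
    m.idx.push_back(as<arma::ivec>(gi[g]));
    m.Z.push_back(as<arma::mat>(gz[g]));
    m.K.push_back(gk[g]);
  }
  m.coef_sd = as<double>(data["coef_sd"]);
  m.sd_rate = as<double>(data["sd_rate"]);
  m.n = m.y.n_elem;
  m.p = m.X.n_cols;
  m.npar = m.p;
  for (int g = 0; g < m.G; ++g) m.npar += m.K[g];
  m.npar += m.G;
  return m;
}

const double LOG2PI = 1.8378770664093454836;

// log posterior and gradient; theta = (beta, z_1..z_G, log sigma_1..G)
double logp_grad(const ModelData& m, const arma::vec& theta,
                 arma::vec& grad, bool jacobian) {
  const int p = m.p, G = m.G, n = m.n;
  arma::vec beta = theta.subvec(0, p - 1);
  std::vector<arma::vec> z(G);
  int off = p;
  for (int g = 0; g < G; ++g) {
    z[g] = theta.subvec(off, off + m.K[g] - 1);
    off += m.K[g];
  }
  arma::vec lambda = (G > 0) ? arma::vec(theta.subvec(off, off + G - 1))
                             : arma::vec();
  arma::vec sigma = arma::exp(lambda);

  arma::vec eta = m.X * beta;
  for (int g = 0; g < G; ++g) {
    if (m.type[g] == 0) {
      for (int i = 0; i < n; ++i) eta[i] += sigma[g] * z[g][m.idx[g][i]];
    } else {
      eta += sigma[g] * (m.Z[g] * z[g]);
    }
  }

  // stable Bernoulli log-likelihood and residual y - p
  double ll = 0.0;
  arma::vec r(n);
  for (int i = 0; i < n; ++i) {
    double e = eta[i];
    double pr = 1.0 / (1.0 + std::exp(-e));
    ll += (m.y[i] == 1.0)
        ? (e > 0 ? -std::log1p(std::exp(-e)) : e - std::log1p(std::exp(e)))
        : (e > 0 ? -e - std::log1p(std::exp(-e)) : -std::log1p(std::exp(e)));
    r[i] = m.y[i] - pr;
  }

  double lp = ll;
  grad.set_size(m.npar);

  // beta ~ N(0, coef_sd)
  double cs2 = m.coef_sd * m.coef_sd;
  lp += -0.5 * arma::dot(beta, beta) / cs2 - p * std::log(m.coef_sd)
        - 0.5 * p * LOG2PI;
  grad.subvec(0, p - 1) = m.X.t() * r - beta / cs2;

  off = p;
  std::vector<double> contrib(G);  // sum_i r_i * (A_g z_g)_i per group
  for (int g = 0; g < G; ++g) {
    const int K = m.K[g];
    arma::vec gz(K, arma::fill::zeros);
    double cg = 0.0;
    if (m.type[g] == 0) {
      for (int i = 0; i < n; ++i) {
        gz[m.idx[g][i]] += r[i];
        cg += r[i] * z[g][m.idx[g][i]];
      }
      gz *= sigma[g];
    } else {
      gz = sigma[g] * (m.Z[g].t() * r);
      cg = arma::dot(m.Z[g] * z[g], r);
    }
    contrib[g] = cg;
    lp += -0.5 * arma::dot(z[g], z[g]) - 0.5 * K * LOG2PI;
    grad.subvec(off, off + K - 1) = gz - z[g];
    off += K;
  }
  // sigma ~ Exp(sd_rate), sampled as lambda = log sigma;
  // d/d lambda = sigma * (d ll / d sigma) - rate * sigma (+1 Jacobian)
  for (int g = 0; g < G; ++g) {
    lp += std::log(m.sd_rate) - m.sd_rate * sigma[g];
    grad[off + g] = sigma[g] * contrib[g] - m.sd_rate * sigma[g];
    if (jacobian) { lp += lambda[g]; grad[off + g] += 1.0; }
  }
  return lp;
}

struct Hamilton {
  const ModelData& m;
  arma::vec inv_m;  // diagonal inverse mass (posterior variances)
  explicit Hamilton(const ModelData& mm) : m(mm) {
    inv_m.ones(mm.npar);
  }
  double lp(const arma::vec& th, arma::vec& gr) const {
    return logp_grad(m, th, gr, true);
  }
  double kinetic(const arma::vec& r) const {
    return 0.5 * arma::dot(r, inv_m % r);
  }
  arma::vec sample_momentum() const {
    arma::vec r(m.npar);
    for (int k = 0; k < m.npar; ++k)
      r[k] = norm_rand() / std::sqrt(inv_m[k]);
    return r;
  }
};

struct State {
  arma::vec theta, r, grad;
  double lp;
};

void leapfrog(const Hamilton& H, State& s, double eps) {
  s.r += 0.5 * eps * s.grad;
  s.theta += eps * (H.inv_m % s.r);
  s.lp = H.lp(s.theta, s.grad);
  s.r += 0.5 * eps * s.grad;
}

double log_sum_exp(double a, double b) {
  double mx = std::max(a, b);
  if (!std::isfinite(mx)) return mx;
  return mx + std::log(std::exp(a - mx) + std::exp(b - mx));
}

struct Tree {
  State minus_s, plus_s;
  arma::vec prop;
  double logw;
  bool stop, divergent;
  double alpha;
  int n_alpha;
};

bool uturn(const Hamilton& H, const Tree& t) {
  arma::vec d = t.plus_s.theta - t.minus_s.theta;
  return arma::dot(d, H.inv_m % t.minus_s.r) < 0 ||
         arma::dot(d, H.inv_m % t.plus_s.r) < 0;
}

// recursively build a subtree of depth j starting from state s in
// direction v; H0 is the initial Hamiltonian log-weight reference
Tree build_tree(const Hamilton& H, const State& s, int j, int v,
                double eps, double H0) {
  if (j == 0) {
    Tree t;
    State ns = s;
    leapfrog(H, ns, v * eps);
    double lw = ns.lp - H.kinetic(ns.r) - H0;
    if (!std::isfinite(lw)) lw = -std::numeric_limits<double>::infinity();
    t.minus_s = ns; t.plus_s = ns; t.prop = ns.theta;
    t.logw = lw;
    t.divergent = (lw < -1000.0);
    t.stop = t.divergent;
    t.alpha = std::min(1.0, std::exp(lw));
    t.n_alpha = 1;
    return t;
  }
  Tree t1 = build_tree(H, s, j - 1, v, eps, H0);
  if (t1.stop) return t1;
  const State& edge = (v == 1) ? t1.plus_s : t1.minus_s;
  Tree t2 = build_tree(H, edge, j - 1, v, eps, H0);
  Tree t;
  t.minus_s = (v == 1) ? t1.minus_s : t2.minus_s;
  t.plus_s = (v == 1) ? t2.plus_s : t1.plus_s;
  t.logw = log_sum_exp(t1.logw, t2.logw);
  // multinomial sampling within the subtree
  double pr = std::exp(t2.logw - t.logw);
  t.prop = (unif_rand() < pr) ? t2.prop : t1.prop;
  t.divergent = t1.divergent || t2.divergent;
  t.alpha = t1.alpha + t2.alpha;
  t.n_alpha = t1.n_alpha + t2.n_alpha;
  t.stop = t2.stop || t.divergent || uturn(H, t);
  return t;
}

struct IterResult {
  arma::vec theta;
  double accept_stat;
  int treedepth;
  bool divergent;
  double lp;
};

IterResult nuts_iteration(const Hamilton& H, arma::vec& theta,
                          double eps, int max_treedepth) {
  arma::vec grad(theta.n_elem);
  double lp0 = H.lp(theta, grad);
  State init{theta, H.sample_momentum(), grad, lp0};
  double H0 = lp0 - H.kinetic(init.r);

  Tree whole;
  whole.minus_s = init; whole.plus_s = init;
  whole.prop = theta;
  whole.logw = 0.0;  // weight of the initial point relative to H0
  whole.stop = false; whole.divergent = false;
  whole.alpha = 0.0; whole.n_alpha = 0;

  int depth = 0;
  while (depth < max_treedepth) {
    int v = (unif_rand() < 0.5) ? -1 : 1;
    const State& edge = (v == 1) ? whole.plus_s : whole.minus_s;
    Tree sub = build_tree(H, edge, depth, v, eps, H0);
    whole.alpha += sub.alpha;
    whole.n_alpha += sub.n_alpha;
    if (sub.divergent) whole.divergent = true;
    if (sub.stop) break;
    // progressive, biased sampling toward the new subtree
    double pr = std::exp(sub.logw - whole.logw);
    if (unif_rand() < std::min(1.0, pr)) whole.prop = sub.prop;
    whole.logw = log_sum_exp(whole.logw, sub.logw);
    if (v == 1) whole.plus_s = sub.plus_s; else whole.minus_s = sub.minus_s;
    ++depth;
    if (uturn(H, whole)) break;
  }
  theta = whole.prop;
  IterResult res;
  res.theta = theta;
  res.accept_stat = (whole.n_alpha > 0) ? whole.alpha / whole.n_alpha : 0.0;
  res.treedepth = depth;
  res.divergent = whole.divergent;
  res.lp = 0.0;
  return res;
}

double find_initial_eps(const Hamilton& H, const arma::vec& theta) {
  double eps = 1.0;
  arma::vec grad(theta.n_elem);
  double lp0 = H.lp(theta, grad);
  State s{theta, H.sample_momentum(), grad, lp0};
  double H0 = lp0 - H.kinetic(s.r);
  State s1 = s;
  leapfrog(H, s1, eps);
  double lw = s1.lp - H.kinetic(s1.r) - H0;
  if (!std::isfinite(lw)) lw = -1e10;
  double a = (lw > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    if (a * lw <= -a * std::log(2.0)) break;
    eps *= std::pow(2.0, a);
    State s2 = s;
    leapfrog(H, s2, eps);
    lw = s2.lp - H.kinetic(s2.r) - H0;
    if (!std::isfinite(lw)) lw = -1e10;
  }
  return eps;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
List lehstress_logp_grad(NumericVector theta, List data, bool jacobian) {
  ModelData m = unpack(data);
  arma::vec th = as<arma::vec>(theta);
  if ((int)th.n_elem != m.npar)
    stop("parameter vector has length %d, expected %d", th.n_elem, m.npar);
  arma::vec grad;
  double lp = logp_grad(m, th, grad, jacobian);
  return List::create(_["lp"] = lp,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}

//' @noRd
// [[Rcpp::export]]
List lehstress_nuts_chain(List data, NumericVector init, int n_warmup,
                          int n_iter, double adapt_delta,
                          int max_treedepth) {
  ModelData m = unpack(data);
  Hamilton H(m);
  arma::vec theta = as<arma::vec>(init);
  if ((int)theta.n_elem != m.npar)
    stop("init has length %d, expected %d", theta.n_elem, m.npar);

  // dual averaging (step-size adaptation)
  double eps = find_initial_eps(H, theta);
  double mu = std::log(10.0 * eps);
  double log_eps_bar = 0.0, h_bar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_m = 0;

  // Welford accumulator for windowed diagonal mass adaptation
  const bool adapt_metric = n_warmup >= 150;
  int win_start = 75, win_size = 25;
  int win_end = adapt_metric
      ? std::min(win_start + win_size, n_warmup - 50) : -1;
  arma::vec acc_mean(m.npar, arma::fill::zeros);
  arma::vec acc_m2(m.npar, arma::fill::zeros);
  int acc_n = 0;

  arma::mat draws(n_iter, m.npar);
  int n_divergent = 0;
  IntegerVector treedepths(n_iter);

  for (int it = 0; it < n_warmup + n_iter; ++it) {
    bool warm = it < n_warmup;
    double use_eps = warm ? eps : std::exp(log_eps_bar);
    IterResult res = nuts_iteration(H, theta, use_eps, max_treedepth);

    if (warm) {
      ++da_m;
      double frac = 1.0 / (da_m + t0);
      h_bar = (1 - frac) * h_bar + frac * (adapt_delta - res.accept_stat);
      double log_eps = mu - std::sqrt((double)da_m) / gamma * h_bar;
      eps = std::exp(log_eps);
      double w = std::pow((double)da_m, -kappa);
      log_eps_bar = w * log_eps + (1 - w) * log_eps_bar;

      if (adapt_metric && it >= win_start && it < win_end) {
        ++acc_n;
        arma::vec d = theta - acc_mean;
        acc_mean += d / acc_n;
        acc_m2 += d % (theta - acc_mean);
      }
      if (adapt_metric && it == win_end - 1 && acc_n > 4) {
        arma::vec v = acc_m2 / (acc_n - 1);
        // regularize toward unity as in windowed adaptation schemes
        double w2 = (double)acc_n / (acc_n + 5.0);
        H.inv_m = w2 * v + (1 - w2) * arma::ones(m.npar) * 1e-3;
        H.inv_m.elem(arma::find(H.inv_m < 1e-10)).fill(1e-10);
        // restart step-size adaptation around the current step
        eps = find_initial_eps(H, theta);
        mu = std::log(10.0 * eps);
        h_bar = 0.0; log_eps_bar = std::log(eps); da_m = 0;
        acc_mean.zeros(); acc_m2.zeros(); acc_n = 0;
        win_start = win_end;
        win_size *= 2;
        win_end = std::min(win_start + win_size, n_warmup - 50);
        if (win_end - win_start < win_size &&
            (n_warmup - 50) - win_start < 2 * win_size)
          win_end = n_warmup - 50;  // extend last window to the buffer
      }
    } else {
      int k = it - n_warmup;
      draws.row(k) = theta.t();
      treedepths[k] = res.treedepth;
      if (res.divergent) ++n_divergent;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["draws"] = draws,
    _["n_divergent"] = n_divergent,
    _["step_size"] = std::exp(log_eps_bar),
    _["treedepths"] = treedepths,
    _["inv_metric"] = NumericVector(H.inv_m.begin(), H.inv_m.end()));
}
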