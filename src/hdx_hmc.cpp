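// Fast paths for the kinetic-model log posterior, its gradient, and the
// Hamiltonian Monte Carlo trajectory loop. The math mirrors the reference
// R implementation in R/models.R one-to-one; tests assert agreement.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

constexpr double LOG_SQRT_2PI = 0.918938533204672742;

struct Model {
  int family;            // 0 logistic, 1 weibull, 2 weibull_re
  int nb;                // parameter blocks (1 or C)
  int dim;
  int n_grp;
  NumericVector y, t, logt;
  IntegerVector block;   // 1-based
  IntegerVector grp;     // 1-based, length 0 unless RE
  // prior hyperparameters
  double d_loc, d_scale, a_loc, a_scale, b_loc, b_scale,
         p_loc, p_scale, sigma_rate, tau_scale;
  // 1-based index vectors into theta
  IntegerVector i_d, i_la, i_lb, i_lp, i_ls;
  int i_ltau;            // 1-based, 0 if absent
  IntegerVector i_u;
  bool has_p, re;
  bool prior_only;
};

Model unpack(const List& m) {
  Model M;
  M.family = as<int>(m["family"]);
  M.nb = as<int>(m["nb"]);
  M.dim = as<int>(m["dim"]);
  M.n_grp = as<int>(m["n_grp"]);
  M.y = m["y"]; M.t = m["t"]; M.logt = m["logt"];
  M.block = m["block"]; M.grp = m["grp"];
  NumericVector h = m["prior"];
  M.d_loc = h[0]; M.d_scale = h[1]; M.a_loc = h[2]; M.a_scale = h[3];
  M.b_loc = h[4]; M.b_scale = h[5]; M.p_loc = h[6]; M.p_scale = h[7];
  M.sigma_rate = h[8]; M.tau_scale = h[9];
  M.i_d = m["i_d"]; M.i_la = m["i_la"]; M.i_lb = m["i_lb"];
  M.i_lp = m["i_lp"]; M.i_ls = m["i_ls"];
  M.i_ltau = as<int>(m["i_ltau"]);
  M.i_u = m["i_u"];
  M.has_p = M.family != 0;
  M.re = M.family == 2;
  M.prior_only = as<bool>(m["prior_only"]);
  return M;
}

// log prior (+ Jacobian) and optionally its gradient
double log_prior(const Model& M, const double* th, double* gr) {
  double lp = 0.0;
  for (int k = 0; k < M.nb; ++k) {
    double d = th[M.i_d[k] - 1];
    double la = th[M.i_la[k] - 1];
    double lb = th[M.i_lb[k] - 1];
    double ls = th[M.i_ls[k] - 1];
    double sg = std::exp(ls);
    lp += R::dnorm(d, M.d_loc, M.d_scale, 1);
    lp += R::dnorm(la, M.a_loc, M.a_scale, 1);
    lp += R::dnorm(lb, M.b_loc, M.b_scale, 1);
    lp += R::dexp(sg, 1.0 / M.sigma_rate, 1) + ls;
    if (gr) {
      gr[M.i_d[k] - 1] += -(d - M.d_loc) / (M.d_scale * M.d_scale);
      gr[M.i_la[k] - 1] += -(la - M.a_loc) / (M.a_scale * M.a_scale);
      gr[M.i_lb[k] - 1] += -(lb - M.b_loc) / (M.b_scale * M.b_scale);
      gr[M.i_ls[k] - 1] += 1.0 - M.sigma_rate * sg;
    }
    if (M.has_p) {
      double lpv = th[M.i_lp[k] - 1];
      lp += R::dnorm(lpv, M.p_loc, M.p_scale, 1);
      if (gr) gr[M.i_lp[k] - 1] += -(lpv - M.p_loc) / (M.p_scale * M.p_scale);
    }
  }
  if (M.re) {
    double ltau = th[M.i_ltau - 1];
    double tau = std::exp(ltau);
    lp += -tau * tau / (2.0 * M.tau_scale * M.tau_scale) + ltau +
          std::log(2.0) - std::log(M.tau_scale) - LOG_SQRT_2PI;
    if (gr) gr[M.i_ltau - 1] += 1.0 - tau * tau / (M.tau_scale * M.tau_scale);
    for (int j = 0; j < M.n_grp; ++j) {
      double u = th[M.i_u[j] - 1];
      lp += R::dnorm(u, 0.0, 1.0, 1);
      if (gr) gr[M.i_u[j] - 1] += -u;
    }
  }
  return lp;
}

// joint log posterior; fills grad if non-null; fills ll_i if non-null
double log_post(const Model& M, const double* th, double* gr, double* ll_i) {
  double lp;
  if (gr) {
    std::fill(gr, gr + M.dim, 0.0);
    lp = log_prior(M, th, gr);
  } else {
    lp = log_prior(M, th, nullptr);
  }
  if (!std::isfinite(lp)) return R_NegInf;
  if (M.prior_only && !ll_i) return lp;

  const int n = M.y.size();
  double tau = 0.0;
  if (M.re) tau = std::exp(th[M.i_ltau - 1]);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = M.block[i] - 1;
    double d = th[M.i_d[k] - 1];
    double a = std::exp(th[M.i_la[k] - 1]);
    double b = std::exp(th[M.i_lb[k] - 1]);
    double sg = std::exp(th[M.i_ls[k] - 1]);
    double A = a;
    double uraw = 0.0;
    int gj = -1;
    if (M.re) {
      gj = M.grp[i] - 1;
      uraw = th[M.i_u[gj] - 1];
      A += tau * uraw;
    }
    double ti = M.t[i], lti = M.logt[i];
    double g, dmu_db = 0.0, dmu_dp = 0.0;
    if (M.family == 0) {
      if (ti > 0) {
        double s = 1.0 / (1.0 + std::exp(-b * lti));
        g = s;
        dmu_db = A * s * (1.0 - s) * lti;
      } else g = 0.0;
    } else {
      if (ti > 0) {
        double p = std::exp(th[M.i_lp[k] - 1]);
        double q = std::pow(b * ti, p);
        double E = std::exp(-q);
        g = -std::expm1(-q);
        dmu_db = A * E * q * p / b;
        dmu_dp = A * E * q * (lti + std::log(b));
      } else g = 0.0;
    }
    double mu = d + A * g;
    double r = M.y[i] - mu;
    double li = -std::log(sg) - LOG_SQRT_2PI - r * r / (2.0 * sg * sg);
    if (ll_i) ll_i[i] = li;
    ll += li;
    if (gr && !M.prior_only) {
      double w = r / (sg * sg);
      gr[M.i_d[k] - 1] += w;
      gr[M.i_la[k] - 1] += w * g * a;
      gr[M.i_lb[k] - 1] += w * dmu_db * b;
      if (M.has_p) {
        double p = std::exp(th[M.i_lp[k] - 1]);
        gr[M.i_lp[k] - 1] += (ti > 0 ? w * dmu_dp * p : 0.0);
      }
      gr[M.i_ls[k] - 1] += -1.0 + r * r / (sg * sg);
      if (M.re) {
        gr[M.i_u[gj] - 1] += w * g * tau;
        gr[M.i_ltau - 1] += w * g * uraw * tau;
      }
    }
  }
  if (!std::isfinite(ll)) return R_NegInf;
  return M.prior_only ? lp : lp + ll;
}

} // namespace

// [[Rcpp::export]]
double cpp_lp(List model, NumericVector theta) {
  Model M = unpack(model);
  return log_post(M, theta.begin(), nullptr, nullptr);
}

// [[Rcpp::export]]
NumericVector cpp_grad(List model, NumericVector theta) {
  Model M = unpack(model);
  NumericVector g(M.dim);
  log_post(M, theta.begin(), g.begin(), nullptr);
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_lp_many(List model, NumericMatrix thetas) {
  Model M = unpack(model);
  const int S = thetas.nrow();
  NumericVector out(S);
  std::vector<double> th(M.dim);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < M.dim; ++j) th[j] = thetas(s, j);
    out[s] = log_post(M, th.data(), nullptr, nullptr);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ll_matrix(List model, NumericMatrix thetas) {
  Model M = unpack(model);
  const int S = thetas.nrow(), n = M.y.size();
  NumericMatrix out(S, n);
  std::vector<double> th(M.dim), ll(n);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < M.dim; ++j) th[j] = thetas(s, j);
    log_post(M, th.data(), nullptr, ll.data());
    for (int i = 0; i < n; ++i) out(s, i) = ll[i];
  }
  return out;
}

// One HMC chain: dual-averaging step size, diagonal mass matrix estimated
// from the middle warmup window, jittered leapfrog path lengths. Uses R's
// RNG so runs are reproducible from set.seed().
// [[Rcpp::export]]
List cpp_hmc_chain(List model, NumericVector theta0, int warmup, int samples,
                   double target_accept, int max_leapfrog) {
  Model M = unpack(model);
  const int dim = M.dim;
  RNGScope scope;

  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> cur_gr(dim), g(dim), th(dim), p(dim), inv_mass(dim, 1.0);
  double cur_lp = log_post(M, theta.data(), cur_gr.data(), nullptr);
  if (!std::isfinite(cur_lp)) stop("non-finite log posterior at initial value");

  // initial step size: halve until a single step keeps |dH| moderate
  double eps = 0.1;
  for (int k = 0; k < 30; ++k) {
    double H0 = cur_lp, Hk = 0.0;
    for (int j = 0; j < dim; ++j) { p[j] = norm_rand(); H0 -= 0.5 * p[j] * p[j]; }
    for (int j = 0; j < dim; ++j) p[j] += 0.5 * eps * cur_gr[j];
    for (int j = 0; j < dim; ++j) th[j] = theta[j] + eps * p[j];
    double lp1 = log_post(M, th.data(), g.data(), nullptr);
    bool fin = std::isfinite(lp1);
    if (fin) {
      for (int j = 0; j < dim; ++j) p[j] += 0.5 * eps * g[j];
      Hk = lp1;
      for (int j = 0; j < dim; ++j) Hk -= 0.5 * p[j] * p[j];
      if (std::isfinite(Hk) && std::fabs(Hk - H0) < 2.0) break;
    }
    eps *= 0.5;
  }

  double mu_da = std::log(10.0 * eps);
  double log_eps_bar = 0.0, H_bar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int n_adapt = 0;

  const int total = warmup + samples;
  NumericMatrix draws(samples, dim);
  NumericVector lps(samples);
  double accept_sum = 0.0;
  int divergences = 0;
  const int win_lo = (int)std::floor(warmup * 0.25);
  const int win_hi = (int)std::floor(warmup * 0.75);
  std::vector<double> wsum(dim, 0.0), wsum2(dim, 0.0);
  int wn = 0;

  for (int it = 1; it <= total; ++it) {
    double ke0 = 0.0;
    for (int j = 0; j < dim; ++j) {
      p[j] = norm_rand() / std::sqrt(inv_mass[j]);
      ke0 += 0.5 * inv_mass[j] * p[j] * p[j];
    }
    int L = 1 + (int)std::floor(unif_rand() * max_leapfrog);
    if (L > max_leapfrog) L = max_leapfrog;
    std::copy(theta.begin(), theta.end(), th.begin());
    std::copy(cur_gr.begin(), cur_gr.end(), g.begin());
    bool ok = true;
    double new_lp = 0.0, dH = 0.0;
    for (int j = 0; j < dim; ++j) p[j] += 0.5 * eps * g[j];
    for (int l = 0; l < L && ok; ++l) {
      for (int j = 0; j < dim; ++j) th[j] += eps * inv_mass[j] * p[j];
      new_lp = log_post(M, th.data(), g.data(), nullptr);
      ok = std::isfinite(new_lp);
      if (ok) {
        double half = (l < L - 1) ? eps : 0.5 * eps;
        for (int j = 0; j < dim; ++j) {
          p[j] += half * g[j];
          if (!std::isfinite(p[j])) { ok = false; break; }
        }
      }
    }
    double alpha = 0.0;
    if (ok) {
      double ke1 = 0.0;
      for (int j = 0; j < dim; ++j) ke1 += 0.5 * inv_mass[j] * p[j] * p[j];
      dH = (new_lp - ke1) - (cur_lp - ke0);
      if (!std::isfinite(dH) || dH < -1000.0) ok = false;
    }
    if (ok) {
      alpha = dH >= 0 ? 1.0 : std::exp(dH);
      if (unif_rand() < alpha) {
        std::copy(th.begin(), th.end(), theta.begin());
        cur_lp = new_lp;
        log_post(M, theta.data(), cur_gr.data(), nullptr);
      }
    } else {
      if (it > warmup) ++divergences;
      unif_rand();  // keep the stream aligned across outcomes
    }

    if (it <= warmup) {
      ++n_adapt;
      H_bar = (1.0 - 1.0 / (n_adapt + t0)) * H_bar +
              (target_accept - alpha) / (n_adapt + t0);
      double log_eps = mu_da - std::sqrt((double)n_adapt) / gamma * H_bar;
      double w = std::pow((double)n_adapt, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      if (it > win_lo && it <= win_hi) {
        ++wn;
        for (int j = 0; j < dim; ++j) {
          wsum[j] += theta[j];
          wsum2[j] += theta[j] * theta[j];
        }
      }
      if (it == win_hi && wn > 10) {
        for (int j = 0; j < dim; ++j) {
          double v = (wsum2[j] - wsum[j] * wsum[j] / wn) / (wn - 1);
          if (!std::isfinite(v) || v <= 0) v = 1e-6;
          inv_mass[j] = (wn / (wn + 5.0)) * v + (5.0 / (wn + 5.0)) * 1e-3;
        }
        mu_da = std::log(10.0 * eps);
        H_bar = 0.0; log_eps_bar = std::log(eps); n_adapt = 0;
      }
      if (it == warmup) eps = std::exp(log_eps_bar);
    } else {
      for (int j = 0; j < dim; ++j) draws(it - warmup - 1, j) = theta[j];
      lps[it - warmup - 1] = cur_lp;
      accept_sum += alpha;
    }
  }
  return List::create(_["draws"] = draws, _["lp"] = lps, _["eps"] = eps,
                      _["accept_rate"] = accept_sum / samples,
                      _["divergences"] = divergences);
}
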