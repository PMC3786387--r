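// Adaptive Metropolis-within-Gibbs sampler for the nested-domain robust
// regression model.  Proposal scales adapt (Robbins-Monro on the log scale,
// target acceptance 0.4) during the adaptation phase only, then freeze so
// the chain is Markovian, mirroring JAGS adaptation semantics.
//
// Parameter vector layout (length P):
//   [0]                beta
//   [1 .. D]           delta (domain deviations)
//   [D+1 .. D+J]       eps (outcome deviations)
//   [.. +J]            alpha (intercepts)
//   [.. +J*k]          gamma (covariate coefficients, gamma[j + J*c])
//   [.. +J]            sigma (residual scales)
//   [..]               sigma_domain, sigma_outcome
//   [..]               u = 1/nu (1 value, or J under per-outcome nu)
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct ColData {
  std::vector<double> y;   // observed outcome values
  std::vector<double> x;   // matching biomarker values
  std::vector<double> C;   // matching covariates, column-major (nobs x k)
  int nobs;
};

struct Spec {
  int n, J, D, k;
  std::vector<int> dom;            // 0-based domain per outcome
  bool hier, intercept, per_nu;
  bool fix_sigma, fix_nu;
  std::vector<double> sigma_fixed;
  double nu_fixed;
  double osd, cauchy, sigma_up, u_lo, u_hi;  // prior hyperparameters
};

struct State {
  double beta;
  std::vector<double> delta, eps, alpha, gamma, sigma, u;
  double sD, sO;
};

double col_loglik(const ColData& cd, const Spec& sp, int j,
                  double beta, const std::vector<double>& delta,
                  const std::vector<double>& eps,
                  const std::vector<double>& alpha,
                  const std::vector<double>& gamma,
                  double sigma_j, double nu) {
  double theta = beta;
  if (sp.hier) theta += delta[sp.dom[j]] + eps[j];
  const double a = sp.intercept ? alpha[j] : 0.0;
  const double cst = R::lgammafn((nu + 1.0) / 2.0) - R::lgammafn(nu / 2.0)
    - 0.5 * std::log(nu * M_PI) - std::log(sigma_j);
  const double inv2 = 1.0 / (nu * sigma_j * sigma_j);
  double ll = cd.nobs * cst;
  for (int i = 0; i < cd.nobs; ++i) {
    double mu = a + theta * cd.x[i];
    for (int c = 0; c < sp.k; ++c) mu += gamma[j + sp.J * c] * cd.C[i + cd.nobs * c];
    const double r = cd.y[i] - mu;
    ll -= 0.5 * (nu + 1.0) * std::log1p(r * r * inv2);
  }
  return ll;
}

double get_sigma(const Spec& sp, const State& st, int j) {
  return sp.fix_sigma ? sp.sigma_fixed[j] : st.sigma[j];
}

double get_nu(const Spec& sp, const State& st, int j) {
  if (sp.fix_nu) return sp.nu_fixed;
  return 1.0 / (sp.per_nu ? st.u[j] : st.u[0]);
}

double half_cauchy_log(double x, double scale) {
  if (x < 0) return R_NegInf;
  return std::log(2.0) - std::log(M_PI * scale * (1.0 + (x / scale) * (x / scale)));
}

double log_prior_state(const Spec& sp, const State& st) {
  double lp = R::dnorm(st.beta, 0.0, sp.osd, 1);
  if (sp.intercept)
    for (int j = 0; j < sp.J; ++j) lp += R::dnorm(st.alpha[j], 0.0, sp.osd, 1);
  for (size_t i = 0; i < st.gamma.size(); ++i)
    lp += R::dnorm(st.gamma[i], 0.0, sp.osd, 1);
  if (sp.hier) {
    if (st.sD <= 0 || st.sO <= 0) return R_NegInf;
    lp += half_cauchy_log(st.sD, sp.cauchy) + half_cauchy_log(st.sO, sp.cauchy);
    for (int d = 0; d < sp.D; ++d) lp += R::dnorm(st.delta[d], 0.0, st.sD, 1);
    for (int j = 0; j < sp.J; ++j) lp += R::dnorm(st.eps[j], 0.0, st.sO, 1);
  }
  if (!sp.fix_sigma) {
    for (int j = 0; j < sp.J; ++j) {
      if (st.sigma[j] <= 0 || st.sigma[j] >= sp.sigma_up) return R_NegInf;
      lp += -std::log(sp.sigma_up);
    }
  }
  if (!sp.fix_nu) {
    for (size_t i = 0; i < st.u.size(); ++i) {
      if (st.u[i] < sp.u_lo || st.u[i] > sp.u_hi) return R_NegInf;
      lp += -std::log(sp.u_hi - sp.u_lo);
    }
  }
  return lp;
}

Spec build_spec(int n, const IntegerVector& dom, int n_domains, int k,
                const List& opts) {
  Spec sp;
  sp.n = n; sp.J = dom.size(); sp.D = n_domains; sp.k = k;
  sp.dom.resize(sp.J);
  for (int j = 0; j < sp.J; ++j) sp.dom[j] = dom[j] - 1;
  sp.hier = as<bool>(opts["hierarchical"]);
  sp.intercept = as<bool>(opts["intercept"]);
  sp.per_nu = as<bool>(opts["per_outcome_nu"]);
  sp.fix_sigma = !Rf_isNull(opts["fix_sigma"]);
  if (sp.fix_sigma) sp.sigma_fixed = as<std::vector<double>>(opts["fix_sigma"]);
  sp.fix_nu = !Rf_isNull(opts["fix_nu"]);
  sp.nu_fixed = sp.fix_nu ? as<double>(opts["fix_nu"]) : 0.0;
  NumericVector pr = opts["priors"];  // osd, cauchy, sigma_upper, u_lo, u_hi
  sp.osd = pr[0]; sp.cauchy = pr[1]; sp.sigma_up = pr[2];
  sp.u_lo = pr[3]; sp.u_hi = pr[4];
  return sp;
}

std::vector<ColData> build_cols(const NumericVector& x, const NumericMatrix& Y,
                                const NumericMatrix& C, const Spec& sp) {
  std::vector<ColData> cols(sp.J);
  for (int j = 0; j < sp.J; ++j) {
    ColData cd; cd.nobs = 0;
    for (int i = 0; i < sp.n; ++i) if (!NumericVector::is_na(Y(i, j))) ++cd.nobs;
    cd.y.reserve(cd.nobs); cd.x.reserve(cd.nobs); cd.C.resize((size_t)cd.nobs * sp.k);
    int m = 0;
    for (int i = 0; i < sp.n; ++i) {
      if (NumericVector::is_na(Y(i, j))) continue;
      cd.y.push_back(Y(i, j));
      cd.x.push_back(x[i]);
      for (int c = 0; c < sp.k; ++c) cd.C[m + cd.nobs * c] = C(i, c);
      ++m;
    }
    cols[j] = std::move(cd);
  }
  return cols;
}

State unpack(const NumericVector& v, const Spec& sp) {
  State st;
  int p = 0;
  st.beta = v[p++];
  st.delta.assign(sp.D, 0.0);
  for (int d = 0; d < sp.D; ++d) st.delta[d] = v[p++];
  st.eps.assign(sp.J, 0.0);
  for (int j = 0; j < sp.J; ++j) st.eps[j] = v[p++];
  st.alpha.assign(sp.J, 0.0);
  for (int j = 0; j < sp.J; ++j) st.alpha[j] = v[p++];
  st.gamma.assign((size_t)sp.J * sp.k, 0.0);
  for (size_t i = 0; i < st.gamma.size(); ++i) st.gamma[i] = v[p++];
  st.sigma.assign(sp.J, 1.0);
  for (int j = 0; j < sp.J; ++j) st.sigma[j] = v[p++];
  st.sD = v[p++]; st.sO = v[p++];
  int nu_len = sp.per_nu ? sp.J : 1;
  st.u.assign(nu_len, 0.1);
  for (int i = 0; i < nu_len; ++i) st.u[i] = v[p++];
  return st;
}

void pack(const State& st, const Spec& sp, double* row) {
  int p = 0;
  row[p++] = st.beta;
  for (int d = 0; d < sp.D; ++d) row[p++] = st.delta[d];
  for (int j = 0; j < sp.J; ++j) row[p++] = st.eps[j];
  for (int j = 0; j < sp.J; ++j) row[p++] = st.alpha[j];
  for (size_t i = 0; i < st.gamma.size(); ++i) row[p++] = st.gamma[i];
  for (int j = 0; j < sp.J; ++j) row[p++] = st.sigma[j];
  row[p++] = st.sD; row[p++] = st.sO;
  for (size_t i = 0; i < st.u.size(); ++i) row[p++] = st.u[i];
}

struct Adapt {
  double ls;      // log proposal scale
  long prop = 0, acc = 0;  // counted after adaptation only
  double scale() const { return std::exp(ls); }
  void tally(bool accepted, bool adapting, long t) {
    if (adapting) {
      double g = std::min(0.25, 5.0 / std::sqrt((double)t + 1.0));
      ls += g * ((accepted ? 1.0 : 0.0) - 0.4);
      ls = std::max(-12.0, std::min(6.0, ls));
    } else {
      ++prop; if (accepted) ++acc;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
double cpp_log_posterior(NumericVector state, NumericVector x, NumericMatrix Y,
                         NumericMatrix C, IntegerVector dom, int n_domains,
                         List opts) {
  Spec sp = build_spec(x.size(), dom, n_domains, C.ncol(), opts);
  std::vector<ColData> cols = build_cols(x, Y, C, sp);
  State st = unpack(state, sp);
  double lp = log_prior_state(sp, st);
  if (!std::isfinite(lp)) return lp;
  for (int j = 0; j < sp.J; ++j)
    lp += col_loglik(cols[j], sp, j, st.beta, st.delta, st.eps, st.alpha,
                     st.gamma, get_sigma(sp, st, j), get_nu(sp, st, j));
  return lp;
}

// [[Rcpp::export]]
List run_chain_cpp(NumericVector x, NumericMatrix Y, NumericMatrix C,
                   IntegerVector dom, int n_domains, List opts,
                   NumericVector init, int n_adapt, int n_burn,
                   int n_save, int thin) {
  Spec sp = build_spec(x.size(), dom, n_domains, C.ncol(), opts);
  std::vector<ColData> cols = build_cols(x, Y, C, sp);
  State st = unpack(init, sp);
  const int P = init.size();

  // cached per-column log-likelihoods
  std::vector<double> cl(sp.J);
  for (int j = 0; j < sp.J; ++j)
    cl[j] = col_loglik(cols[j], sp, j, st.beta, st.delta, st.eps, st.alpha,
                       st.gamma, get_sigma(sp, st, j), get_nu(sp, st, j));

  const bool do_ag = sp.intercept || sp.k > 0;
  std::vector<Adapt> ad_ag(sp.J), ad_eps(sp.J), ad_sig(sp.J), ad_delta(sp.D),
      ad_tr(sp.D);
  Adapt ad_beta, ad_sD, ad_sO, ad_tr0;
  std::vector<Adapt> ad_u(sp.per_nu ? sp.J : 1);
  double loc0 = std::log(2.5 / std::sqrt((double)sp.n));
  for (int j = 0; j < sp.J; ++j) {
    ad_ag[j].ls = loc0; ad_eps[j].ls = loc0; ad_sig[j].ls = loc0;
  }
  ad_beta.ls = loc0;
  for (int d = 0; d < sp.D; ++d) ad_delta[d].ls = loc0;
  ad_sD.ls = std::log(0.5); ad_sO.ls = std::log(0.5);
  ad_tr0.ls = std::log(0.1);
  for (int d = 0; d < sp.D; ++d) ad_tr[d].ls = std::log(0.1);
  for (size_t i = 0; i < ad_u.size(); ++i) ad_u[i].ls = std::log(0.02);

  const long total = (long)n_adapt + n_burn + (long)n_save * thin;
  NumericMatrix draws(n_save, P);
  int saved = 0;
  RNGScope scope;

  std::vector<double> alpha_prop, gamma_prop;
  for (long t = 0; t < total; ++t) {
    const bool adapting = t < n_adapt;

    // -- per-outcome location block: (alpha_j, gamma_j.) --------------------
    if (do_ag) {
      for (int j = 0; j < sp.J; ++j) {
        const double s = ad_ag[j].scale();
        alpha_prop = st.alpha; gamma_prop = st.gamma;
        double dpr = 0.0;
        if (sp.intercept) {
          alpha_prop[j] = st.alpha[j] + s * norm_rand();
          dpr += R::dnorm(alpha_prop[j], 0, sp.osd, 1) -
                 R::dnorm(st.alpha[j], 0, sp.osd, 1);
        }
        for (int c = 0; c < sp.k; ++c) {
          const size_t idx = j + (size_t)sp.J * c;
          gamma_prop[idx] = st.gamma[idx] + s * norm_rand();
          dpr += R::dnorm(gamma_prop[idx], 0, sp.osd, 1) -
                 R::dnorm(st.gamma[idx], 0, sp.osd, 1);
        }
        const double ll = col_loglik(cols[j], sp, j, st.beta, st.delta, st.eps,
                                     alpha_prop, gamma_prop,
                                     get_sigma(sp, st, j), get_nu(sp, st, j));
        const bool acc = std::log(unif_rand()) < ll - cl[j] + dpr;
        if (acc) { st.alpha = alpha_prop; st.gamma = gamma_prop; cl[j] = ll; }
        ad_ag[j].tally(acc, adapting, t);
      }
    }

    // -- outcome deviations eps_j ------------------------------------------
    if (sp.hier) {
      for (int j = 0; j < sp.J; ++j) {
        const double ep = st.eps[j] + ad_eps[j].scale() * norm_rand();
        std::vector<double> eps_prop = st.eps; eps_prop[j] = ep;
        const double ll = col_loglik(cols[j], sp, j, st.beta, st.delta,
                                     eps_prop, st.alpha, st.gamma,
                                     get_sigma(sp, st, j), get_nu(sp, st, j));
        const double dpr = R::dnorm(ep, 0, st.sO, 1) -
                           R::dnorm(st.eps[j], 0, st.sO, 1);
        const bool acc = std::log(unif_rand()) < ll - cl[j] + dpr;
        if (acc) { st.eps[j] = ep; cl[j] = ll; }
        ad_eps[j].tally(acc, adapting, t);
      }
    }

    // -- residual scales sigma_j -------------------------------------------
    if (!sp.fix_sigma) {
      for (int j = 0; j < sp.J; ++j) {
        const double sg = st.sigma[j] + ad_sig[j].scale() * norm_rand();
        bool acc = false;
        if (sg > 0 && sg < sp.sigma_up) {
          const double ll = col_loglik(cols[j], sp, j, st.beta, st.delta,
                                       st.eps, st.alpha, st.gamma, sg,
                                       get_nu(sp, st, j));
          acc = std::log(unif_rand()) < ll - cl[j];
          if (acc) { st.sigma[j] = sg; cl[j] = ll; }
        }
        ad_sig[j].tally(acc, adapting, t);
      }
    }

    // -- overall slope beta -------------------------------------------------
    {
      const double bp = st.beta + ad_beta.scale() * norm_rand();
      std::vector<double> ll(sp.J);
      double llsum = 0, clsum = 0;
      for (int j = 0; j < sp.J; ++j) {
        ll[j] = col_loglik(cols[j], sp, j, bp, st.delta, st.eps, st.alpha,
                           st.gamma, get_sigma(sp, st, j), get_nu(sp, st, j));
        llsum += ll[j]; clsum += cl[j];
      }
      const double dpr = R::dnorm(bp, 0, sp.osd, 1) -
                         R::dnorm(st.beta, 0, sp.osd, 1);
      const bool acc = std::log(unif_rand()) < llsum - clsum + dpr;
      if (acc) { st.beta = bp; cl = ll; }
      ad_beta.tally(acc, adapting, t);
    }

    if (sp.hier) {
      // -- domain deviations delta_d ---------------------------------------
      for (int d = 0; d < sp.D; ++d) {
        const double dp = st.delta[d] + ad_delta[d].scale() * norm_rand();
        std::vector<double> delta_prop = st.delta; delta_prop[d] = dp;
        double llsum = 0, clsum = 0;
        std::vector<std::pair<int, double>> touched;
        for (int j = 0; j < sp.J; ++j) {
          if (sp.dom[j] != d) continue;
          const double ll = col_loglik(cols[j], sp, j, st.beta, delta_prop,
                                       st.eps, st.alpha, st.gamma,
                                       get_sigma(sp, st, j), get_nu(sp, st, j));
          touched.push_back({j, ll});
          llsum += ll; clsum += cl[j];
        }
        const double dpr = R::dnorm(dp, 0, st.sD, 1) -
                           R::dnorm(st.delta[d], 0, st.sD, 1);
        const bool acc = std::log(unif_rand()) < llsum - clsum + dpr;
        if (acc) {
          st.delta[d] = dp;
          for (auto& pr : touched) cl[pr.first] = pr.second;
        }
        ad_delta[d].tally(acc, adapting, t);
      }

      // -- ridge translation moves -----------------------------------------
      // theta_j = beta + delta_d + eps_j is invariant under
      // (beta + e, delta - e) and (delta_d + e, eps_{j in d} - e), so these
      // moves leave the likelihood untouched and only face the priors;
      // they decorrelate the overall slope from the deviations.
      {
        const double e = ad_tr0.scale() * norm_rand();
        double ratio = R::dnorm(st.beta + e, 0, sp.osd, 1) -
                       R::dnorm(st.beta, 0, sp.osd, 1);
        for (int d = 0; d < sp.D; ++d)
          ratio += R::dnorm(st.delta[d] - e, 0, st.sD, 1) -
                   R::dnorm(st.delta[d], 0, st.sD, 1);
        const bool acc = std::log(unif_rand()) < ratio;
        if (acc) {
          st.beta += e;
          for (int d = 0; d < sp.D; ++d) st.delta[d] -= e;
        }
        ad_tr0.tally(acc, adapting, t);
      }
      for (int d = 0; d < sp.D; ++d) {
        const double e = ad_tr[d].scale() * norm_rand();
        double ratio = R::dnorm(st.delta[d] + e, 0, st.sD, 1) -
                       R::dnorm(st.delta[d], 0, st.sD, 1);
        for (int j = 0; j < sp.J; ++j) {
          if (sp.dom[j] != d) continue;
          ratio += R::dnorm(st.eps[j] - e, 0, st.sO, 1) -
                   R::dnorm(st.eps[j], 0, st.sO, 1);
        }
        const bool acc = std::log(unif_rand()) < ratio;
        if (acc) {
          st.delta[d] += e;
          for (int j = 0; j < sp.J; ++j)
            if (sp.dom[j] == d) st.eps[j] -= e;
        }
        ad_tr[d].tally(acc, adapting, t);
      }

      // -- hierarchical deviation SDs --------------------------------------
      {
        const double sdp = st.sD + ad_sD.scale() * norm_rand();
        bool acc = false;
        if (sdp > 0) {
          double ratio = half_cauchy_log(sdp, sp.cauchy) -
                         half_cauchy_log(st.sD, sp.cauchy);
          for (int d = 0; d < sp.D; ++d)
            ratio += R::dnorm(st.delta[d], 0, sdp, 1) -
                     R::dnorm(st.delta[d], 0, st.sD, 1);
          acc = std::log(unif_rand()) < ratio;
          if (acc) st.sD = sdp;
        }
        ad_sD.tally(acc, adapting, t);
      }
      {
        const double sop = st.sO + ad_sO.scale() * norm_rand();
        bool acc = false;
        if (sop > 0) {
          double ratio = half_cauchy_log(sop, sp.cauchy) -
                         half_cauchy_log(st.sO, sp.cauchy);
          for (int j = 0; j < sp.J; ++j)
            ratio += R::dnorm(st.eps[j], 0, sop, 1) -
                     R::dnorm(st.eps[j], 0, st.sO, 1);
          acc = std::log(unif_rand()) < ratio;
          if (acc) st.sO = sop;
        }
        ad_sO.tally(acc, adapting, t);
      }
    }

    // -- degrees of freedom (on the u = 1/nu scale) ------------------------
    if (!sp.fix_nu) {
      if (sp.per_nu) {
        for (int j = 0; j < sp.J; ++j) {
          const double up = st.u[j] + ad_u[j].scale() * norm_rand();
          bool acc = false;
          if (up >= sp.u_lo && up <= sp.u_hi) {
            const double ll = col_loglik(cols[j], sp, j, st.beta, st.delta,
                                         st.eps, st.alpha, st.gamma,
                                         get_sigma(sp, st, j), 1.0 / up);
            acc = std::log(unif_rand()) < ll - cl[j];
            if (acc) { st.u[j] = up; cl[j] = ll; }
          }
          ad_u[j].tally(acc, adapting, t);
        }
      } else {
        const double up = st.u[0] + ad_u[0].scale() * norm_rand();
        bool acc = false;
        if (up >= sp.u_lo && up <= sp.u_hi) {
          std::vector<double> ll(sp.J);
          double llsum = 0, clsum = 0;
          for (int j = 0; j < sp.J; ++j) {
            ll[j] = col_loglik(cols[j], sp, j, st.beta, st.delta, st.eps,
                               st.alpha, st.gamma, get_sigma(sp, st, j),
                               1.0 / up);
            llsum += ll[j]; clsum += cl[j];
          }
          acc = std::log(unif_rand()) < llsum - clsum;
          if (acc) { st.u[0] = up; cl = ll; }
        }
        ad_u[0].tally(acc, adapting, t);
      }
    }

    if (t >= (long)n_adapt + n_burn &&
        ((t - n_adapt - n_burn + 1) % thin == 0) && saved < n_save) {
      std::vector<double> row(P);
      pack(st, sp, row.data());
      for (int p = 0; p < P; ++p) draws(saved, p) = row[p];
      ++saved;
    }
  }

  auto rate = [](const Adapt& a) {
    return a.prop > 0 ? (double)a.acc / a.prop : NA_REAL;
  };
  NumericVector acc_ag(sp.J), acc_eps(sp.J), acc_sig(sp.J), acc_delta(sp.D);
  for (int j = 0; j < sp.J; ++j) {
    acc_ag[j] = rate(ad_ag[j]); acc_eps[j] = rate(ad_eps[j]);
    acc_sig[j] = rate(ad_sig[j]);
  }
  for (int d = 0; d < sp.D; ++d) acc_delta[d] = rate(ad_delta[d]);
  NumericVector acc_u(ad_u.size());
  for (size_t i = 0; i < ad_u.size(); ++i) acc_u[i] = rate(ad_u[i]);

  return List::create(
    _["draws"] = draws,
    _["acceptance"] = List::create(
      _["alpha_gamma"] = acc_ag, _["eps"] = acc_eps, _["sigma"] = acc_sig,
      _["beta"] = rate(ad_beta), _["delta"] = acc_delta,
      _["translate_overall"] = rate(ad_tr0),
      _["sigma_domain"] = rate(ad_sD), _["sigma_outcome"] = rate(ad_sO),
      _["u"] = acc_u));
}
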