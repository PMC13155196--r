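#include <Rcpp.h>
using namespace Rcpp;

// link codes: 0 = cloglog, 1 = logistic, 2 = identical (cloglog incidence,
// one shared frailty). Draw storage convention: column i of u1/u2 holds the
// K retained draws for subject i; for cloglog u1 = x*y and u2 = y/2, for
// logistic (u1, u2) are the gamma and beta components, for identical both
// columns hold the single shared u.

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + log1p(exp((a < b ? a : b) - m));
}

// log pi(U=1) for linear predictor eta
static inline double log_pi_c(double eta, int link) {
  if (link == 1) { // logistic
    return eta > 0 ? -log1p(exp(-eta)) : eta - log1p(exp(eta));
  }
  return -exp(eta); // cloglog
}

static inline double log_1mpi_c(double eta, int link) {
  if (link == 1) {
    return eta > 0 ? -eta - log1p(exp(-eta)) : -log1p(exp(eta));
  }
  double a = exp(eta);
  if (a < 1e-10) return eta; // log(1 - exp(-a)) ~ log(a) = eta
  return log(-expm1(-a));
}

// log-likelihood of one subject's records given latency multiplier m and
// incidence log-frailty term w2; per-record contribution (up to constants
// free of the frailties): event: log pi + log m - Lam*ezb*m,
// censored: log(1 - pi + pi * exp(-Lam*ezb*m)).
static double subject_ll(int from, int to, const double* Lam,
                         const double* ezb, const double* vg,
                         const int* delta, double m, double w2, int link) {
  double ll = 0.0;
  for (int j = from; j < to; ++j) {
    double eta = vg[j] + w2;
    double ex = Lam[j] * ezb[j] * m;
    if (delta[j] == 1) {
      ll += log_pi_c(eta, link) + log(m) - ex;
    } else {
      ll += logsumexp2(log_1mpi_c(eta, link), log_pi_c(eta, link) - ex);
    }
  }
  return ll;
}

static inline double logit(double p) { return log(p) - log1p(-p); }
// keep beta-distributed states strictly inside (0,1); with shape < 1 the
// sampler can otherwise return exactly 0 or 1 in floating point
static inline double clamp01(double p) {
  const double eps = 1e-14;
  return p < eps ? eps : (p > 1.0 - eps ? 1.0 - eps : p);
}
static inline double expit(double z) {
  return z > 0 ? 1.0 / (1.0 + exp(-z)) : exp(z) / (1.0 + exp(z));
}

// Metropolis-within-Gibbs E-step. Each sweep updates every subject with an
// independence proposal from each prior component plus a random-walk proposal
// (log / logit scale), so chains mix even when the posterior is far from the
// prior. Returns K retained draws per subject plus acceptance diagnostics and
// final states for warm-starting the next EM iteration.
// [[Rcpp::export]]
List cf_mh_estep(IntegerVector subj_off, NumericVector Lam, NumericVector ezb,
                 NumericVector vg, IntegerVector delta, double alpha,
                 int link, int K, int burnin, int thin,
                 NumericVector state1, NumericVector state2) {
  const int N = subj_off.size() - 1;
  NumericMatrix du1(K, N), du2(K, N);
  NumericVector acc(N);
  const double* pLam = REAL(Lam);
  const double* pezb = REAL(ezb);
  const double* pvg = REAL(vg);
  const int* pdel = INTEGER(delta);
  std::vector<double> s1(state1.begin(), state1.end());
  std::vector<double> s2(state2.begin(), state2.end());
  std::vector<double> cur(N);
  std::vector<long> nacc(N, 0), nprop(N, 0);
  const double sw = 0.7; // random-walk step (log / logit scale)

  // state -> (m, w2)
  auto mw2 = [&](double a, double b, double& m, double& w2) {
    if (link == 0) { m = a * b; w2 = log(b / 2.0); }       // a=x, b=y
    else if (link == 1) { m = a * b; w2 = logit(b); }      // a=u1, b=u2
    else { m = a; w2 = log(a); }                           // a=u
  };
  auto ll_of = [&](int i, double a, double b) {
    double m, w2; mw2(a, b, m, w2);
    return subject_ll(subj_off[i], subj_off[i + 1], pLam, pezb, pvg, pdel,
                      m, w2, link);
  };
  for (int i = 0; i < N; ++i) cur[i] = ll_of(i, s1[i], s2[i]);

  int total = burnin + K * thin;
  int kept = 0;
  for (int sweep = 0; sweep < total; ++sweep) {
    bool do_ind = (sweep % 2) == 0; // alternate proposal kinds across sweeps
    for (int i = 0; i < N; ++i) {
      double a = s1[i], b = s2[i];
      // --- independence proposals from the prior components ---
      if (!do_ind) {
        // skip to the random-walk block below
      } else if (link == 0) {
        double ap = clamp01(R::rbeta(alpha, alpha));
        double lr = ll_of(i, ap, b) - cur[i];
        ++nprop[i];
        if (log(unif_rand()) < lr) { s1[i] = a = ap; cur[i] += lr; ++nacc[i]; }
        double bp = R::rgamma(2.0 * alpha, 1.0 / alpha);
        lr = ll_of(i, a, bp) - cur[i];
        ++nprop[i];
        if (log(unif_rand()) < lr) { s2[i] = b = bp; cur[i] += lr; ++nacc[i]; }
      } else if (link == 1) {
        double ap = R::rgamma(2.0 / alpha, alpha);
        double lr = ll_of(i, ap, b) - cur[i];
        ++nprop[i];
        if (log(unif_rand()) < lr) { s1[i] = a = ap; cur[i] += lr; ++nacc[i]; }
        double bp = clamp01(R::rbeta(1.0 / alpha, 1.0 / alpha));
        lr = ll_of(i, a, bp) - cur[i];
        ++nprop[i];
        if (log(unif_rand()) < lr) { s2[i] = b = bp; cur[i] += lr; ++nacc[i]; }
      } else {
        double ap = R::rgamma(alpha, 1.0 / alpha);
        double lr = ll_of(i, ap, b) - cur[i];
        ++nprop[i];
        if (log(unif_rand()) < lr) { s1[i] = a = ap; s2[i] = ap; cur[i] += lr; ++nacc[i]; }
      }
      // --- random-walk proposals (prior enters the ratio explicitly) ---
      if (do_ind) {
        // independence sweep done above
      } else if (link == 0) {
        // x on logit scale; Beta(alpha, alpha) prior, Jacobian x(1-x)
        double z = logit(a) + sw * norm_rand();
        double ap = clamp01(expit(z));
        if (ap > 0 && ap < 1) {
          double lr = ll_of(i, ap, b) - cur[i] +
            alpha * (log(ap) + log1p(-ap) - log(a) - log1p(-a));
          ++nprop[i];
          if (log(unif_rand()) < lr) {
            s1[i] = a = ap;
            cur[i] = ll_of(i, a, b);
            ++nacc[i];
          }
        }
        // y on log scale; Gamma(2 alpha, rate alpha) prior, Jacobian y
        double bp = b * exp(sw * norm_rand());
        double lr = ll_of(i, a, bp) - cur[i] +
          2.0 * alpha * (log(bp) - log(b)) - alpha * (bp - b);
        ++nprop[i];
        if (log(unif_rand()) < lr) { s2[i] = b = bp; cur[i] = ll_of(i, a, b); ++nacc[i]; }
      } else if (link == 1) {
        double ap = a * exp(sw * norm_rand());
        double lr = ll_of(i, ap, b) - cur[i] +
          (2.0 / alpha) * (log(ap) - log(a)) - (ap - a) / alpha;
        ++nprop[i];
        if (log(unif_rand()) < lr) { s1[i] = a = ap; cur[i] = ll_of(i, a, b); ++nacc[i]; }
        double z = logit(b) + sw * norm_rand();
        double bp = clamp01(expit(z));
        if (bp > 0 && bp < 1) {
          lr = ll_of(i, a, bp) - cur[i] +
            (1.0 / alpha) * (log(bp) + log1p(-bp) - log(b) - log1p(-b));
          ++nprop[i];
          if (log(unif_rand()) < lr) { s2[i] = b = bp; cur[i] = ll_of(i, a, b); ++nacc[i]; }
        }
      } else {
        double ap = a * exp(sw * norm_rand());
        double lr = ll_of(i, ap, b) - cur[i] +
          alpha * (log(ap) - log(a)) - alpha * (ap - a);
        ++nprop[i];
        if (log(unif_rand()) < lr) { s1[i] = ap; s2[i] = ap; cur[i] = ll_of(i, ap, ap); ++nacc[i]; }
      }
    }
    if (sweep >= burnin && ((sweep - burnin) % thin == 0) && kept < K) {
      for (int i = 0; i < N; ++i) {
        if (link == 0) { du1(kept, i) = s1[i] * s2[i]; du2(kept, i) = s2[i] / 2.0; }
        else { du1(kept, i) = s1[i]; du2(kept, i) = s2[i]; }
      }
      ++kept;
    }
  }
  for (int i = 0; i < N; ++i) acc[i] = nprop[i] ? (double)nacc[i] / nprop[i] : 1.0;
  return List::create(_["u1"] = du1, _["u2"] = du2, _["accept"] = acc,
                      _["state1"] = NumericVector(s1.begin(), s1.end()),
                      _["state2"] = NumericVector(s2.begin(), s2.end()));
}

// Per-record x per-draw posterior non-cure probabilities and the posterior
// latency weights used by the Breslow update and the latency objective:
// ubar_k(j,k) = E[U_j | draw k] (1 for events, Bayes posterior for censored),
// a[j] = mean_k ubar_k * m_k (joint expectation E[U m | data]),
// ubar[j] = mean_k ubar_k.
// [[Rcpp::export]]
List cf_ubar_stats(IntegerVector subj, NumericVector Lam, NumericVector ezb,
                   NumericVector vg, IntegerVector delta,
                   NumericMatrix u1, NumericMatrix u2, int link) {
  const int nrec = subj.size();
  const int K = u1.nrow();
  NumericMatrix ubar_k(nrec, K);
  NumericVector a(nrec), ubar(nrec);
  for (int j = 0; j < nrec; ++j) {
    int i = subj[j] - 1;
    double sa = 0.0, su = 0.0;
    for (int k = 0; k < K; ++k) {
      double m, w2;
      if (link == 0) { m = u1(k, i); w2 = log(u2(k, i)); }
      else if (link == 1) { m = u1(k, i) * u2(k, i); w2 = logit(u2(k, i)); }
      else { m = u1(k, i); w2 = log(m); }
      double ub;
      if (delta[j] == 1) {
        ub = 1.0;
      } else {
        double eta = vg[j] + w2;
        double lnum = log_pi_c(eta, link) - Lam[j] * ezb[j] * m;
        ub = exp(lnum - logsumexp2(log_1mpi_c(eta, link), lnum));
      }
      ubar_k(j, k) = ub;
      sa += ub * m;
      su += ub;
    }
    a[j] = sa / K;
    ubar[j] = su / K;
  }
  return List::create(_["ubar_k"] = ubar_k, _["a"] = a, _["ubar"] = ubar);
}

// Monte Carlo expected incidence log-likelihood, with per-record gradient and
// Hessian in the linear predictor (summed over draws, divided by K).
// mode 0: complete-data binomial form  sum_k [Ubar log pi + (1-Ubar) log(1-pi)]
// mode 1: as-printed form, which additionally counts delta*log pi for events
//         and the linearized censored survival term -(1-delta)*pi.
// [[Rcpp::export]]
List cf_inc_obj(NumericVector vg, NumericMatrix omega2, IntegerVector subj,
                IntegerVector delta, NumericMatrix ubar_k, int link,
                int mode, bool derivs) {
  const int nrec = vg.size();
  const int K = omega2.nrow();
  double val = 0.0;
  NumericVector gre(derivs ? nrec : 0), hes(derivs ? nrec : 0);
  for (int j = 0; j < nrec; ++j) {
    int i = subj[j] - 1;
    double vj = 0.0, gj = 0.0, hj = 0.0;
    int dj = delta[j];
    for (int k = 0; k < K; ++k) {
      double eta = vg[j] + omega2(k, i);
      double ub = ubar_k(j, k);
      double lp = log_pi_c(eta, link), l1p = log_1mpi_c(eta, link);
      double dlp, d1p, hlp, h1p, pi, dpi, hpi;
      if (link == 1) {
        pi = expit(eta);
        dlp = 1.0 - pi; d1p = -pi; hlp = h1p = -pi * (1.0 - pi);
        dpi = pi * (1.0 - pi); hpi = dpi * (1.0 - 2.0 * pi);
      } else {
        double aa = exp(eta);
        pi = exp(lp);
        dlp = -aa; hlp = -aa;
        d1p = aa * exp(lp - l1p);
        h1p = d1p * (1.0 - aa - d1p);
        dpi = -aa * pi; hpi = -aa * pi * (1.0 - aa);
      }
      vj += ub * lp + (1.0 - ub) * l1p;
      if (derivs) {
        gj += ub * dlp + (1.0 - ub) * d1p;
        hj += ub * hlp + (1.0 - ub) * h1p;
      }
      if (mode == 1) {
        vj += dj * lp - (1 - dj) * pi;
        if (derivs) {
          gj += dj * dlp - (1 - dj) * dpi;
          hj += dj * hlp - (1 - dj) * hpi;
        }
      }
    }
    val += vj / K;
    if (derivs) { gre[j] = gj / K; hes[j] = hj / K; }
  }
  return List::create(_["value"] = val, _["grad_eta"] = gre,
                      _["hess_eta"] = hes);
}
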