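#' Complete-data log-likelihood of the joint frailty mixture cure model
#'
#' Evaluates the complete-data log-likelihood treating the latent cure
#' statuses `U` and the frailties as known:
#' \deqn{l_c = \sum_{ij} (1-U_{ij})\log(1-\pi_{ij}) + \sum_{ij} U_{ij}\log
#'   \pi_{ij} + \sum_{ij} \log G_{ij} + \sum_i \log f(\omega_i),}
#' with \eqn{G_{ij} = f_1(t_{ij}\mid\omega_{1i})^{\delta_{ij}}
#' S(t_{ij}\mid\omega_i)^{1-\delta_{ij}}} (the censored factor is the mixture
#' survival, marginal on U) and \eqn{f(\omega)} the link-appropriate joint
#' frailty density.
#'
#' A record with an exactly degenerate \eqn{\pi \in \{0,1\}} contradicting its
#' `U` yields `-Inf` (with a warning), not an error.
#'
#' @param time,status Gap times and event indicators, one per record.
#' @param U Latent non-cure indicators per record; must be 1 wherever
#'   `status == 1`.
#' @param subj Integer subject index (1..N) per record.
#' @param lp Latency linear predictors \eqn{Z'\beta} per record.
#' @param veta Incidence linear predictors \eqn{V'\gamma} per record
#'   (excluding the frailty, which is added internally).
#' @param u1,u2 Frailty components, one per subject (for the identical model
#'   pass the shared `u` twice).
#' @param alpha Frailty heterogeneity parameter.
#' @param baseline A `cf_baseline` object.
#' @param link `"cloglog"`, `"logistic"` or `"identical"`.
#' @return The complete-data log-likelihood (scalar).
#' @export
loglik_complete <- function(time, status, U, subj, lp, veta, u1, u2, alpha,
                            baseline, link = c("cloglog", "logistic",
                                               "identical")) {
  link <- match.arg(link)
  if (any(status == 1 & U != 1)) {
    stop("U must be 1 for every event record (status == 1).", call. = FALSE)
  }
  fr <- frailty_terms(u1, u2, alpha, link)
  om1 <- fr$omega1[subj]
  eta <- veta + fr$omega2[subj]
  ilink <- if (link == "logistic") "logistic" else "cloglog"
  logpi <- log_pi(eta, ilink)
  log1mpi <- log_1mpi(eta, ilink)
  bern <- U * logpi + (1 - U) * log1mpi
  if (any(!is.finite(bern))) {
    warning("Degenerate non-cure probability contradicts a latent U; ",
            "returning -Inf.")
    return(-Inf)
  }
  g <- ifelse(status == 1,
              log(cond_density(time, lp, om1, baseline)),
              log(marginal_survival(time, lp, om1, eta, baseline, ilink)))
  sum(bern) + sum(g) + sum(fr$logf)
}

# link-specific frailty transforms and joint log-density (per subject)
frailty_terms <- function(u1, u2, alpha, link) {
  switch(link,
    cloglog = list(omega1 = log(u1), omega2 = log(u2),
                   logf = dfrailty_cloglog(u1, u2, alpha)),
    logistic = {
      o1 <- log(u1 * u2)
      o2 <- log(u2) - log1p(-u2)
      list(omega1 = o1, omega2 = o2, logf = dfrailty_logistic(o1, o2, alpha))
    },
    identical = list(omega1 = log(u1), omega2 = log(u1),
                     logf = dloggamma(log(u1), alpha))
  )
}

#' Posterior probability of being non-cured
#'
#' Bayes posterior of \eqn{U = 1} given the observed record and the frailty
#' pair: an observed recurrence implies non-cure, so \eqn{\bar U = 1} when
#' \eqn{\delta = 1}; a censored record yields
#' \deqn{\bar U = \frac{\pi S_1(t)}{1 - \pi + \pi S_1(t)},}
#' the posterior under the mixture survival. \eqn{\bar U} is nonincreasing in
#' \eqn{t} for censored records: the longer a subject stays event-free, the
#' more likely they are cured.
#'
#' @inheritParams loglik_complete
#' @param omega1 Latency log-frailty per record.
#' @param eta Full incidence linear predictor \eqn{V'\gamma + \omega_2} per
#'   record.
#' @inheritParams noncure_probability
#' @return Posterior non-cure probabilities in \eqn{[0,1]}.
#' @export
posterior_noncure <- function(time, status, lp, omega1, eta, baseline,
                              link = c("cloglog", "logistic")) {
  link <- match.arg(link)
  lnum <- log_pi(eta, link) - cumhaz(baseline, time) * exp(lp + omega1)
  lden <- mapply(function(a, b) max(a, b) + log1p(exp(min(a, b) - max(a, b))),
                 log_1mpi(eta, link), lnum)
  ifelse(status == 1, 1, exp(lnum - lden))
}

#' Monte Carlo expected incidence log-likelihood
#'
#' The E-step approximation of the incidence block of the complete-data
#' log-likelihood over `K` retained frailty draws. Two forms are available:
#' `"binomial"` (default), the complete-data Bernoulli form
#' \eqn{K^{-1}\sum_k \sum_{ij} [\bar U^k \log\pi^k + (1-\bar U^k)
#' \log(1-\pi^k)]}, and `"as_printed"`, which additionally counts
#' \eqn{\delta \log \pi^k} for every event (double-weighting uncensored
#' records) and a linearized censored survival term \eqn{-(1-\delta)\pi^k}.
#'
#' @param veta Incidence linear predictors \eqn{V'\gamma} per record.
#' @param omega2 K x N matrix of incidence log-frailty draws.
#' @inheritParams loglik_complete
#' @param ubar_k nrec x K matrix of per-draw posterior non-cure probabilities
#'   (1 for events).
#' @inheritParams noncure_probability
#' @param mode `"binomial"` or `"as_printed"`.
#' @return Scalar value of the MC objective.
#' @export
loglik_incidence_mc <- function(veta, omega2, subj, status, ubar_k,
                                link = c("cloglog", "logistic"),
                                mode = c("binomial", "as_printed")) {
  link <- match.arg(link)
  mode <- match.arg(mode)
  stopifnot(ncol(omega2) >= max(subj), nrow(ubar_k) == length(veta),
            ncol(ubar_k) == nrow(omega2))
  res <- cf_inc_obj(veta, omega2, as.integer(subj), as.integer(status),
                    ubar_k, if (link == "logistic") 1L else 0L,
                    if (mode == "as_printed") 1L else 0L, FALSE)
  res$value
}

#' Expected latency log-likelihood
#'
#' The E-step latency objective. In `"as_printed"` form only event records
#' contribute:
#' \deqn{\sum_{ij} \delta_{ij}\big[\log\lambda_0(t_{ij}) + Z_{ij}'\beta -
#'   \Lambda_0(t_{ij}) e^{Z_{ij}'\beta} E[m_i \mid \cdot] +
#'   E[\log m_i \mid \cdot]\big],}
#' with \eqn{m} the latency frailty multiplier. The `"extended"` form
#' (default in fitting) keeps the event terms but accumulates the cumulative
#' hazard over every record, weighting each by the joint posterior expectation
#' \eqn{E[U_{ij} m_i \mid \cdot]}, so censored subjects contribute their
#' at-risk exposure in proportion to their posterior probability of being
#' non-cured.
#'
#' @inheritParams loglik_complete
#' @param em Per-record posterior expectation \eqn{E[U m \mid \cdot]}
#'   (equals \eqn{E[m \mid \cdot]} for events).
#' @param elogm Per-record posterior expectation \eqn{E[\log m \mid \cdot]}
#'   (only event records use it).
#' @inheritParams loglik_incidence_mc
#' @return Scalar objective value; `-Inf` (with warning) if an event sits at a
#'   gap time with zero baseline mass.
#' @export
loglik_latency_expected <- function(time, status, lp, em, elogm, baseline,
                                    mode = c("extended", "as_printed")) {
  mode <- match.arg(mode)
  lam <- basehaz_point(baseline, time)
  if (any(status == 1 & lam <= 0)) {
    warning("Event at a gap time with zero baseline mass; returning -Inf.")
    return(-Inf)
  }
  Lam <- cumhaz(baseline, time)
  ev <- status == 1
  evterm <- sum(log(lam[ev]) + lp[ev] + elogm[ev])
  if (mode == "as_printed") {
    evterm - sum((Lam * exp(lp) * em)[ev])
  } else {
    evterm - sum(Lam * exp(lp) * em)
  }
}

#' Expected frailty log-likelihood for the clog-log bivariate gamma pair
#'
#' \eqn{\sum_i E[\log f(u_{1i}, u_{2i}); \alpha]} expressed through the
#' sufficient posterior expectations:
#' \deqn{N(\log 2 + 2\alpha\log\alpha - 2\log\Gamma(\alpha)) +
#'  (\alpha-1)\sum_i (E[\log u_{1i}] + E[\log(2u_{2i}-u_{1i})]) -
#'  2\alpha \sum_i E[u_{2i}].}
#' Linear in the sufficient statistics, so it equals the average of per-draw
#' evaluations of [dfrailty_cloglog()] exactly.
#'
#' @param elogu1,elog2u2mu1,eu2 Per-subject posterior expectations of
#'   \eqn{\log u_1}, \eqn{\log(2u_2-u_1)} and \eqn{u_2}.
#' @inheritParams loglik_complete
#' @return Scalar expected log-likelihood.
#' @export
loglik_frailty_cloglog <- function(elogu1, elog2u2mu1, eu2, alpha) {
  check_alpha(alpha)
  n <- length(eu2)
  n * (log(2) + 2 * alpha * log(alpha) - 2 * lgamma(alpha)) +
    (alpha - 1) * sum(elogu1 + elog2u2mu1) - 2 * alpha * sum(eu2)
}

#' Expected frailty log-likelihood for the shared (identical) frailty
#'
#' \eqn{l_\alpha(\alpha) = N\alpha\log\alpha - \alpha\sum_i E[u_i] +
#' (\alpha-1)\sum_i E[\log u_i] - N\log\Gamma(\alpha)}.
#'
#' @param eu,elogu Per-subject posterior expectations of \eqn{u} and
#'   \eqn{\log u}.
#' @inheritParams loglik_complete
#' @return Scalar expected log-likelihood.
#' @export
loglik_alpha_shared <- function(eu, elogu, alpha) {
  check_alpha(alpha)
  n <- length(eu)
  n * alpha * log(alpha) - alpha * sum(eu) + (alpha - 1) * sum(elogu) -
    n * lgamma(alpha)
}

#' Expected frailty log-likelihood of the logistic split component
#'
#' \eqn{\sum_i E[\log f_\psi(\psi_i); \alpha]} where
#' \eqn{\psi = \omega_1 - \omega_2 = \log(u_1(1-u_2))} is the independent
#' log-gamma split used by the two-stage logistic estimator (see
#' [dloggamma_conditional()]).
#'
#' @param epsi,eexppsi Per-subject posterior expectations of \eqn{\psi} and
#'   \eqn{e^\psi = u_1(1-u_2)}.
#' @inheritParams loglik_complete
#' @return Scalar expected log-likelihood.
#' @export
loglik_psi_logistic <- function(epsi, eexppsi, alpha) {
  check_alpha(alpha)
  n <- length(epsi)
  k <- 1 / alpha
  n * (k * log(k) - lgamma(k)) + k * sum(epsi) - k * sum(eexppsi)
}

#' @rdname loglik_psi_logistic
#' @param elogA,eA,elogB,eB Per-subject posterior expectations of
#'   \eqn{\log A}, \eqn{A = u_1 u_2}, \eqn{\log B}, \eqn{B = u_1(1-u_2)} — the
#'   two independent \eqn{\Gamma(1/\alpha, 1/\alpha)} components of the
#'   logistic construction. `loglik_frailty_logistic_full()` is the expected
#'   log of the full joint frailty density \eqn{f_{LG}(\omega_1) f_\psi(\psi)},
#'   the proper-EM alternative to the stage-1 \eqn{\psi}-only objective.
#' @export
loglik_frailty_logistic_full <- function(elogA, eA, elogB, eB, alpha) {
  check_alpha(alpha)
  n <- length(eA)
  k <- 1 / alpha
  2 * n * (k * log(k) - lgamma(k)) +
    k * (sum(elogA) - sum(eA) + sum(elogB) - sum(eB))
}

#' Approximate conditional log-likelihood of the logistic model
#'
#' The working objective of the two-stage logistic estimator:
#' \deqn{\sum_{ij}\delta_{ij}(\log S_1 + \log\lambda_1) +
#'  \sum_{ij}(1-\delta_{ij})\,(-\pi_{ij}(1 - S_1)),}
#' where the censored term is the first-order expansion of
#' \eqn{\log(1-\pi(1-S_1))}. The attribute `"approx_error_bound"` carries the
#' worst-case per-record linearization error bound
#' \eqn{x^2/(2(1-x))} with \eqn{x = \pi(1-S_1)}.
#'
#' @inheritParams posterior_noncure
#' @return Scalar objective with attribute `approx_error_bound`.
#' @export
loglik_logistic_censored <- function(time, status, lp, omega1, eta, baseline) {
  s1 <- cond_survival(time, lp, omega1, baseline)
  lam1 <- cond_hazard(time, lp, omega1, baseline)
  pi <- noncure_probability(eta, "logistic")
  ev <- status == 1
  x <- (pi * (1 - s1))[!ev]
  val <- sum(log(s1[ev]) + log(lam1[ev])) - sum(x)
  attr(val, "approx_error_bound") <-
    if (length(x)) max(x^2 / (2 * pmax(1 - x, 1e-12))) else 0
  val
}

#' Stage-1 objective of the two-stage logistic estimator
#'
#' \eqn{\sum_{ij}\delta_{ij}(\log S_1 + \log\lambda_1) +
#' \sum_i \log f(\omega_{2i}\mid\omega_{1i})}, used to update \eqn{(\beta,
#' \alpha)} at fixed \eqn{\gamma}.
#'
#' @inheritParams loglik_complete
#' @param omega1,omega2 Per-subject log-frailties.
#' @return Scalar objective value.
#' @export
loglik_logistic_stage1 <- function(time, status, lp, subj, omega1, omega2,
                                   alpha, baseline) {
  o1 <- omega1[subj]
  s1 <- cond_survival(time, lp, o1, baseline)
  lam1 <- cond_hazard(time, lp, o1, baseline)
  ev <- status == 1
  sum(log(s1[ev]) + log(lam1[ev])) +
    sum(dloggamma_conditional(omega2, omega1, alpha))
}

#' Stage-2 objective of the two-stage logistic estimator
#'
#' \eqn{\sum_{ij}(1-\delta_{ij})(-\pi_{ij}(1-S_1^0)) +
#' \sum_i \log f(\omega_{1i}; \alpha_0)}, with \eqn{S_1^0} frozen at the
#' stage-1 estimates; only \eqn{\gamma} (through \eqn{\pi}) varies. Note that
#' with any censoring present this objective is monotone decreasing in every
#' \eqn{\pi_{ij}}, which is why the fitting engine defaults to the bounded /
#' binomial gamma update (see [mcem_control()]).
#'
#' @inheritParams loglik_complete
#' @param s1_0 Per-record conditional survival evaluated at the frozen
#'   stage-1 parameters.
#' @param eta Incidence linear predictors \eqn{V'\gamma + \omega_2}.
#' @param omega1 Per-subject latency log-frailties.
#' @param alpha0 Frozen stage-1 heterogeneity parameter.
#' @return Scalar objective value.
#' @export
loglik_logistic_stage2 <- function(time, status, s1_0, eta, omega1, alpha0) {
  pi <- noncure_probability(eta, "logistic")
  cens <- status == 0
  -sum((pi * (1 - s1_0))[cens]) +
    sum(dloggamma_raw(omega1, 1 / alpha0, 1 / alpha0))
}
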