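#' Control parameters for the Monte Carlo EM fitter
#'
#' @param K Monte Carlo sample size per E-step (retained draws per subject).
#' @param burnin Discarded Metropolis-within-Gibbs sweeps at the first EM
#'   iteration (fresh chains).
#' @param burnin_warm Discarded sweeps at subsequent iterations, where chains
#'   are warm-started at the previous iteration's final states.
#' @param thin Keep-every interval for retained draws.
#' @param tol Convergence tolerance: the fit is declared converged when the
#'   largest absolute change in \eqn{(\beta, \gamma, \log\alpha)} stays below
#'   `tol` for two successive iterations (guards against Monte Carlo jitter).
#' @param max_iter Maximum outer EM iterations.
#' @param seed Optional integer seed; fits are fully reproducible given the
#'   data and this seed.
#' @param eq9_mode Incidence objective form: `"binomial"` (complete-data
#'   Bernoulli, default) or `"as_printed"` (adds the event double-count and
#'   linearized censored terms); see [loglik_incidence_mc()].
#' @param eq10_mode Latency objective form: `"extended"` (default; censored
#'   records contribute posterior-weighted exposure) or `"as_printed"` (event
#'   records only); see [loglik_latency_expected()].
#' @param gamma_mode Incidence update of the two-stage logistic fit:
#'   `"binomial"` (default) or `"as_printed"` (the monotone stage-2 objective,
#'   box-constrained to \eqn{\|\gamma\|_\infty \le 20}).
#' @param alpha_mode Heterogeneity update of the logistic fit: `"full"`
#'   (default; fits the full joint frailty density, i.e. both independent
#'   log-gamma components) or `"stage1"` (the conditional
#'   \eqn{f(\omega_2\mid\omega_1)} component only, as in the stage-1
#'   objective).
#' @param k_ramp Use a smaller Monte Carlo size (`max(25, K/4)`) for the
#'   first 60% of the EM iterations and the full `K` afterwards. The early
#'   iterations only steer the parameters toward the solution, so coarse
#'   E-step averages suffice there; convergence is only ever declared in the
#'   full-`K` phase.
#' @param loglik_draws Fresh prior importance-sampling draws per subject used
#'   for the observed-data log-likelihood (and AIC) at convergence.
#' @param se Compute Louis standard errors?
#' @param init_cap Absolute cap applied to the no-frailty GLM initial values of
#'   `gamma` (guards against separation in the initializer).
#' @return A list of class `cf_control`.
#' @export
mcem_control <- function(K = 1000, burnin = 200, burnin_warm = 50, thin = 1,
                         tol = 0.001, max_iter = 200, seed = NULL,
                         eq9_mode = c("binomial", "as_printed"),
                         eq10_mode = c("extended", "as_printed"),
                         gamma_mode = c("binomial", "as_printed"),
                         alpha_mode = c("full", "stage1"),
                         k_ramp = TRUE, loglik_draws = 500, se = TRUE,
                         init_cap = 8) {
  stopifnot(K >= 1, burnin >= 0, thin >= 1, tol > 0, max_iter >= 1)
  structure(list(K = as.integer(K), burnin = as.integer(burnin),
                 burnin_warm = as.integer(burnin_warm),
                 thin = as.integer(thin), tol = tol,
                 max_iter = as.integer(max_iter), seed = seed,
                 eq9_mode = match.arg(eq9_mode),
                 eq10_mode = match.arg(eq10_mode),
                 gamma_mode = match.arg(gamma_mode),
                 alpha_mode = match.arg(alpha_mode),
                 k_ramp = isTRUE(k_ramp),
                 loglik_draws = as.integer(loglik_draws), se = se,
                 init_cap = init_cap),
            class = "cf_control")
}

link_code <- function(link) {
  c(cloglog = 0L, logistic = 1L, identical = 2L)[[link]]
}

# Build the internal record structure from a long-format data frame.
prep_cure_data <- function(data, latency, incidence, id = "id",
                           time = "time", status = "status") {
  stopifnot(is.data.frame(data))
  for (col in c(id, time, status)) {
    if (!col %in% names(data)) stop("Column `", col, "` not found.", call. = FALSE)
  }
  ord <- order(match(data[[id]], unique(data[[id]])))
  data <- data[ord, , drop = FALSE]
  t <- as.numeric(data[[time]])
  delta <- as.integer(data[[status]])
  if (any(t <= 0)) stop("All gap times must be positive.", call. = FALSE)
  if (!all(delta %in% c(0L, 1L))) {
    stop("`status` must be 0/1.", call. = FALSE)
  }
  Z <- stats::model.matrix(latency, data)
  Z <- Z[, colnames(Z) != "(Intercept)", drop = FALSE]
  V <- stats::model.matrix(incidence, data)
  subj <- match(data[[id]], unique(data[[id]]))
  n_i <- tabulate(subj)
  list(time = t, status = delta, Z = Z, V = V, subj = subj,
       subj_off = c(0L, cumsum(n_i)), N = max(subj), nrec = length(t),
       ids = unique(data[[id]]))
}

# prior draws of the frailty state, used to initialize chains and for the
# importance-sampled observed-data log-likelihood
prior_state <- function(link, alpha, n) {
  if (link == "cloglog") {
    list(s1 = stats::rbeta(n, alpha, alpha),
         s2 = stats::rgamma(n, 2 * alpha, rate = alpha))
  } else if (link == "logistic") {
    list(s1 = stats::rgamma(n, 2 / alpha, rate = 1 / alpha),
         s2 = stats::rbeta(n, 1 / alpha, 1 / alpha))
  } else {
    u <- stats::rgamma(n, alpha, rate = alpha)
    list(s1 = u, s2 = u)
  }
}

# latency multiplier and incidence log-frailty from stored draw matrices
draw_multiplier <- function(u1, u2, link) {
  switch(link, cloglog = u1, logistic = u1 * u2, identical = u1)
}
draw_omega2 <- function(u1, u2, link) {
  switch(link, cloglog = log(u2), logistic = log(u2) - log1p(-u2),
         identical = log(u1))
}

#' Draw frailties from their per-subject posterior (Monte Carlo E-step)
#'
#' Runs the Metropolis-within-Gibbs sampler targeting
#' \eqn{f(u \mid \text{subject data}; \theta_0) \propto
#' \prod_j [\pi f_1]^{\delta}[1-\pi+\pi S_1]^{1-\delta} f(u)} for every
#' subject, with independence proposals from the prior components plus
#' log-/logit-scale random-walk proposals. Subjects with no records reproduce
#' the prior.
#'
#' @inheritParams loglik_complete
#' @param veta Incidence linear predictors \eqn{V'\gamma} per record.
#' @param beta,gamma,alpha Current parameter values (`gamma` only enters via
#'   `veta`, kept for clarity of the signature).
#' @param baseline Current `cf_baseline`.
#' @param control A [mcem_control()] object (uses `K`, `burnin`, `thin`).
#' @param state Optional warm-start state list from a previous call.
#' @return List with `u1`, `u2` (K x N draw matrices), `accept` (per-subject
#'   acceptance rates), and `state` for warm restarts. A warning is issued if
#'   any subject's acceptance rate falls below 1%.
#' @export
estep_frailties <- function(time, status, subj, lp, veta, alpha, baseline,
                            link = c("cloglog", "logistic", "identical"),
                            control = mcem_control(), state = NULL) {
  link <- match.arg(link)
  n_i <- tabulate(subj)
  subj_off <- c(0L, cumsum(n_i))
  N <- length(n_i)
  if (is.null(state)) {
    ps <- prior_state(link, alpha, N)
    state <- list(s1 = ps$s1, s2 = ps$s2)
  }
  Lam <- cumhaz(baseline, time)
  res <- cf_mh_estep(as.integer(subj_off), Lam, exp(lp), veta,
                     as.integer(status), alpha, link_code(link),
                     control$K, control$burnin, control$thin,
                     state$s1, state$s2)
  if (min(res$accept) < 0.01) {
    warning("Frailty sampler acceptance rate below 1% for at least one ",
            "subject (min = ", signif(min(res$accept), 3), ").")
  }
  list(u1 = res$u1, u2 = res$u2, accept = res$accept,
       state = list(s1 = res$state1, s2 = res$state2))
}

# Newton-Raphson with step halving on the MC incidence objective.
update_gamma <- function(dat, omega2, ubar_k, gamma0, link, mode) {
  ilink <- if (link == "logistic") 1L else 0L
  imode <- if (mode == "as_printed") 1L else 0L
  g <- gamma0
  obj <- function(gm, derivs) {
    cf_inc_obj(as.numeric(dat$V %*% gm), omega2, dat$subj, dat$status,
               ubar_k, ilink, imode, derivs)
  }
  cur <- obj(g, TRUE)
  for (it in 1:3) {  # generalized EM: a few ascent steps per outer iteration
    grad <- crossprod(dat$V, cur$grad_eta)
    hess <- crossprod(dat$V * cur$hess_eta, dat$V)
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) {
      warning("Singular Hessian in the incidence update; ridge step taken.")
      step <- solve(hess - diag(1e-6 + abs(diag(hess)) * 1e-8,
                                nrow(hess)), grad)
    }
    step <- -as.numeric(step)
    sh <- 1
    repeat {
      cand <- g + sh * step
      new <- obj(cand, TRUE)
      if (new$value >= cur$value - 1e-12 || sh < 1e-4) break
      sh <- sh / 2
    }
    if (new$value < cur$value) break  # no ascent possible; keep g
    moved <- max(abs(sh * step))
    g <- cand
    cur <- new
    if (moved < 1e-8) break
  }
  list(gamma = g, value = cur$value)
}

# box-constrained maximization of the printed stage-2 objective (logistic)
update_gamma_printed <- function(dat, omega2, s1_k, gamma0) {
  cens <- dat$status == 0
  o2c <- omega2[, dat$subj[cens], drop = FALSE]  # K x ncens
  s1c <- s1_k[, cens, drop = FALSE]
  Vc <- dat$V[cens, , drop = FALSE]
  fn <- function(gm) {
    eta <- sweep(o2c, 2, as.numeric(Vc %*% gm), `+`)
    pi <- stats::plogis(eta)
    -mean(colSums(t(pi * (1 - s1c))))  # minimize sum of mean_k pi(1-S1)
  }
  gr <- function(gm) {
    eta <- sweep(o2c, 2, as.numeric(Vc %*% gm), `+`)
    pi <- stats::plogis(eta)
    w <- colMeans(pi * (1 - pi) * (1 - s1c))
    as.numeric(crossprod(Vc, w))
  }
  if (!any(cens)) return(gamma0)
  out <- stats::optim(gamma0, fn, gr, method = "L-BFGS-B",
                      lower = -20, upper = 20)
  out$par
}

# alternate Breslow update and Newton step on the latency objective
update_beta_baseline <- function(dat, a_rec, elogm_rec, beta0, mode,
                                 max_cycles = 20) {
  beta <- beta0
  p <- ncol(dat$Z)
  ev <- dat$status == 1
  base <- NULL
  for (cyc in seq_len(max_cycles)) {
    lp <- if (p) as.numeric(dat$Z %*% beta) else numeric(dat$nrec)
    base <- breslow_core(dat$time, dat$status, a_rec * exp(lp))
    if (!p) break
    Lam <- cumhaz(base, dat$time)
    cc <- Lam * a_rec
    if (mode == "as_printed") cc[!ev] <- 0
    old <- beta
    for (nr in 1:25) {
      lp <- as.numeric(dat$Z %*% beta)
      r <- cc * exp(lp)
      grad <- colSums(dat$Z[ev, , drop = FALSE]) - crossprod(dat$Z, r)
      hess <- -crossprod(dat$Z * r, dat$Z)
      step <- tryCatch(-solve(hess, grad), error = function(e) {
        warning("Singular Hessian in the latency update; ridge step taken.")
        -solve(hess - diag(1e-6 + abs(diag(hess)) * 1e-8, p), grad)
      })
      obj0 <- sum(lp[ev]) - sum(r)
      sh <- 1
      repeat {
        cand <- beta + sh * as.numeric(step)
        lpc <- as.numeric(dat$Z %*% cand)
        objc <- sum(lpc[ev]) - sum(cc * exp(lpc))
        if (objc >= obj0 - 1e-12 || sh < 1e-4) break
        sh <- sh / 2
      }
      if (objc < obj0) break
      beta <- cand
      if (max(abs(sh * as.numeric(step))) < 1e-9) break
    }
    if (max(abs(beta - old)) < 1e-7) {
      lp <- as.numeric(dat$Z %*% beta)
      base <- breslow_core(dat$time, dat$status, a_rec * exp(lp))
      break
    }
  }
  list(beta = beta, baseline = base)
}

# bounded 1-D maximization of the expected frailty log-likelihood in log alpha
update_alpha <- function(stats_i, link, alpha_mode = "full") {
  f <- switch(link,
    cloglog = function(la) loglik_frailty_cloglog(
      stats_i$elogu1, stats_i$elog2u2mu1, stats_i$eu2, exp(la)),
    logistic = if (alpha_mode == "full") {
      function(la) loglik_frailty_logistic_full(
        stats_i$elogA, stats_i$eA, stats_i$epsi, stats_i$eexppsi, exp(la))
    } else {
      function(la) loglik_psi_logistic(
        stats_i$epsi, stats_i$eexppsi, exp(la))
    },
    identical = function(la) loglik_alpha_shared(
      stats_i$eu, stats_i$elogu, exp(la))
  )
  fs <- function(la) {
    v <- f(la)
    if (is.finite(v)) v else -1e300
  }
  opt <- stats::optimize(fs, interval = log(c(1e-3, 1e3)), maximum = TRUE,
                         tol = 1e-7)
  la <- opt$maximum
  if (la < log(1e-3) + 1e-4 || la > log(1e3) - 1e-4) {
    warning("alpha update hit the search boundary [1e-3, 1e3]; clipped.")
  }
  exp(la)
}

# per-subject posterior expectations needed by the alpha update
alpha_suffstats <- function(u1, u2, link) {
  if (link == "cloglog") {
    list(elogu1 = colMeans(log(u1)), elog2u2mu1 = colMeans(log(2 * u2 - u1)),
         eu2 = colMeans(u2))
  } else if (link == "logistic") {
    b <- u1 * (1 - u2)
    a <- u1 * u2
    list(epsi = colMeans(log(b)), eexppsi = colMeans(b),
         elogA = colMeans(log(a)), eA = colMeans(a))
  } else {
    list(eu = colMeans(u1), elogu = colMeans(log(u1)))
  }
}

# observed-data log-likelihood by importance sampling from the frailty prior
obs_loglik_is <- function(dat, beta, gamma, alpha, baseline, link, kdraws) {
  ps <- prior_state(link, alpha, dat$N * kdraws)
  u1 <- matrix(ps$s1, kdraws, dat$N)
  u2 <- matrix(ps$s2, kdraws, dat$N)
  if (link == "cloglog") {
    m <- u1 * u2      # s1 = x, s2 = y: u1 = x*y
    u2v <- u2 / 2
    u1 <- m
    u2 <- u2v
  }
  mm <- draw_multiplier(u1, u2, link)[, dat$subj, drop = FALSE]
  o2 <- draw_omega2(u1, u2, link)[, dat$subj, drop = FALSE]
  lp <- if (ncol(dat$Z)) as.numeric(dat$Z %*% beta) else numeric(dat$nrec)
  veta <- as.numeric(dat$V %*% gamma)
  eta <- sweep(o2, 2, veta, `+`)
  ilink <- if (link == "logistic") "logistic" else "cloglog"
  Lam <- cumhaz(baseline, dat$time)
  lam <- basehaz_point(baseline, dat$time)
  ex <- sweep(mm, 2, Lam * exp(lp), `*`)
  ll <- matrix(0, kdraws, dat$nrec)
  ev <- dat$status == 1
  if (any(ev)) {
    ll[, ev] <- log_pi(eta[, ev, drop = FALSE], ilink) +
      log(mm[, ev, drop = FALSE]) - ex[, ev, drop = FALSE] +
      rep((log(lam) + lp)[ev], each = kdraws)
  }
  if (any(!ev)) {
    a <- log_1mpi(eta[, !ev, drop = FALSE], ilink)
    b <- log_pi(eta[, !ev, drop = FALSE], ilink) - ex[, !ev, drop = FALSE]
    mx <- pmax(a, b)
    ll[, !ev] <- mx + log1p(exp(pmin(a, b) - mx))
  }
  persub <- rowsum(t(ll), dat$subj)          # N x kdraws
  mx <- apply(persub, 1, max)
  sum(mx + log(rowMeans(exp(persub - mx))))
}

#' Fit a joint frailty mixture cure model to recurrent gap-time data
#'
#' Fits the mixture cure model for recurrent event gap times by Monte Carlo
#' EM. Three frailty specifications are available through `link`:
#' `"cloglog"` (correlated bivariate gamma frailties, complementary log-log
#' incidence), `"logistic"` (gamma x beta construction, logistic incidence,
#' estimated by the two-stage scheme), and `"identical"` (one shared gamma
#' frailty in both submodels, clog-log incidence). The baseline hazard is
#' nonparametric (posterior-weighted Breslow steps on the gap-time scale) and
#' standard errors come from the Louis identity evaluated over the final
#' E-step draws.
#'
#' @param data Long-format data frame: one row per gap time with a subject
#'   id column, a positive gap-time column, a 0/1 event indicator and
#'   covariate columns.
#' @param latency One-sided formula for the latency (proportional hazards)
#'   covariates Z; no intercept is used.
#' @param incidence One-sided formula for the incidence (cure status)
#'   covariates V; an intercept is always included.
#' @param link Frailty/link specification, see above.
#' @param id,time,status Names of the subject id, gap-time and event-indicator
#'   columns.
#' @param control A [mcem_control()] list.
#' @param init Optional named list with any of `beta`, `gamma`, `alpha` to
#'   override the data-driven initial values.
#' @return An object of class `cf_fit` with components `coefficients`
#'   (`gamma`, `beta`, `alpha`), `se`, `baseline` (tibble of step times and
#'   increments), `loglik`, `aic`, `converged`, `n_iter`, `trace` (tibble of
#'   the per-iteration parameter history), `accept` (E-step acceptance
#'   summary) and bookkeeping fields. Methods: [tidy.cf_fit()],
#'   [glance.cf_fit()], `print()`, [autoplot.cf_fit()].
#' @examples
#' \donttest{
#' sim <- simulate_recurrent_cure(150, link = "cloglog", gamma0 = 1,
#'                                gamma = -1, beta = -1, alpha = 1.5,
#'                                seed = 7)
#' fit <- fit_cure(sim, link = "cloglog",
#'                 control = mcem_control(K = 50, max_iter = 15, seed = 1))
#' tidy(fit)
#' }
#' @export
fit_cure <- function(data, latency = ~z, incidence = ~v,
                     link = c("cloglog", "logistic", "identical"),
                     id = "id", time = "time", status = "status",
                     control = mcem_control(), init = NULL) {
  link <- match.arg(link)
  dat <- prep_cure_data(data, latency, incidence, id, time, status)
  if (!any(dat$status == 1)) {
    stop("At least one observed event is required.", call. = FALSE)
  }
  if (!is.null(control$seed)) set.seed(control$seed)
  p <- ncol(dat$Z)
  q <- ncol(dat$V)

  # --- initial values: no-frailty fits ---
  beta <- rep(0, p)
  if (p && is.null(init$beta)) {
    cx <- tryCatch(survival::coxph(
      survival::Surv(dat$time, dat$status) ~ dat$Z, ties = "breslow"),
      error = function(e) NULL)
    if (!is.null(cx) && all(is.finite(stats::coef(cx)))) beta <- unname(stats::coef(cx))
  }
  if (!is.null(init$beta)) beta <- rep_len(init$beta, p)
  gamma <- rep(0, q)
  if (is.null(init$gamma)) {
    yy <- if (link == "logistic") dat$status else 1L - dat$status
    fam <- if (link == "logistic") stats::binomial() else
      stats::binomial(link = "cloglog")
    gl <- tryCatch(suppressWarnings(
      stats::glm.fit(dat$V, yy, family = fam)$coefficients),
      error = function(e) NULL)
    if (!is.null(gl) && all(is.finite(gl))) {
      gamma <- pmin(pmax(unname(gl), -control$init_cap), control$init_cap)
    }
  } else {
    gamma <- rep_len(init$gamma, q)
  }
  alpha <- if (is.null(init$alpha)) 1 else init$alpha
  lp <- if (p) as.numeric(dat$Z %*% beta) else numeric(dat$nrec)
  baseline <- breslow_core(dat$time, dat$status, exp(lp))

  state <- NULL
  trace <- matrix(NA_real_, control$max_iter, p + q + 1)
  stable <- 0L
  converged <- FALSE
  acc_min <- 1
  n_iter <- 0L
  es <- NULL
  lcode <- link_code(link)

  ramp_end <- if (control$k_ramp) ceiling(0.6 * control$max_iter) else 0L
  for (it in seq_len(control$max_iter)) {
    n_iter <- it
    veta <- as.numeric(dat$V %*% gamma)
    ctrl_it <- control
    if (it <= ramp_end) ctrl_it$K <- max(25L, control$K %/% 4L)
    ctrl_it$burnin <- if (it == 1L) control$burnin else control$burnin_warm
    es <- estep_frailties(dat$time, dat$status, dat$subj, lp, veta, alpha,
                          baseline, link, ctrl_it, state)
    state <- es$state
    acc_min <- min(acc_min, min(es$accept))
    Lam <- cumhaz(baseline, dat$time)
    st <- cf_ubar_stats(dat$subj, Lam, exp(lp), veta, dat$status,
                        es$u1, es$u2, lcode)
    mm <- draw_multiplier(es$u1, es$u2, link)
    elogm <- colMeans(log(mm))[dat$subj]
    o2 <- draw_omega2(es$u1, es$u2, link)

    old <- c(beta, gamma, log(alpha))

    if (link == "logistic" && control$gamma_mode == "as_printed") {
      ex <- sweep(mm[, dat$subj, drop = FALSE], 2, Lam * exp(lp), `*`)
      gamma <- update_gamma_printed(dat, o2, exp(-ex), gamma)
    } else {
      mode <- if (link == "logistic") "binomial" else control$eq9_mode
      gamma <- update_gamma(dat, o2, st$ubar_k, gamma, link, mode)$gamma
    }
    ub <- update_beta_baseline(dat, st$a, elogm, beta, control$eq10_mode)
    beta <- ub$beta
    baseline <- ub$baseline
    lp <- if (p) as.numeric(dat$Z %*% beta) else numeric(dat$nrec)
    alpha <- update_alpha(alpha_suffstats(es$u1, es$u2, link), link,
                          control$alpha_mode)

    trace[it, ] <- c(beta, gamma, log(alpha))
    if (it > ramp_end &&
        max(abs(c(beta, gamma, log(alpha)) - old)) < control$tol) {
      stable <- stable + 1L
      if (stable >= 2L) { converged <- TRUE; break }
    } else {
      stable <- 0L
    }
  }

  # --- final E-step at the converged parameters for SEs ---
  veta <- as.numeric(dat$V %*% gamma)
  se <- list(gamma = rep(NA_real_, q), beta = rep(NA_real_, p),
             alpha = NA_real_)
  vcovs <- list()
  info_flag <- FALSE
  if (control$se) {
    es <- estep_frailties(dat$time, dat$status, dat$subj, lp, veta, alpha,
                          baseline, link, {
                            ctl <- control; ctl$burnin <- control$burnin_warm
                            ctl
                          }, state)
    lou <- louis_all(dat, es, beta, gamma, alpha, baseline, link, control)
    se <- lou$se
    vcovs <- lou$vcov
    info_flag <- lou$pseudo_inverse
  }
  ll <- obs_loglik_is(dat, beta, gamma, alpha, baseline, link,
                      control$loglik_draws)
  npar <- p + q + 1
  nm_b <- colnames(dat$Z)
  nm_g <- colnames(dat$V)
  trace <- trace[seq_len(n_iter), , drop = FALSE]
  colnames(trace) <- c(nm_b, paste0("gamma:", nm_g), "log_alpha")

  structure(list(
    coefficients = list(gamma = stats::setNames(gamma, nm_g),
                        beta = stats::setNames(beta, nm_b), alpha = alpha),
    se = se, vcov = vcovs,
    baseline = tibble::tibble(time = baseline$event_times,
                              dLambda0 = baseline$dLambda0),
    loglik = ll, aic = -2 * ll + 2 * npar, npar = npar,
    converged = converged, n_iter = n_iter,
    trace = tibble::as_tibble(trace),
    accept = list(final = es$accept, min_seen = acc_min),
    pseudo_inverse_se = info_flag,
    link = link, control = control,
    nobs = dat$nrec, n_subjects = dat$N, n_events = sum(dat$status),
    ids = dat$ids
  ), class = "cf_fit")
}

#' @rdname fit_cure
#' @param ... Passed on to [fit_cure()].
#' @export
fit_cloglog_cure <- function(data, ...) fit_cure(data, link = "cloglog", ...)

#' @rdname fit_cure
#' @export
fit_logistic_cure <- function(data, ...) fit_cure(data, link = "logistic", ...)

#' @rdname fit_cure
#' @export
fit_shared_cure <- function(data, ...) fit_cure(data, link = "identical", ...)
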