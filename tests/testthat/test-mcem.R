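make_dat <- function(rec, latency = ~z, incidence = ~v) {
  curefrail:::prep_cure_data(rec, latency, incidence)
}

test_that("E-step sampler reproduces the prior when there are no data", {
  # subjects with a single far-censored record at pi ~ 0 carry no frailty
  # information in the incidence part and almost none in the latency part
  n <- 300
  rec <- tibble::tibble(id = 1:n, time = rep(1e-8, n), status = 0L,
                        z = 0, v = 0)
  dat <- make_dat(rec)
  bl <- baseline_np(1, 0)  # zero hazard: S1 = 1 everywhere
  set.seed(31)
  es <- estep_frailties(dat$time, dat$status, dat$subj, rep(0, n),
                        rep(-50, n), alpha = 1.5, bl, "cloglog",
                        mcem_control(K = 200, burnin = 100))
  u1 <- as.numeric(es$u1)
  u2 <- as.numeric(es$u2)
  expect_lt(abs(mean(u1) - 1), 0.03)
  expect_lt(abs(mean(u2) - 1), 0.03)
  expect_lt(abs(var(u1) - 1 / 1.5), 0.05)
  expect_lt(abs(var(u2) - 1 / 3), 0.04)
})

test_that("E-step posterior mean matches 2-D quadrature on one subject", {
  # one censored record; posterior ~ [1 - pi + pi S1] * prior
  alpha <- 1.5
  t0 <- 1.2
  lp <- 0.3
  vg <- 0.2
  bl <- baseline_weibull(1, 1.5)
  Lam <- cumhaz(bl, t0)
  lik <- function(u1, u2) {
    eta <- vg + log(u2)
    pi <- exp(-exp(eta))
    (1 - pi + pi * exp(-Lam * exp(lp) * u1))
  }
  # quadrature in the (x, y) parameterization: u1 = x y, u2 = y / 2
  f_num <- function(x, y) lik(x * y, y / 2) * x * y *
    dbeta(x, alpha, alpha) * dgamma(y, 2 * alpha, rate = alpha)
  f_den <- function(x, y) lik(x * y, y / 2) *
    dbeta(x, alpha, alpha) * dgamma(y, 2 * alpha, rate = alpha)
  int2 <- function(f) {
    integrate(function(y) vapply(y, function(yy) {
      integrate(function(x) f(x, yy), 0, 1, rel.tol = 1e-9)$value
    }, 0), 0, 60, rel.tol = 1e-8)$value
  }
  eu1_oracle <- int2(f_num) / int2(f_den)
  rec <- tibble::tibble(id = 1L, time = t0, status = 0L, z = 1, v = 1)
  dat <- curefrail:::prep_cure_data(rec, ~z, ~v - 1)
  set.seed(77)
  es <- estep_frailties(dat$time, dat$status, dat$subj, lp, vg, alpha, bl,
                        "cloglog", mcem_control(K = 4000, burnin = 500))
  eu1_mc <- mean(es$u1)
  expect_lt(abs(eu1_mc - eu1_oracle), 3 * sd(es$u1) / sqrt(4000 / 10) + 0.02)
})

test_that("incidence Newton update maximizes and ascends", {
  # intercept-only, all events: closed-form/1-D oracle
  n <- 50
  K <- 30
  set.seed(5)
  o2 <- matrix(rnorm(K * n, sd = 0.5), K, n)
  status <- rep(c(1L, 0L), length.out = n)
  rec <- tibble::tibble(id = 1:n, time = runif(n) + 0.2, status = status,
                        z = 0, v = 0)
  dat <- make_dat(rec, ~1, ~1)
  # censored records carry partial posterior non-cure weights, so the
  # binomial objective has an interior maximum
  ub <- matrix(1, n, K)
  ub[dat$status == 0, ] <- matrix(runif(sum(status == 0) * K, 0.1, 0.6),
                                  ncol = K)
  # the update takes a few generalized-EM Newton steps per call; iterate it
  # to convergence before comparing with the scalar oracle
  g <- 0
  for (i in 1:10) g <- curefrail:::update_gamma(dat, o2, ub, g, "cloglog",
                                                "binomial")$gamma
  f <- function(g) loglik_incidence_mc(rep(g, n), o2, dat$subj, dat$status,
                                       ub, "cloglog", "binomial")
  opt <- optimize(f, c(-4, 4), maximum = TRUE, tol = 1e-9)
  expect_equal(g, opt$maximum, tolerance = 1e-5)
  # ascent property from an arbitrary start
  g0 <- c(1.5)
  up2 <- curefrail:::update_gamma(dat, o2, ub, g0, "cloglog", "binomial")
  expect_gte(up2$value, f(g0) - 1e-10)
})

test_that("latency update with unit weights matches a semiparametric PH fit", {
  set.seed(6)
  n <- 250
  z <- rbinom(n, 1, 0.5)
  t <- rweibull(n, 1.4, 1) * exp(-0.8 * z / 1.4)
  d <- as.integer(runif(n) < 0.75)
  rec <- tibble::tibble(id = 1:n, time = t, status = d, z = z, v = 0)
  dat <- make_dat(rec)
  up <- curefrail:::update_beta_baseline(dat, a_rec = rep(1, n),
                                         elogm_rec = rep(0, n), beta0 = 0,
                                         mode = "extended", max_cycles = 60)
  cx <- survival::coxph(survival::Surv(t, d) ~ z, ties = "breslow")
  expect_equal(unname(up$beta), unname(coef(cx)), tolerance = 1e-4)
  # frailty-scale equivariance: doubling all weights leaves beta unchanged
  # and halves the baseline increments
  up2 <- curefrail:::update_beta_baseline(dat, a_rec = rep(2, n),
                                          elogm_rec = rep(0, n), beta0 = 0,
                                          mode = "extended", max_cycles = 60)
  expect_equal(up2$beta, up$beta, tolerance = 1e-8)
  expect_equal(up2$baseline$dLambda0, up$baseline$dLambda0 / 2,
               tolerance = 1e-8)
})

test_that("alpha update recovers the generating value from population summaries", {
  p <- rfrailty_cloglog(2e5, 1.5, seed = 41)
  st <- list(elogu1 = mean(log(p$u1)),
             elog2u2mu1 = mean(log(2 * p$u2 - p$u1)), eu2 = mean(p$u2))
  a <- curefrail:::update_alpha(st, "cloglog")
  expect_lt(abs(a - 1.5), 0.02)
  # degenerate summaries push to the bound with a warning
  expect_warning(
    ab <- curefrail:::update_alpha(list(elogu1 = 0, elog2u2mu1 = 0,
                                        eu2 = 1), "cloglog"),
    "boundary")
  expect_equal(ab, 1e3, tolerance = 0.01)
})

test_that("seeded fits are deterministic and traces match", {
  sim <- simulate_recurrent_cure(60, link = "cloglog", gamma0 = 1,
                                 gamma = -1, beta = -1, alpha = 1.5,
                                 seed = 21)
  ctl <- mcem_control(K = 40, burnin = 50, max_iter = 6, seed = 99,
                      loglik_draws = 100)
  f1 <- suppressWarnings(fit_cure(sim, link = "cloglog", control = ctl))
  f2 <- suppressWarnings(fit_cure(sim, link = "cloglog", control = ctl))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("louis information equals the finite-difference Hessian on degenerate draws", {
  skip_if_not_installed("numDeriv")
  set.seed(4)
  n <- 6
  u1v <- rep(1.3, n)
  u2v <- rep(0.9, n)
  time <- rexp(n) + 0.2
  status <- rep(1L, n)
  Z <- cbind(z = rnorm(n))
  V <- cbind("(Intercept)" = 1, v = rbinom(n, 1, 0.5))
  beta <- 0.4
  gamma <- c(0.5, -0.7)
  alpha <- 1.4
  bl <- baseline_weibull(1, 1.5)
  u1 <- matrix(u1v, 1)
  u2 <- matrix(u2v, 1)
  compl <- function(th, blk) {
    b <- beta; g <- gamma; a <- alpha
    if (blk == "gamma") g <- th else if (blk == "beta") b <- th else a <- th
    lp <- as.numeric(Z %*% b)
    eta <- as.numeric(V %*% g) + log(u2v)
    sum(noncure_probability(eta, "cloglog", log = TRUE)) +
      sum(log(cond_hazard(time, lp, log(u1v), bl))) -
      sum(cumhaz(bl, time) * exp(lp) * u1v) +
      sum(dfrailty_cloglog(u1v, u2v, a))
  }
  for (blk in c("gamma", "beta", "alpha")) {
    I <- louis_information(time, status, 1:n, Z, V, beta, gamma, alpha, bl,
                           "cloglog", u1, u2, block = blk)
    th0 <- switch(blk, gamma = gamma, beta = beta, alpha = alpha)
    H <- numDeriv::hessian(function(th) compl(th, blk), th0)
    expect_equal(unname(I), unname(-H), tolerance = 1e-4)
  }
  # information adds over independent subjects
  I_all <- louis_information(time, status, 1:n, Z, V, beta, gamma, alpha,
                             bl, "cloglog", u1, u2, block = "beta")
  Ia <- louis_information(time[1:3], status[1:3], 1:3, Z[1:3, , drop = FALSE],
                          V[1:3, , drop = FALSE], beta, gamma, alpha, bl,
                          "cloglog", u1[, 1:3, drop = FALSE],
                          u2[, 1:3, drop = FALSE], block = "beta")
  Ib <- louis_information(time[4:6], status[4:6], 1:3, Z[4:6, , drop = FALSE],
                          V[4:6, , drop = FALSE], beta, gamma, alpha, bl,
                          "cloglog", u1[, 4:6, drop = FALSE],
                          u2[, 4:6, drop = FALSE], block = "beta")
  expect_equal(I_all, Ia + Ib, tolerance = 1e-10)
})

test_that("MC objective is monotone within an iteration on the same draws", {
  sim <- simulate_recurrent_cure(150, link = "cloglog", gamma0 = 1,
                                 gamma = -1, beta = -1, alpha = 1.5,
                                 seed = 8)
  dat <- make_dat(sim)
  set.seed(12)
  lp <- rep(0, dat$nrec)
  veta <- rep(0, dat$nrec)
  bl <- breslow_update(dat$time, dat$status, lp)
  es <- estep_frailties(dat$time, dat$status, dat$subj, lp, veta, 1, bl,
                        "cloglog", mcem_control(K = 80, burnin = 100))
  st <- curefrail:::cf_ubar_stats(dat$subj, cumhaz(bl, dat$time), exp(lp),
                                  veta, dat$status, es$u1, es$u2, 0L)
  o2 <- log(es$u2)
  g0 <- c(0, 0)
  up <- curefrail:::update_gamma(dat, o2, st$ubar_k, g0, "cloglog",
                                 "binomial")
  f <- function(g) loglik_incidence_mc(as.numeric(dat$V %*% g), o2,
                                       dat$subj, dat$status, st$ubar_k,
                                       "cloglog", "binomial")
  expect_gte(up$value, f(g0))
  expect_equal(up$value, f(up$gamma), tolerance = 1e-10)
})

test_that("shared-frailty fit reduces to a gamma-frailty PH model without cure", {
  # all-non-cured data: incidence intercept pushed low so pi ~ 1
  sim <- simulate_recurrent_cure(500, link = "identical", gamma0 = -8,
                                 gamma = 0, beta = -1, alpha = 1,
                                 weibull_scale = 1, weibull_shape = 1.5,
                                 seed = 14)
  fit <- suppressWarnings(fit_cure(sim, link = "identical",
                                   control = mcem_control(K = 80,
                                                          max_iter = 60,
                                                          seed = 3,
                                                          se = FALSE)))
  cph <- survival::coxph(
    survival::Surv(time, status) ~ z + survival::frailty.gamma(id),
    data = sim)
  expect_lt(abs(fit$coefficients$beta[1] - coef(cph)[1]), 0.05)
})

test_that("estimates are insensitive to the Monte Carlo sample size", {
  sim <- simulate_recurrent_cure(250, link = "cloglog", gamma0 = 1,
                                 gamma = -1.5, beta = -1, alpha = 1,
                                 weibull_scale = 1.5, weibull_shape = 3,
                                 seed = 55)
  f_small <- suppressWarnings(fit_cure(sim, link = "cloglog",
    control = mcem_control(K = 50, max_iter = 40, seed = 1, se = FALSE,
                           loglik_draws = 50)))
  f_big <- suppressWarnings(fit_cure(sim, link = "cloglog",
    control = mcem_control(K = 500, max_iter = 40, seed = 2, se = FALSE,
                           loglik_draws = 50)))
  expect_lt(abs(f_small$coefficients$beta - f_big$coefficients$beta), 0.1)
  expect_lt(abs(log(f_small$coefficients$alpha) -
                  log(f_big$coefficients$alpha)), 0.25)
  expect_lt(max(abs(f_small$coefficients$gamma - f_big$coefficients$gamma)),
            0.2)
})
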