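test_that("complete-data log-likelihood matches a term-by-term oracle", {
  rec <- toy_records()
  U <- c(1, 0, 1, 1, 1)
  u1 <- c(0.8, 1.4, 0.6)
  u2 <- c(0.9, 1.1, 0.5)
  alpha <- 1.3
  beta <- -0.7
  gamma <- c(0.4, 1.2)
  bl <- baseline_weibull(1, 1.5)
  lp <- beta * rec$z
  veta <- gamma[1] + gamma[2] * rec$v
  val <- loglik_complete(rec$time, rec$status, U, rec$id, lp, veta, u1, u2,
                         alpha, bl, "cloglog")
  # brute-force, one term at a time
  oracle <- 0
  for (r in seq_len(nrow(rec))) {
    i <- rec$id[r]
    eta <- veta[r] + log(u2[i])
    pi <- exp(-exp(eta))
    oracle <- oracle + if (U[r] == 1) log(pi) else log(1 - pi)
    oracle <- oracle + if (rec$status[r] == 1) {
      log(cond_density(rec$time[r], lp[r], log(u1[i]), bl))
    } else {
      log(1 - pi + pi * cond_survival(rec$time[r], lp[r], log(u1[i]), bl))
    }
  }
  oracle <- oracle + sum(dfrailty_cloglog(u1, u2, alpha))
  expect_equal(val, oracle, tolerance = 1e-10)
  # invariance under subject relabeling
  perm <- c(3, 1, 2)
  val2 <- loglik_complete(rec$time, rec$status, U, perm[rec$id], lp, veta,
                          u1[order(perm)], u2[order(perm)], alpha, bl,
                          "cloglog")
  expect_equal(val, val2, tolerance = 1e-12)
  # U must be 1 on event records
  expect_error(loglik_complete(rec$time, rec$status, c(0, 0, 1, 1, 1),
                               rec$id, lp, veta, u1, u2, alpha, bl,
                               "cloglog"), "U must be 1")
})

test_that("posterior non-cure probability is the Bayes posterior", {
  bl <- baseline_weibull(1, 1.5)
  # events are non-cured with certainty
  expect_equal(posterior_noncure(1.5, 1, 0, 0, 5, bl, "cloglog"), 1)
  # t = 0 (S1 = 1): no information, posterior equals prior pi
  eta <- 0.3
  expect_equal(posterior_noncure(0, 0, 0, 0, eta, bl, "cloglog"),
               noncure_probability(eta, "cloglog"), tolerance = 1e-12)
  # enumeration oracle: pi = 0.4, S1 = 0.25 -> 0.1/0.7
  # choose t so that S1 = 0.25 with lp = omega1 = 0
  t <- (-log(0.25))^(1 / 1.5)
  eta_for_04 <- log(-log(0.4))
  expect_equal(
    posterior_noncure(t, 0, 0, 0, eta_for_04, bl, "cloglog"),
    0.4 * 0.25 / (0.6 + 0.4 * 0.25), tolerance = 1e-10)
  # nonincreasing in t for censored records
  tt <- seq(0.01, 6, length.out = 50)
  for (eta in c(-1, 0.3, 2)) {
    ub <- posterior_noncure(tt, 0, 0.2, -0.1, eta, bl, "cloglog")
    expect_true(all(diff(ub) < 0))
  }
})

test_that("MC incidence objective matches hand oracles in both modes", {
  # K = 1, one censored record, Ubar = 0.5
  o2 <- matrix(0.2, 1, 1)
  ub <- matrix(0.5, 1, 1)
  veta <- 0.4
  eta <- veta + 0.2
  pi <- exp(-exp(eta))
  hand_bin <- 0.5 * log(pi) + 0.5 * log(1 - pi)
  expect_equal(loglik_incidence_mc(veta, o2, 1L, 0L, ub, "cloglog",
                                   "binomial"), hand_bin, tolerance = 1e-12)
  # as-printed adds -(1 - delta) * pi for the censored record
  expect_equal(loglik_incidence_mc(veta, o2, 1L, 0L, ub, "cloglog",
                                   "as_printed"), hand_bin - pi,
               tolerance = 1e-12)
  # with all events the two modes differ exactly by the double-counted
  # sum of delta * log pi
  set.seed(2)
  K <- 7; n <- 5
  o2 <- matrix(rnorm(K * 2), K, 2)
  subj <- c(1L, 1L, 2L, 2L, 2L)
  veta <- rnorm(n)
  ub <- matrix(1, n, K)
  delta <- rep(1L, n)
  v1 <- loglik_incidence_mc(veta, o2, subj, delta, ub, "cloglog", "binomial")
  v2 <- loglik_incidence_mc(veta, o2, subj, delta, ub, "cloglog",
                            "as_printed")
  dup <- sum(vapply(seq_len(n), function(j) {
    mean(-exp(veta[j] + o2[, subj[j]]))
  }, 0))
  expect_equal(v2 - v1, dup, tolerance = 1e-10)
  # linearity in draws: value is the average of per-draw values
  perdraw <- vapply(seq_len(K), function(k) {
    loglik_incidence_mc(veta, o2[k, , drop = FALSE], subj, delta,
                        ub[, k, drop = FALSE], "cloglog", "binomial")
  }, 0)
  expect_equal(v1, mean(perdraw), tolerance = 1e-10)
})

test_that("expected latency objective reduces to the Cox-Breslow objective", {
  rec <- toy_records()
  bl <- breslow_update(rec$time, rec$status, 0 * rec$z)
  # hand oracle on one event record with everything at 1
  b1 <- baseline_np(1, 1)
  v <- loglik_latency_expected(1, 1, 0.3, em = 1, elogm = 0, b1)
  expect_equal(v, log(1) + 0.3 - 1 * exp(0.3), tolerance = 1e-12)
  # E[m] = 1, E[log m] = 0: equals the semiparametric PH objective on events
  lp <- -0.5 * rec$z
  blb <- breslow_update(rec$time, rec$status, lp)
  Lam <- cumhaz(blb, rec$time)
  lam <- curefrail:::basehaz_point(blb, rec$time)
  ev <- rec$status == 1
  cox_obj <- sum(log(lam[ev]) + lp[ev]) - sum(Lam * exp(lp))
  expect_equal(
    loglik_latency_expected(rec$time, rec$status, lp, em = rep(1, 5),
                            elogm = rep(0, 5), blb, mode = "extended"),
    cox_obj, tolerance = 1e-12)
  # beta = 0: event term independent of Z (printed mode drops censored rows)
  v1 <- loglik_latency_expected(rec$time, rec$status, rep(0, 5), rep(1, 5),
                                rep(0, 5), blb, mode = "as_printed")
  expect_equal(v1, sum(log(lam[ev])) - sum((Lam * 1)[ev]), tolerance = 1e-12)
  # event with zero baseline mass flags -Inf
  expect_warning(
    v0 <- loglik_latency_expected(0.77, 1, 0, 1, 0, b1), "zero baseline")
  expect_identical(v0, -Inf)
})

test_that("expected clog-log frailty log-likelihood equals draw averages and recovers alpha", {
  set.seed(3)
  n <- 40; K <- 25
  alpha <- 1.5
  p <- rfrailty_cloglog(n * K, alpha)
  u1 <- matrix(p$u1, K, n)
  u2 <- matrix(p$u2, K, n)
  st <- list(elogu1 = colMeans(log(u1)),
             elog2u2mu1 = colMeans(log(2 * u2 - u1)),
             eu2 = colMeans(u2))
  for (a in c(0.7, 1.5, 3)) {
    val <- loglik_frailty_cloglog(st$elogu1, st$elog2u2mu1, st$eu2, a)
    draws <- mean(vapply(seq_len(K), function(k) {
      sum(dfrailty_cloglog(u1[k, ], u2[k, ], a))
    }, 0)) * 1  # per-draw complete evaluation, averaged
    expect_equal(val / K * K, draws * n / n, tolerance = 1e-8)
    expect_equal(val, draws, tolerance = 1e-8)
  }
  # population self-consistency: maximizer over a grid recovers alpha = 1.5
  p2 <- rfrailty_cloglog(2e5, alpha, seed = 9)
  stats_pop <- list(elogu1 = mean(log(p2$u1)),
                    elog2u2mu1 = mean(log(2 * p2$u2 - p2$u1)),
                    eu2 = mean(p2$u2))
  grid <- seq(0.8, 2.5, by = 0.01)
  vals <- vapply(grid, function(a) loglik_frailty_cloglog(
    stats_pop$elogu1, stats_pop$elog2u2mu1, stats_pop$eu2, a), 0)
  expect_lt(abs(grid[which.max(vals)] - alpha), 0.05)
  # strictly concave in alpha (numeric second difference < 0)
  aa <- seq(0.1, 50, length.out = 200)
  v <- vapply(aa, function(a) loglik_frailty_cloglog(
    stats_pop$elogu1, stats_pop$elog2u2mu1, stats_pop$eu2, a), 0)
  expect_true(all(diff(diff(v)) < 0))
})

test_that("shared-frailty alpha log-likelihood matches its printed form", {
  set.seed(4)
  u <- rgamma(30, 2, 2)
  eu <- u; elogu <- log(u)  # degenerate posterior
  # alpha = 1: N*0 - sum(u) + 0 - N*0
  expect_equal(loglik_alpha_shared(eu, elogu, 1), -sum(u), tolerance = 1e-12)
  # draw-average oracle: the printed objective is the expected log gamma
  # density of u itself (it differs from the log-gamma density of log(u) by
  # the alpha-free Jacobian term sum(E[log u]))
  for (a in c(0.6, 2.3)) {
    expect_equal(loglik_alpha_shared(eu, elogu, a),
                 sum(dgamma(u, a, rate = a, log = TRUE)), tolerance = 1e-8)
    expect_equal(loglik_alpha_shared(eu, elogu, a),
                 sum(dloggamma(log(u), a)) - sum(log(u)), tolerance = 1e-8)
  }
  # maximizer recovery at the truth on a large sample
  u <- rgamma(2e5, 1.7, 1.7)
  grid <- seq(1, 2.6, by = 0.01)
  vals <- vapply(grid, function(a) loglik_alpha_shared(u, log(u), a), 0)
  expect_lt(abs(grid[which.max(vals)] - 1.7), 0.06)
})

test_that("logistic approximate likelihood respects the linearization bound", {
  bl <- baseline_weibull(2, 5)
  set.seed(5)
  n <- 30
  time <- runif(n, 0.2, 1.4)
  status <- rbinom(n, 1, 0.5)
  lp <- rnorm(n, 0, 0.3)
  o1 <- rnorm(n, 0, 0.5)
  eta <- rnorm(n, 0, 1)
  val <- loglik_logistic_censored(time, status, lp, o1, eta, bl)
  # pi = 0 (eta -> -Inf): censored terms vanish
  v0 <- loglik_logistic_censored(time, status, lp, o1, rep(-60, n), bl)
  ev <- status == 1
  expect_equal(as.numeric(v0),
               sum(log(cond_density(time[ev], lp[ev], o1[ev], bl))),
               tolerance = 1e-10)
  # matches the exact censored term within the stated bound
  s1 <- cond_survival(time, lp, o1, bl)
  pi <- plogis(eta)
  exact <- sum(log(cond_density(time[ev], lp[ev], o1[ev], bl))) +
    sum(log(1 - pi[!ev] * (1 - s1[!ev])))
  x <- (pi * (1 - s1))[!ev]
  bound <- sum(x^2 / (2 * (1 - x)))
  expect_lte(abs(as.numeric(val) - exact), bound + 1e-12)
  expect_gte(attr(val, "approx_error_bound"), max(abs(log(1 - x) + x)))
})

test_that("two-stage logistic objectives decompose as stated", {
  bl <- baseline_weibull(2, 5)
  set.seed(6)
  N <- 10
  subj <- rep(1:N, each = 2)
  n <- length(subj)
  time <- runif(n, 0.2, 1.3)
  status <- rbinom(n, 1, 0.6)
  lp <- rnorm(n, 0, 0.2)
  p <- rfrailty_logistic(N, 0.8, seed = 3)
  alpha <- 0.8
  # stage 1 = event terms + conditional log-gamma term
  v <- loglik_logistic_stage1(time, status, lp, subj, p$omega1, p$omega2,
                              alpha, bl)
  ev <- status == 1
  o1r <- p$omega1[subj]
  expect_equal(v, sum(log(cond_density(time[ev], lp[ev], o1r[ev], bl))) +
                 sum(dloggamma_conditional(p$omega2, p$omega1, alpha)),
               tolerance = 1e-10)
  # stage 2: all-events data depend only on the omega1 prior term
  s1_0 <- cond_survival(time, lp, o1r, bl)
  eta <- rnorm(n)
  v2 <- loglik_logistic_stage2(time, rep(1L, n), s1_0, eta, p$omega1, alpha)
  expect_equal(v2, sum(curefrail:::dloggamma_raw(p$omega1, 1 / alpha,
                                                 1 / alpha)),
               tolerance = 1e-12)
  # monotone decreasing in pi when s1 < 1 is fixed
  etas <- seq(-3, 3, by = 0.5)
  vals <- vapply(etas, function(e) {
    loglik_logistic_stage2(time, status, s1_0, rep(e, n), p$omega1, alpha)
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("full logistic frailty objective recovers alpha at the population", {
  p <- rfrailty_logistic(2e5, 0.91, seed = 10)
  a_comp <- p$u1 * p$u2
  b_comp <- p$u1 * (1 - p$u2)
  grid <- seq(0.5, 1.6, by = 0.005)
  vals <- vapply(grid, function(a) loglik_frailty_logistic_full(
    mean(log(a_comp)), mean(a_comp), mean(log(b_comp)), mean(b_comp), a), 0)
  expect_lt(abs(grid[which.max(vals)] - 0.91), 0.03)
  # psi-only objective is also maximized near the truth
  vals2 <- vapply(grid, function(a) loglik_psi_logistic(
    mean(log(b_comp)), mean(b_comp), a), 0)
  expect_lt(abs(grid[which.max(vals2)] - 0.91), 0.04)
})

test_that("MC objective variance scales as 1/K", {
  set.seed(8)
  n <- 6
  subj <- rep(1:3, each = 2)
  veta <- rnorm(n)
  delta <- c(1L, 0L, 1L, 0L, 1L, 0L)
  vr <- vapply(c(10, 100, 1000), function(K) {
    vals <- vapply(1:30, function(r) {
      o2 <- matrix(rnorm(K * 3, sd = 0.7), K, 3)
      ub <- matrix(ifelse(rep(delta, K) == 1, 1, runif(n * K)), n, K)
      loglik_incidence_mc(veta, o2, subj, delta, ub, "cloglog", "binomial")
    }, 0)
    var(vals)
  }, 0)
  # variance drops roughly tenfold per tenfold K (allow wide slack)
  expect_lt(vr[2], vr[1] / 3)
  expect_lt(vr[3], vr[2] / 3)
})
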