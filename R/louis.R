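#' Louis observed information from E-step draws
#'
#' Estimates the observed-data information matrix of one parameter block by
#' the Louis identity
#' \deqn{I = E[-B_c] - E[S_c S_c'] + S_m S_m',}
#' where \eqn{B_c} and \eqn{S_c} are the complete-data Hessian and score and
#' \eqn{S_m} is the Monte Carlo estimate of the observed-data score, all
#' evaluated over the retained frailty draws. The latent cure statuses are
#' integrated out analytically (Rao-Blackwellized: the score is linear in
#' \eqn{U}, so conditional means and Bernoulli variances enter in closed
#' form). Blocks are treated separately, as in the estimation algorithm; the
#' baseline hazard is profiled out.
#'
#' @inheritParams loglik_complete
#' @param Z,V Latency and incidence design matrices (V includes the
#'   intercept).
#' @param beta,gamma,alpha Parameter values (normally the converged
#'   estimates).
#' @param u1,u2 K x N matrices of posterior frailty draws (see
#'   [estep_frailties()]).
#' @param block `"gamma"`, `"beta"` or `"alpha"`.
#' @return The information matrix for the block (symmetric; its inverse's
#'   diagonal gives squared standard errors).
#' @export
louis_information <- function(time, status, subj, Z, V, beta, gamma, alpha,
                              baseline, link = c("cloglog", "logistic",
                                                 "identical"),
                              u1, u2, block = c("gamma", "beta", "alpha")) {
  link <- match.arg(link)
  block <- match.arg(block)
  p <- ncol(Z)
  lp <- if (p) as.numeric(Z %*% beta) else numeric(length(time))
  veta <- as.numeric(V %*% gamma)
  Lam <- cumhaz(baseline, time)
  st <- cf_ubar_stats(as.integer(subj), Lam, exp(lp), veta,
                      as.integer(status), u1, u2, link_code(link))
  ub <- t(st$ubar_k)                                   # K x nrec
  N <- ncol(u1)
  K <- nrow(u1)
  if (block == "gamma") {
    o2 <- draw_omega2(u1, u2, link)
    eta <- sweep(o2[, subj, drop = FALSE], 2, veta, `+`)
    ilink <- if (link == "logistic") "logistic" else "cloglog"
    d <- link_derivs(eta, ilink)
    louis_block(V, subj, N, K,
                s = ub * d$dlp + (1 - ub) * d$d1p,
                negb = -(ub * d$hlp + (1 - ub) * d$h1p),
                varu = ub * (1 - ub) * (d$dlp - d$d1p)^2)
  } else if (block == "beta") {
    stopifnot(p >= 1)
    mm <- draw_multiplier(u1, u2, link)[, subj, drop = FALSE]
    cc <- Lam * exp(lp)
    r <- ub * sweep(mm, 2, cc, `*`)
    dlt <- rep(as.numeric(status), each = K)
    louis_block(Z, subj, N, K,
                s = matrix(dlt, K) - r,
                negb = r,
                varu = ub * (1 - ub) * sweep(mm, 2, cc, `*`)^2)
  } else {
    s <- alpha_score_draws(u1, u2, alpha, link)
    enb <- alpha_neg_hess(u1, u2, alpha, link)
    matrix(enb - sum(colMeans(s^2)) + sum(colMeans(s)^2), 1, 1)
  }
}

# first and second derivatives of log pi and log(1 - pi) in eta
link_derivs <- function(eta, link) {
  if (link == "logistic") {
    pi <- stats::plogis(eta)
    list(dlp = 1 - pi, d1p = -pi, hlp = -pi * (1 - pi), h1p = -pi * (1 - pi))
  } else {
    a <- exp(eta)
    lpv <- -a
    l1pv <- log_1mpi(eta, "cloglog")
    d1p <- a * exp(lpv - l1pv)
    list(dlp = -a, d1p = d1p, hlp = -a, h1p = d1p * (1 - a - d1p))
  }
}

# assemble one Louis block from per-(draw, record) score factors;
# s, negb, varu are K x nrec, X is the nrec x d design matrix
louis_block <- function(X, subj, N, K, s, negb, varu) {
  d <- ncol(X)
  I1 <- crossprod(X * colMeans(negb), X)
  Vt <- crossprod(X * colMeans(varu), X)
  Smat <- vector("list", d)
  for (j in seq_len(d)) {
    Smat[[j]] <- rowsum(t(s) * X[, j], subj)           # N x K
  }
  ESS <- matrix(0, d, d)
  Sm <- matrix(0, N, d)
  for (a in seq_len(d)) {
    Sm[, a] <- rowMeans(Smat[[a]])
    for (b in a:d) {
      ESS[a, b] <- ESS[b, a] <- sum(Smat[[a]] * Smat[[b]]) / K
    }
  }
  I1 - (ESS + Vt) + crossprod(Sm)
}

# per-draw complete-data score in alpha (K x N)
alpha_score_draws <- function(u1, u2, alpha, link) {
  if (link == "cloglog") {
    2 * log(alpha) + 2 - 2 * digamma(alpha) + log(u1) + log(2 * u2 - u1) -
      2 * u2
  } else if (link == "logistic") {
    k1 <- 1 / alpha
    psi <- log(u1 * (1 - u2))
    dldk <- log(k1) + 1 - digamma(k1) + psi - exp(psi)
    -dldk / alpha^2
  } else {
    log(alpha) + 1 - digamma(alpha) + log(u1) - u1
  }
}

# total E[-B] for the alpha block
alpha_neg_hess <- function(u1, u2, alpha, link) {
  N <- ncol(u1)
  if (link == "cloglog") {
    N * (2 * trigamma(alpha) - 2 / alpha)
  } else if (link == "logistic") {
    k1 <- 1 / alpha
    psi <- log(u1 * (1 - u2))
    dldk <- log(k1) + 1 - digamma(k1) + psi - exp(psi)
    b <- (1 / k1 - trigamma(k1)) / alpha^4 + dldk * (2 / alpha^3)
    -sum(colMeans(b))
  } else {
    N * (trigamma(alpha) - 1 / alpha)
  }
}

# all blocks + SEs; pseudo-inverse fallback when a block is not PD
louis_all <- function(dat, es, beta, gamma, alpha, baseline, link, control) {
  p <- ncol(dat$Z)
  blocks <- c("gamma", if (p) "beta", "alpha")
  vc <- list()
  flag <- FALSE
  for (b in blocks) {
    I <- louis_information(dat$time, dat$status, dat$subj, dat$Z, dat$V,
                           beta, gamma, alpha, baseline, link,
                           es$u1, es$u2, block = b)
    vb <- tryCatch(chol2inv(chol(I)), error = function(e) NULL)
    if (is.null(vb)) {
      # not PD (large missing-information fraction / MC noise): floor the
      # eigenvalues, which yields conservative (large) standard errors
      flag <- TRUE
      eig <- eigen(I, symmetric = TRUE)
      ev <- pmax(eig$values, max(abs(eig$values)) * 1e-8)
      vb <- eig$vectors %*% (t(eig$vectors) / ev)
    }
    vc[[b]] <- vb
  }
  if (flag) warning("Louis information not positive definite for at least ",
                    "one block; pseudo-inverse used.")
  se <- list(
    gamma = stats::setNames(sqrt(pmax(diag(vc$gamma), 0)), colnames(dat$V)),
    beta = if (p) stats::setNames(sqrt(pmax(diag(vc$beta), 0)),
                                  colnames(dat$Z)) else numeric(0),
    alpha = sqrt(max(vc$alpha[1, 1], 0))
  )
  list(se = se, vcov = vc, pseudo_inverse = flag)
}
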