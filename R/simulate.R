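#' Simulate recurrent gap-time data with a cure fraction and joint frailty
#'
#' Generates data exactly under the joint frailty mixture cure model. For
#' each subject: a loss-to-follow-up time \eqn{C_i \sim U(0,
#' \text{followup})}; a frailty pair from the link-appropriate construction
#' ([rfrailty_cloglog()] or [rfrailty_logistic()], or a single shared
#' \eqn{u \sim \Gamma(\alpha,\alpha)} for `link = "identical"`); scalar
#' covariates \eqn{Z_i, V_i \sim \mathrm{Bernoulli}(0.5)} drawn once per
#' subject. Recurrences are then generated gap by gap: draw the cure status
#' \eqn{U_{ij}} from the link's non-cure probability
#' \eqn{\pi(\gamma_0 + \gamma V_i + \omega_{2i})}; if non-cured, draw the gap
#' by inverting the Weibull conditional survival
#' \eqn{S(t) = \exp(-\lambda t^\mu e^{Z_i'\beta} m_i)}, where \eqn{m_i} is the
#' latency multiplier (\eqn{u_{1i}}, \eqn{u_{1i}u_{2i}}, or \eqn{u_i} by
#' link), so \eqn{t = (-\log W / (\lambda e^{Z\beta} m))^{1/\mu}}. Generation
#' stops when the cumulative gap time crosses \eqn{C_i} (the crossing record
#' is censored at the remaining time) or when a cured status \eqn{U = 0} is
#' drawn (one final censored record with gap equal to the remaining time to
#' \eqn{C_i}).
#'
#' Time is on one abstract unit scale (think years): the censoring horizon
#' and the Weibull baseline live on the same scale.
#'
#' @param n Number of subjects.
#' @inheritParams fit_cure
#' @param gamma0,gamma Incidence intercept and covariate coefficient.
#' @param beta Latency covariate coefficient.
#' @param alpha Frailty heterogeneity parameter.
#' @param weibull_scale,weibull_shape Baseline hazard \eqn{\Lambda_0(t) =
#'   \lambda t^\mu}.
#' @param followup Maximum follow-up (censoring \eqn{C \sim U(0,
#'   \text{followup})}).
#' @param seed Optional integer seed.
#' @return A tibble of class `cf_sim` with one row per gap: `id`, `j`
#'   (recurrence index), `time` (gap), `status`, `z`, `v`. The latent truth is
#'   attached as `attr(x, "latent")` (per-subject tibble with `u1`, `u2`,
#'   `C`, `cured` — whether generation ended by drawing \eqn{U=0} — and
#'   `n_events`), and the generating configuration as `attr(x, "config")`.
#' @examples
#' sim <- simulate_recurrent_cure(50, gamma0 = 1, gamma = -1, beta = -1,
#'                                alpha = 1.5, seed = 1)
#' cure_rate(sim)
#' @export
simulate_recurrent_cure <- function(n, link = c("cloglog", "logistic",
                                                "identical"),
                                    gamma0 = 1, gamma = 2.5, beta = -1,
                                    alpha = 1.5, weibull_scale = 1,
                                    weibull_shape = 1.5, followup = 5,
                                    seed = NULL) {
  link <- match.arg(link)
  check_alpha(alpha)
  stopifnot(n >= 1, followup > 0, weibull_scale > 0, weibull_shape > 0)
  if (!is.null(seed)) set.seed(seed)
  C <- stats::runif(n, 0, followup)
  fr <- switch(link,
    cloglog = rfrailty_cloglog(n, alpha),
    logistic = rfrailty_logistic(n, alpha),
    identical = {
      u <- stats::rgamma(n, alpha, rate = alpha)
      tibble::tibble(u1 = u, u2 = u, omega1 = log(u), omega2 = log(u))
    })
  m <- switch(link, cloglog = fr$u1, logistic = fr$u1 * fr$u2,
              identical = fr$u1)
  z <- stats::rbinom(n, 1, 0.5)
  v <- stats::rbinom(n, 1, 0.5)
  ilink <- if (link == "logistic") "logistic" else "cloglog"
  pi_i <- noncure_probability(gamma0 + gamma * v + fr$omega2, ilink)
  rate_i <- weibull_scale * exp(beta * z) * m

  rows <- vector("list", n)
  cured <- logical(n)
  n_events <- integer(n)
  for (i in seq_len(n)) {
    elapsed <- 0
    j <- 0L
    tt <- numeric(0)
    dd <- integer(0)
    repeat {
      j <- j + 1L
      U <- stats::rbinom(1, 1, pi_i[i])
      if (U == 0L) {
        cured[i] <- TRUE
        tt[j] <- C[i] - elapsed
        dd[j] <- 0L
        break
      }
      gap <- (-log(stats::runif(1)) / rate_i[i])^(1 / weibull_shape)
      if (elapsed + gap >= C[i]) {
        tt[j] <- C[i] - elapsed
        dd[j] <- 0L
        break
      }
      tt[j] <- gap
      dd[j] <- 1L
      n_events[i] <- n_events[i] + 1L
      elapsed <- elapsed + gap
    }
    rows[[i]] <- tibble::tibble(id = i, j = seq_len(j), time = tt,
                                status = dd, z = z[i], v = v[i])
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "latent") <- tibble::tibble(
    id = seq_len(n), u1 = fr$u1, u2 = fr$u2, C = C, cured = cured,
    n_events = n_events)
  attr(out, "config") <- list(n = n, link = link, gamma0 = gamma0,
                              gamma = gamma, beta = beta, alpha = alpha,
                              weibull_scale = weibull_scale,
                              weibull_shape = weibull_shape,
                              followup = followup, seed = seed)
  class(out) <- c("cf_sim", class(out))
  out
}

#' Cure and censoring diagnostics of a simulated dataset
#'
#' `cure_rate()` is the fraction of subjects whose generation terminated by
#' drawing the latent cured status \eqn{U = 0} (the latent-truth definition);
#' `censoring_rate()` is the fraction of records with `status == 0`;
#' `noncure_draw_rate()` is the mean per-record latent non-cure probability —
#' three candidate operational readings of a dataset's "cure rate", all
#' reported by the study harness.
#'
#' @param x A `cf_sim` tibble from [simulate_recurrent_cure()].
#' @return A single number.
#' @export
cure_rate <- function(x) {
  lat <- attr(x, "latent")
  stopifnot(!is.null(lat))
  mean(lat$cured)
}

#' @rdname cure_rate
#' @export
censoring_rate <- function(x) mean(x$status == 0)

#' @rdname cure_rate
#' @export
noncure_draw_rate <- function(x) {
  cfg <- attr(x, "config")
  lat <- attr(x, "latent")
  stopifnot(!is.null(cfg), !is.null(lat))
  ilink <- if (cfg$link == "logistic") "logistic" else "cloglog"
  omega2 <- switch(cfg$link, logistic = log(lat$u2) - log1p(-lat$u2),
                   log(lat$u2))
  first <- x[!duplicated(x$id), ]
  mean(noncure_probability(cfg$gamma0 + cfg$gamma * first$v +
                             omega2[match(first$id, lat$id)], ilink))
}
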