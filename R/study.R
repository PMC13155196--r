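#' Replicated parameter-recovery simulation study
#'
#' Simulates datasets under a given truth, fits the requested model to each
#' replication, and aggregates parameter recovery the way simulation studies
#' in this literature report it: mean estimate, MSE (mean squared deviation of
#' the estimates from the truth), ESE (mean of the Louis standard errors) and
#' the SD of those standard errors, plus cure-rate/censoring diagnostics
#' across replications. Replication seeds are derived deterministically from
#' `seed`. Replications that error out are dropped (and counted);
#' non-converged fits are flagged and counted but kept in the aggregates, so
#' the summaries are not selectively biased by the stopping rule.
#'
#' @param n Subjects per replication.
#' @param reps Number of replications (at least 2).
#' @inheritParams simulate_recurrent_cure
#' @param fit_link Model to fit; defaults to the generating link
#'   (`"identical"` data are fitted with the identical model).
#' @param control [mcem_control()] used for every fit (its `seed` is
#'   overridden per replication).
#' @param seed Root seed for the whole study.
#' @return A list of class `cf_study`: `summary` (tibble with one row per
#'   parameter), `estimates` (per-replication tibble), `rates` (cure-rate
#'   diagnostics), `n_failed`, `n_nonconverged`, and the configuration.
#' @export
run_study <- function(n = 1000, reps = 20, link = "cloglog",
                      gamma0 = 1, gamma = 2.5, beta = -1, alpha = 1.5,
                      weibull_scale = 1, weibull_shape = 1.5, followup = 5,
                      fit_link = link, control = mcem_control(K = 100),
                      seed = 1) {
  stopifnot(reps >= 2)
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, 2 * reps)
  est <- vector("list", reps)
  rates <- vector("list", reps)
  n_failed <- 0L
  n_nonconv <- 0L
  for (r in seq_len(reps)) {
    sim <- simulate_recurrent_cure(n, link = link, gamma0 = gamma0,
                                   gamma = gamma, beta = beta, alpha = alpha,
                                   weibull_scale = weibull_scale,
                                   weibull_shape = weibull_shape,
                                   followup = followup,
                                   seed = rep_seeds[2 * r - 1])
    ctl <- control
    ctl$seed <- rep_seeds[2 * r]
    fit <- tryCatch(
      suppressWarnings(fit_cure(sim, latency = ~z, incidence = ~v,
                                link = fit_link, control = ctl)),
      error = function(e) NULL)
    rates[[r]] <- tibble::tibble(rep = r, cure_rate = cure_rate(sim),
                                 censoring_rate = censoring_rate(sim),
                                 noncure_draw_rate = noncure_draw_rate(sim))
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    if (!fit$converged) n_nonconv <- n_nonconv + 1L
    co <- fit$coefficients
    est[[r]] <- tibble::tibble(
      rep = r,
      parameter = c("gamma0", "gamma", "beta", "alpha"),
      truth = c(gamma0, gamma, beta, alpha),
      estimate = c(co$gamma[1], co$gamma[2], co$beta[1], co$alpha),
      louis_se = c(fit$se$gamma[1], fit$se$gamma[2], fit$se$beta[1],
                   fit$se$alpha),
      converged = fit$converged)
  }
  est <- dplyr::bind_rows(est)
  if (!nrow(est)) stop("Every replication failed.", call. = FALSE)
  summary <- est |>
    dplyr::group_by(.data$parameter, .data$truth) |>
    dplyr::summarise(
      mean_estimate = mean(.data$estimate),
      mse = mean((.data$estimate - .data$truth)^2),
      emp_sd = stats::sd(.data$estimate),
      ese = mean(.data$louis_se, na.rm = TRUE),
      sd_se = stats::sd(.data$louis_se, na.rm = TRUE),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$parameter, c("gamma0", "gamma", "beta",
                                            "alpha")))
  rates <- dplyr::bind_rows(rates)
  structure(list(
    summary = summary, estimates = est,
    rates = tibble::tibble(
      cure_rate_mean = mean(rates$cure_rate),
      cure_rate_sd = stats::sd(rates$cure_rate),
      censoring_rate_mean = mean(rates$censoring_rate),
      noncure_draw_rate_mean = mean(rates$noncure_draw_rate)),
    n_failed = n_failed, n_nonconverged = n_nonconv, reps = reps,
    config = list(n = n, link = link, fit_link = fit_link, gamma0 = gamma0,
                  gamma = gamma, beta = beta, alpha = alpha,
                  weibull_scale = weibull_scale,
                  weibull_shape = weibull_shape, followup = followup,
                  seed = seed, K = control$K)
  ), class = "cf_study")
}

#' Harrell's concordance index for gap times
#'
#' Probability that, among usable (comparable under right censoring) record
#' pairs, the record with the higher risk score has the shorter gap time.
#' A pair is comparable when the smaller time is an event; ties in the
#' predictor receive half credit; tied times are not compared.
#'
#' @param time,status Gap times and event indicators.
#' @param lp Risk scores (higher = shorter expected gap), typically the
#'   latency linear predictor \eqn{Z'\hat\beta}.
#' @return A list with `cindex`, `concordant`, `discordant`, `tied`, `pairs`.
#' @export
concordance_index <- function(time, status, lp) {
  n <- length(time)
  stopifnot(length(status) == n, length(lp) == n)
  conc <- disc <- tied <- 0
  for (a in which(status == 1)) {
    usable <- time > time[a]
    if (!any(usable)) next
    conc <- conc + sum(lp[usable] < lp[a])
    disc <- disc + sum(lp[usable] > lp[a])
    tied <- tied + sum(lp[usable] == lp[a])
  }
  pairs <- conc + disc + tied
  list(cindex = if (pairs > 0) (conc + 0.5 * tied) / pairs else NA_real_,
       concordant = conc, discordant = disc, tied = tied, pairs = pairs)
}

#' Train/test concordance with a subject-level 70:30 split
#'
#' Splits subjects (not records) into a training and a held-out set, fits the
#' requested model on the training records, and reports Harrell's C of the
#' latency linear predictor on both sets. A small train-test gap indicates no
#' overfitting of the latency component.
#'
#' @inheritParams fit_cure
#' @param split Training fraction (default 0.70).
#' @param seed Seed for the subject split.
#' @param ... Passed to [fit_cure()].
#' @return A list with `c_train`, `c_test` and the fitted model `fit`.
#' @export
train_test_cindex <- function(data, latency = ~z, incidence = ~v,
                              link = "cloglog", split = 0.70, seed = 1,
                              id = "id", time = "time", status = "status",
                              ...) {
  set.seed(seed)
  ids <- unique(data[[id]])
  tr_ids <- sample(ids, floor(split * length(ids)))
  tr <- data[data[[id]] %in% tr_ids, , drop = FALSE]
  te <- data[!data[[id]] %in% tr_ids, , drop = FALSE]
  fit <- fit_cure(tr, latency = latency, incidence = incidence, link = link,
                  id = id, time = time, status = status, ...)
  lp_of <- function(d) {
    Z <- stats::model.matrix(latency, d)
    Z <- Z[, colnames(Z) != "(Intercept)", drop = FALSE]
    as.numeric(Z %*% fit$coefficients$beta)
  }
  c_tr <- concordance_index(tr[[time]], tr[[status]], lp_of(tr))$cindex
  c_te <- concordance_index(te[[time]], te[[status]], lp_of(te))$cindex
  list(c_train = c_tr, c_test = c_te, fit = fit)
}

#' Rank fitted cure models by AIC
#'
#' Sorts a set of [fit_cure()] results by AIC (ascending) and reports
#' differences to the best model. The observed-data log-likelihoods behind
#' these AICs are Monte Carlo estimates under each model's own frailty law
#' with the baseline hazard profiled out, so rankings are meaningful between
#' the models of this package but not against parametric AICs; a reminder
#' column flags this.
#'
#' @param fits Named list of `cf_fit` objects.
#' @return A tibble sorted by AIC with `model`, `link`, `loglik`, `npar`,
#'   `aic`, `delta_aic`, `comparable`.
#' @export
compare_models_aic <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "cf_fit")))
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  out <- tibble::tibble(
    model = names(fits),
    link = unname(vapply(fits, function(f) f$link, "")),
    loglik = unname(vapply(fits, function(f) f$loglik, 0)),
    npar = unname(vapply(fits, function(f) as.integer(f$npar), 0L)),
    aic = unname(vapply(fits, function(f) f$aic, 0))
  ) |> dplyr::arrange(.data$aic)
  out$delta_aic <- out$aic - out$aic[1]
  out$comparable <- length(unique(out$npar)) == 1
  out
}
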