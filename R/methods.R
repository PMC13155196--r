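#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted joint frailty cure model
#'
#' One row per model term, broom-style, with a `component` column separating
#' the incidence coefficients (`gamma`), the latency coefficients (`beta`)
#' and the frailty heterogeneity parameter (`alpha`).
#'
#' @param x A `cf_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `component`, `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.cf_fit <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    component = c(rep("incidence", length(co$gamma)),
                  rep("latency", length(co$beta)), "frailty"),
    term = c(names(co$gamma), names(co$beta), "alpha"),
    estimate = c(unname(co$gamma), unname(co$beta), co$alpha),
    std.error = c(unname(x$se$gamma), unname(x$se$beta), x$se$alpha)
  )
}

#' Model-level summary of a fitted joint frailty cure model
#'
#' @inheritParams tidy.cf_fit
#' @return A one-row tibble with `logLik`, `AIC`, `npar`, `converged`,
#'   `n_iter`, `nobs`, `n_subjects`, `n_events`.
#' @export
glance.cf_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, npar = x$npar,
                 converged = x$converged, n_iter = x$n_iter, nobs = x$nobs,
                 n_subjects = x$n_subjects, n_events = x$n_events)
}

#' @export
print.cf_fit <- function(x, ...) {
  cat("Joint frailty mixture cure model (", x$link, " link)\n", sep = "")
  cat(sprintf("  %d records, %d subjects, %d events\n", x$nobs,
              x$n_subjects, x$n_events))
  cat(sprintf("  MCEM: %d iterations, %sconverged (K = %d)\n", x$n_iter,
              if (x$converged) "" else "NOT ", x$control$K))
  print(tidy(x), n = Inf)
  cat(sprintf("  logLik %.2f  AIC %.2f\n", x$loglik, x$aic))
  invisible(x)
}

#' Plot a fitted joint frailty cure model
#'
#' `what = "trace"` shows the per-iteration parameter history of the MCEM
#' run; `what = "baseline"` shows the estimated cumulative baseline hazard
#' step function.
#'
#' @param object A `cf_fit`.
#' @param what `"trace"` or `"baseline"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cf_fit <- function(object, what = c("trace", "baseline"), ...) {
  what <- match.arg(what)
  if (what == "trace") {
    tr <- object$trace
    tr$iteration <- seq_len(nrow(tr))
    long <- tidyr::pivot_longer(tr, -"iteration", names_to = "parameter",
                                values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "EM iteration", y = "estimate",
                    title = "MCEM parameter trace")
  } else {
    bl <- object$baseline
    bl$cumhaz <- cumsum(bl$dLambda0)
    ggplot2::ggplot(bl, ggplot2::aes(.data$time, .data$cumhaz)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "gap time", y = expression(Lambda[0](t)),
                    title = "Cumulative baseline hazard")
  }
}

#' @export
print.cf_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Recovery study: %d reps, N = %d, %s data, %s fit (K = %d)\n",
              x$reps, cfg$n, cfg$link, cfg$fit_link, cfg$K))
  print(x$summary, n = Inf)
  cat(sprintf("  cure rate %.1f%% (SD %.1f), censoring rate %.1f%%\n",
              100 * x$rates$cure_rate_mean, 100 * x$rates$cure_rate_sd,
              100 * x$rates$censoring_rate_mean))
  if (x$n_failed) cat("  failed replications:", x$n_failed, "\n")
  if (x$n_nonconverged) {
    cat("  non-converged (kept, flagged):", x$n_nonconverged, "\n")
  }
  invisible(x)
}

#' Plot a recovery study
#'
#' Dot-and-error plot of the per-replication estimates against the truth for
#' each parameter.
#'
#' @param object A `cf_study` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cf_study <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(.data$parameter, .data$estimate)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5) +
    ggplot2::geom_point(data = object$summary,
                        ggplot2::aes(.data$parameter, .data$truth),
                        colour = "red", shape = 4, size = 3) +
    ggplot2::labs(y = "estimate", x = NULL,
                  title = "Parameter recovery across replications",
                  subtitle = "red cross = truth")
}

#' @export
print.cf_sim <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Simulated recurrent cure data: %d subjects, %d records (%s link)\n",
    cfg$n, nrow(x), cfg$link))
  cat(sprintf("  cure rate %.1f%%, censoring rate %.1f%%\n",
              100 * cure_rate(x), 100 * censoring_rate(x)))
  NextMethod()
}
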