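# small deterministic fixtures shared across test files

# five-record, three-subject toy dataset (subject 3 all-censored)
toy_records <- function() {
  tibble::tibble(
    id = c(1L, 1L, 2L, 2L, 3L),
    j = c(1L, 2L, 1L, 2L, 1L),
    time = c(0.5, 1.2, 0.8, 2.0, 3.1),
    status = c(1L, 0L, 1L, 1L, 0L),
    z = c(1, 1, 0, 0, 1),
    v = c(0, 0, 1, 1, 1)
  )
}

# nested adaptive quadrature of f(u1, u2) over 0 < u1 < 2 u2
integrate2d_cloglog <- function(f, alpha, upper = 40, n = 400) {
  inner <- function(b) {
    vapply(b, function(bb) {
      stats::integrate(function(u1) f(u1, bb), 0, 2 * bb,
                       rel.tol = 1e-9, stop.on.error = FALSE)$value
    }, 0)
  }
  stats::integrate(inner, 0, upper, rel.tol = 1e-8,
                   stop.on.error = FALSE)$value
}
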