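# curefrail

Joint frailty mixture cure models for recurrent gap-time data with dependent
censoring.

## The problem

In follow-up studies of recurrent clinical events — hospital readmissions
after colorectal cancer surgery, repeated tumor recurrences, repeated heart
attacks — two things complicate a standard recurrent-event analysis. A
fraction of subjects is *cured* after some recurrence and will never
experience the event again, yet they can only ever be observed as censored;
and subjects differ in unobserved ways that drive *both* their chance of
remaining susceptible and how fast they recur when susceptible. Ignoring
either produces biased covariate effects and an informative (dependent)
censoring mechanism that standard estimators do not account for.

`curefrail` is for biostatisticians analyzing such data. It models, for
subject *i* and gap *j*:

* **incidence** (cure status after each recurrence):
  `P(U_ij = 1 | ω2_i) = exp(−exp(V'γ + ω2_i))` (complementary log–log link)
  or `expit(V'γ + ω2_i)` (logistic link);
* **latency** (gap-time hazard among the susceptible):
  `λ(t | U = 1, ω1_i) = λ0(t) exp(Z'β + ω1_i)` with a nonparametric
  (Breslow-step) baseline `Λ0`;
* **frailties**: a correlated, non-identical pair `(ω1_i, ω2_i)` driven by a
  single heterogeneity parameter `α`. For the clog–log model, `u1 = x·y`,
  `u2 = y/2` with `x ~ Beta(α, α)`, `y ~ Γ(2α, α)` gives unit-mean gamma
  marginals and `Corr(ω1, ω2) = √(ψ′(2α)/ψ′(α))`; for the logistic model a
  gamma × beta construction gives `Corr(ω1, ω2) = 1/√2 ≈ 0.707`. A shared
  single-frailty comparator model (`link = "identical"`) is included.

Estimation is Monte Carlo EM: a Metropolis-within-Gibbs E-step over the
subject-level frailties, posterior-weighted Breslow baseline updates,
Newton–Raphson and bounded 1-D M-steps, and Louis-method standard errors.
The matching data simulator, a replication-study harness (bias, MSE, Louis
SE calibration), Harrell's C-index with a 70:30 subject split, AIC model
ranking, long-format CSV IO including an adapter for the colorectal
readmission layout, and a small CLI round out the package. The methods and
every numerical choice are documented in
`vignettes/joint-frailty-cure.Rmd`.

## Worked example

Simulate a cohort of 400 subjects under the clog–log model (strong
dependence, `α = 0.5`) and fit it:

```r
library(curefrail)
sim <- simulate_recurrent_cure(400, link = "cloglog", gamma0 = 1, gamma = -5,
                               beta = -4, alpha = 0.5,
                               weibull_scale = 3, weibull_shape = 10, seed = 42)
fit <- fit_cure(sim, latency = ~z, incidence = ~v, link = "cloglog",
                control = mcem_control(K = 100, max_iter = 80, seed = 7))
fit
#> Joint frailty mixture cure model (cloglog link)
#>   779 records, 400 subjects, 379 events
#>   MCEM: 80 iterations, NOT converged (K = 100)
#> # A tibble: 4 × 4
#>   component term        estimate std.error
#>   <chr>     <chr>          <dbl>     <dbl>
#> 1 incidence (Intercept)    0.992    0.166
#> 2 incidence v             -4.60     0.431
#> 3 latency   z             -4.16     0.198
#> 4 frailty   alpha          0.450    0.0376
#>   logLik -2264.64  AIC 4537.28
```

The generating values (1, −5, −4, 0.5) are recovered within roughly one
standard error each. The incidence row for `v` says subjects with `v = 1`
are far more likely to stay susceptible (the clog–log link is decreasing:
larger `V'γ + ω2` means more likely cured); the latency row is a log hazard
ratio among the susceptible, and `alpha = 0.45` implies substantial
heterogeneity (frailty variance `1/α ≈ 2.2`) and log-frailty correlation
`√(ψ′(1)/ψ′(0.5)) ≈ 0.58`. "NOT converged" records that the ±0.001
two-iteration stopping rule was never met at this Monte Carlo size — the
trace (`autoplot(fit, "trace")`) shows the estimates flat long before the
iteration cap; see the vignette on convergence and Monte Carlo jitter.

`tidy(fit)` and `glance(fit)` give the broom-style views;
`autoplot(fit, "baseline")` plots the estimated cumulative baseline hazard.
Replication studies, e.g.,

```r
run_study(n = 1000, reps = 20, link = "cloglog", gamma0 = 1, gamma = -5,
          beta = -4, alpha = 0.5, weibull_scale = 3, weibull_shape = 10,
          control = mcem_control(K = 100, max_iter = 100), seed = 1)
```

report per-parameter mean estimate, MSE, empirical SD, and mean Louis SE
across replications, plus cure-rate diagnostics. A shell entry point does
the same from the command line (`exec/curefrail simulate|fit|study|evaluate`).

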