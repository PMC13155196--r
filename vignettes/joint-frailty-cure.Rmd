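---
title: "Joint frailty mixture cure models for recurrent gap times: model, estimation, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint frailty mixture cure models for recurrent gap times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`curefrail` fits mixture cure models to recurrent-event *gap times* — the
durations between successive events of the same subject, e.g., between a
hospital discharge and the next readmission. Two features of such data
motivate the model. First, after every recurrence a subject may be *cured*
(no further events will ever occur), and cured subjects can only be observed
as censored; the censoring mechanism is therefore informative. Second,
subjects differ in unobserved ways that affect *both* how likely they are to
remain susceptible and how quickly susceptible subjects recur. The model
captures both with a pair of correlated subject-level frailties.

For subject $i$ with gap times $t_{ij}$, event indicators $\delta_{ij}$,
latency covariates $Z_{ij}$ and incidence covariates $V_{ij}$ (with leading
intercept):

* **Incidence**: the latent non-cure status after each recurrence is
  $U_{ij} \sim \mathrm{Bernoulli}(\pi_{ij})$ with
  $\pi_{ij} = \exp\{-\exp(V_{ij}'\gamma + \omega_{2i})\}$ (complementary
  log–log link) or $\pi_{ij} = \mathrm{expit}(V_{ij}'\gamma + \omega_{2i})$
  (logistic link). An observed recurrence implies $U_{ij} = 1$; a censored
  record leaves $U_{ij}$ latent.
* **Latency**: given non-cure, the gap-time hazard is proportional,
  $\lambda(t \mid U=1, \omega_{1i}) = \lambda_0(t)\,
  e^{Z_{ij}'\beta + \omega_{1i}}$, with a nonparametric baseline
  $\Lambda_0$. Marginally on $U$,
  $S(t \mid \omega) = 1 - \pi + \pi\,e^{-\Lambda_0(t) e^{Z'\beta+\omega_1}}$.
* **Frailties**: a single heterogeneity parameter $\alpha > 0$ governs a
  correlated, non-identical pair $(\omega_{1i}, \omega_{2i})$, constructed so
  that the multiplicative frailties have mean one (identifiability against
  the baseline).

## The three frailty specifications

**Complementary log–log model.** With independent
$x \sim \mathrm{Beta}(\alpha, \alpha)$ and
$y \sim \Gamma(2\alpha, \text{rate } \alpha)$, set $u_1 = xy$ and
$u_2 = y/2$, $\omega_k = \log u_k$. Beta–gamma algebra gives the marginals
$u_1 \sim \Gamma(\alpha, \alpha)$, $u_2 \sim \Gamma(2\alpha, 2\alpha)$, so
$E[u_1] = E[u_2] = 1$, $V[u_1] = 1/\alpha$, $V[u_2] = 1/(2\alpha)$, and
$\mathrm{Corr}(\omega_1, \omega_2) = \sqrt{\psi'(2\alpha) / \psi'(\alpha)}$
($\psi'$ = trigamma), which is strictly positive and grows towards
$1/\sqrt{2}$ as $\alpha \to \infty$. The joint density, by a change of
variables, is
$f(u_1, u_2) = 2\alpha^{2\alpha} u_1^{\alpha-1} (2u_2 - u_1)^{\alpha-1}
e^{-2\alpha u_2} / \Gamma(\alpha)^2$ on $0 < u_1 < 2u_2$. All of these
identities are verified against the sampler in the test suite. All gamma
distributions in this package are shape–rate.

**Logistic model.** With independent
$u_1 \sim \Gamma(2/\alpha, \text{rate } 1/\alpha)$ and
$u_2 \sim \mathrm{Beta}(1/\alpha, 1/\alpha)$, set
$\omega_1 = \log(u_1 u_2)$ (so the latency multiplier $u_1 u_2$ has mean 1)
and $\omega_2 = \mathrm{logit}(u_2)$ (symmetric about 0). The key structural
fact, used throughout the implementation, is the gamma-splitting property:
$A = u_1 u_2$ and $B = u_1(1 - u_2)$ are *independent*
$\Gamma(1/\alpha, 1/\alpha)$ variables. Hence $\omega_1 = \log A$ and
$\psi = \omega_1 - \omega_2 = \log B$ are independent log-gammas, the joint
density of $(\omega_1, \omega_2)$ factors as
$f_{LG}(\omega_1) f_{LG}(\omega_1 - \omega_2)$ in closed form, the
conditional $f(\omega_2 \mid \omega_1)$ is exactly the log-gamma density of
$\psi$, and $\mathrm{Corr}(\omega_1, \omega_2) = 1/\sqrt{2} \approx 0.707$
for every $\alpha$ — a fixed correlation that is a known limitation of this
specification. Because these densities are available in closed form, no
numerical integration is needed for them; quadrature appears only as an
independent oracle in the tests.

**Identical-frailty comparator.** One shared $u_i \sim \Gamma(\alpha,
\alpha)$ enters both submodels ($\omega_{1i} = \omega_{2i} = \log u_i$, with
the clog–log incidence link). It is the natural null model against which the
dependent-frailty fits are compared by AIC.

# Estimation

All three models are estimated by Monte Carlo EM.

**E-step.** The per-subject posterior
$f(u \mid \text{data}; \theta_0) \propto \prod_j [\pi f_1]^{\delta_{ij}}
[1 - \pi + \pi S_1]^{1-\delta_{ij}}\, f(u)$ has no closed form, so each
subject gets a short Metropolis-within-Gibbs chain on the frailty
components. Sweeps alternate between *independence proposals from the prior
components* (exact in the no-data limit, cheap, and self-tuning when the
posterior is close to the prior) and *random-walk proposals* on the log or
logit scale with step 0.7 (which keep the chain mobile when the data pull
the posterior far from the prior). Chains are warm-started across EM
iterations: burn-in is 200 sweeps at the first iteration and 50 afterwards.
`K` retained draws per subject (the Monte Carlo size, default 1000) feed
every expectation; an acceptance rate below 1% for any subject triggers a
diagnostic warning. Beta-distributed states are kept strictly inside
$(0, 1)$ (at distance $10^{-14}$): with shapes below one the sampler can
otherwise produce floating-point 0 or 1, whose log-frailty is not finite.

**Posterior cure weights.** For a censored record the posterior probability
of being non-cured is the Bayes ratio
$\bar U = \pi S_1 / (1 - \pi + \pi S_1)$, evaluated per draw; events have
$\bar U = 1$. $\bar U$ decreases in the censored gap time: the longer a
subject goes event-free, the more likely they are cured.

**M-step, incidence ($\gamma$).** Newton–Raphson with analytic gradient and
Hessian and step-halving on the Monte Carlo expectation of the Bernoulli
complete-data log-likelihood,
$K^{-1}\sum_k \sum_{ij} \bar U^k \log \pi^k + (1 - \bar U^k) \log(1-\pi^k)$.
A variant objective (`eq9_mode = "as_printed"`) that additionally counts
$\delta \log \pi^k$ for events and a linearized censored term
$-(1-\delta)\pi^k$ is provided for comparison; it double-weights events and
is not the default because it is not the expectation of any single
complete-data likelihood and produced visibly biased recovery in our
simulation checks. Only a few Newton steps are taken per outer iteration
(generalized EM); the ascent property is enforced by step-halving.

**M-step, latency ($\beta$, $\Lambda_0$).** The baseline is profiled out by
a posterior-weighted Breslow estimator on the gap-time scale:
$d\Lambda_0(t_{(k)}) = d_k / \sum_{(i,j):\, t_{ij} \ge t_{(k)}}
w_{ij} e^{Z_{ij}'\beta}$, where the weight $w_{ij} = E[U_{ij} m_i \mid
\text{data}]$ is the joint posterior expectation of being non-cured times
the latency multiplier $m_i$ ($u_1$, $u_1u_2$, or $u$ by model). Censored
records thus stay in the risk sets in proportion to their posterior
susceptibility — the model's own answer to the question of how
possibly-cured records should contribute exposure. The same weights appear
in the cumulative-hazard term of the $\beta$ objective, so the alternation
(Breslow update, Newton step on $\beta$, at most 20 cycles) maximizes one
coherent profile objective; with all weights equal to one it reproduces the
classical Cox–Breslow estimate exactly (a test asserts agreement with
`survival::coxph` to $10^{-4}$). An `eq10_mode = "as_printed"` variant
restricts the cumulative-hazard term to event records only; it is retained
for comparison but mismatches the Breslow risk sets and is not the default.

**M-step, heterogeneity ($\alpha$).** Bounded scalar maximization of the
expected log frailty density over $\log\alpha \in [\log 10^{-3},
\log 10^{3}]$ (`stats::optimize`); hitting a bound raises a warning and
clips. The objectives are linear in sufficient posterior expectations
(verified against per-draw averages to $10^{-8}$): for the clog–log pair,
$N(\log 2 + 2\alpha\log\alpha - 2\log\Gamma(\alpha)) + (\alpha-1)\sum_i
(E\log u_1 + E\log(2u_2 - u_1)) - 2\alpha \sum_i E u_2$; for the shared
frailty, $N\alpha\log\alpha - \alpha\sum E u + (\alpha-1)\sum E\log u -
N\log\Gamma(\alpha)$. For the logistic model the default
(`alpha_mode = "full"`) fits the *full* joint frailty density — both
independent components $\log A$ and $\log B$ — which is the proper EM
M-step for the posterior the E-step targets. The alternative
(`alpha_mode = "stage1"`) uses only the conditional
$f(\omega_2 \mid \omega_1)$ term of the two-stage objective; in our
simulations at the logistic study design it overestimated $\alpha$ by about
20% (mean 1.10 at truth 0.91, versus 0.91 for the full objective), so the
full objective is the default.

**Two-stage logistic scheme.** The logistic fit alternates a stage that
updates $(\beta, \Lambda_0, \alpha)$ from the event terms plus the frailty
component, and a stage that updates $\gamma$. The censored-record objective
$\sum (1-\delta)\,(-\pi(1 - S_1^0))$ — a first-order expansion of
$\log(1 - \pi(1-S_1^0))$, with linearization error bounded by
$x^2/(2(1-x))$, $x = \pi(1-S_1^0)$, and exposed as a diagnostic — contains
no event term in $\pi$ and is therefore monotone decreasing in every
$\pi_{ij}$: on any data set with censoring its maximizer in $\gamma$ is
unbounded below. The package therefore defaults to the Bernoulli
$\bar U$-weighted update for $\gamma$ (`gamma_mode = "binomial"`), with the
literal stage-2 objective available box-constrained
(`gamma_mode = "as_printed"`, $\|\gamma\|_\infty \le 20$) for comparison.

**Standard errors.** The Louis identity
$I = E[-B_c] - \{E[S_c S_c'] - S_m S_m'\}$ is evaluated block-wise
($\gamma$, $\beta$, $\alpha$) over the final E-step draws, with the latent
cure statuses integrated out analytically (the scores are linear in $U$, so
conditional means and Bernoulli variances enter in closed form). The
baseline is profiled, so the $\beta$ block is conditional on
$\hat\Lambda_0$ — mildly optimistic, as in most semiparametric frailty
software. A block that is not positive definite (possible when the missing
information is nearly total, e.g., under very high cure rates, or from
Monte Carlo noise) is inverted after flooring its eigenvalues, yields
deliberately conservative (large) standard errors, and flags the fit.

**Observed-data likelihood and AIC.** The observed log-likelihood is
estimated by importance sampling from the frailty prior (default 500 fresh
draws per subject) and AIC is $-2\hat\ell + 2(p + q + 1)$, counting the
regression coefficients and $\alpha$ but not the baseline increments, the
usual semiparametric convention. These AICs compare the models of this
package against each other; they are not comparable to fully parametric
AICs.

**Initialization, convergence, Monte Carlo size.** $\beta$ starts at a
no-frailty Cox fit, $\gamma$ at a no-frailty binomial GLM using the event
indicator as a cure-status proxy (its coefficients are capped at $\pm 8$,
since that GLM separates whenever a covariate arm has no events), and
$\alpha = 1$. Convergence requires the largest absolute change in
$(\beta, \gamma, \log\alpha)$ to stay below `tol` (default $10^{-3}$) for
two successive iterations, which guards against Monte Carlo jitter
triggering a spurious stop; with small `K` the jitter can exceed `tol`
indefinitely, in which case the fit runs to `max_iter` and is flagged
non-converged even though the estimates have long stabilized. For this
reason the study harness keeps non-converged fits in its aggregates (and
counts them) rather than silently excluding them. To save time the first
60% of iterations use a quarter-size Monte Carlo sample (`k_ramp`), with
convergence only declarable in the full-size phase.

# The data simulator

`simulate_recurrent_cure()` generates data exactly under the model: per
subject a censoring time $C \sim U(0, 5)$ (one abstract time unit scale —
think years — shared by the censoring horizon and the Weibull baseline
$\Lambda_0(t) = \lambda t^\mu$), a frailty pair, and Bernoulli(0.5)
covariates $Z, V$ drawn once per subject (constant across that subject's
records, matching how sex, chemotherapy and stage behave in readmission
data). Gap times are drawn by inverting the conditional survival,
$t = \{-\log W / (\lambda e^{Z\beta} m)\}^{1/\mu}$; generation stops when a
cured status is drawn (one final censored record with the remaining time to
$C$) or when the cumulative time crosses $C$ (censored crossing record).
The latent truth (frailties, cure flags, $C$) is attached to the returned
tibble, and three distinct "cure rate" diagnostics are reported — the
latent subject-level cure fraction, the record-level censoring fraction,
and the mean per-record non-cure probability — because these genuinely
differ and summaries in this literature do not always say which one they
report.

What the simulator does *not* emulate: covariates that vary within subject,
time-dependent covariates, left truncation, interval censoring, a terminal
event competing with recurrence (death enters only through $C$ and the cure
mechanism), or model misspecification of any kind. Passing recovery tests
on these data therefore demonstrates internal consistency of the estimator
under its own assumptions — not robustness on real registries.

# Study designs, problem sizes, and known limitations

The recovery studies shipped in the tests and the acceptance script use
N = 1000 subjects with 8–20 replications and Monte Carlo sizes K =
100–1000, with EM iteration caps of 40–150 chosen so that the parameter
traces are flat well before the cap at each design; these sizes are the
package's desk-scale choices (simulation studies in the literature commonly
use 250 replications, which the harness supports via `reps`).

Three estimation-side findings from those studies are worth knowing:

* **Extreme cure fractions break incidence identifiability.** At a design
  with a large positive incidence coefficient (e.g., $\gamma = 2.5$ with a
  clog–log link), one covariate arm has essentially no events; its
  coefficient is then separated — the likelihood increases monotonically in
  $\gamma$ — and any finite estimate reflects the stopping rule, not the
  data. The same design leaves under 5% of subjects ever experiencing an
  event, so the frailty parameter is close to non-identified and the EM
  stays near its starting value. The package reports what the data support;
  users should read enormous incidence standard errors or a pinned
  $\hat\alpha$ as the diagnostic it is.
* **The logistic model is the more fragile specification**: fixed 0.707
  frailty correlation, an approximate (linearized) censored-data objective,
  and a $\gamma$ update that is only well posed in its Bernoulli form. It
  also tends to need more EM iterations than the clog–log model.
* **Tied gap times** are handled by the Breslow convention throughout;
  gap times of exactly zero are rejected at the door.

Degenerate inputs: datasets with no events are refused; subjects with no
records reproduce the frailty prior in the E-step; events sitting at gap
times with zero estimated baseline mass yield a flagged $-\infty$
objective rather than a crash.
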