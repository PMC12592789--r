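---
title: "Joint modelling of irregularly observed longitudinal outcomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of irregularly observed longitudinal outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sunjoint)
```

## The model

For subjects $i = 1, \dots, n$ observed on $[0, \tau)$, let $Y_i(t)$ be the
outcome, $X_i$ a vector of time-invariant covariates, $N_i(t)$ the counting
process of visit (assessment) times, $C_i$ the end of follow-up, and
$\Delta_i(t) = I(C_i \ge t)$ the at-risk indicator. A positive subject-level
frailty $\nu_i$ with $E(\nu_i \mid X_i) = 1$ couples the outcome and visit
processes:

$$E\{Y_i(t) \mid X_i, \nu_i\} = \nu_i\, \mu_0(t)\, e^{X_i'\beta}, \qquad
  \lambda(t \mid X_i, \nu_i) = \nu_i\, \lambda_0(t)\, e^{X_i'\gamma}.$$

Outcomes are only seen at jumps of $N_i$; because $\nu_i$ multiplies both
intensities, subjects with systematically high (or low) outcomes are seen
more (or less) often, and a regression on the pooled visit records is
confounded. The model assumes the outcome, visit and censoring processes are
conditionally independent given $(X_i, \nu_i)$, covariates are
time-invariant, and censoring is non-informative.

## Estimation

**Stage 1 — the visit process.** `fit_visit_model()` estimates $\gamma$ by
the Andersen–Gill partial likelihood on the recurrent visit events
(counting-process intervals, Breslow tie handling), delegating the
maximization to `survival::coxph()`. The marginal visit intensity given $X$
alone is still proportional because $E(\nu \mid X) = 1$, so the unweighted
partial likelihood is consistent for $\gamma$ even though the frailty is not
modelled. The cumulative baseline is the Breslow step function
$$\hat\Lambda_0(t) = \sum_{u \le t} \frac{\sum_i \Delta_i(u)\, dN_i(u)}
  {\sum_i \Delta_i(u)\, e^{X_i'\hat\gamma}},$$
with unit frailty weight in the denominator. This convention is deliberate:
the frailty-moment estimators below are defined in terms of exactly this
baseline, and using it first breaks what would otherwise be a circular
definition (the $\hat\omega$-weighted denominator appears only afterwards,
inside the extended estimating equation). A gamma-frailty penalized fit
(`frailty = "gamma"`) is provided for data analyses where an explicit
frailty-adjusted $\hat\gamma$ is preferred; the simulation engine uses the
unweighted fit throughout.

**Stage 2 — frailty moments.** Given $(X_i, \nu_i, C_i)$ the visit count
$m_i$ is Poisson with mean $\nu_i \Lambda_0(C_i) e^{X_i'\gamma}$, so matching
the first two conditional moments of $m_i$ gives
$$\hat\omega_i = \frac{m_i}{\hat\Lambda_0(C_i)\, e^{X_i'\hat\gamma}}, \qquad
  \hat\Omega_i = \frac{m_i(m_i - 1)}{\hat\Lambda_0(C_i)^2\, e^{2X_i'\hat\gamma}},$$
estimating $\nu_i$ and $\nu_i^2$. Subjects with $m_i \le 1$ get
$\hat\Omega_i = 0$ and with $m_i = 0$ also $\hat\omega_i = 0$: they carry no
usable information about their own frailty and enter later stages only
through risk sets.

**Stage 3a — relative effects only.** `fit_sun()` solves
$U(\beta) = n^{-1}\sum_i \int (X_i - \bar X(t;\beta)) \Delta_i Y_i\, dN_i = 0$
with the $\hat\Omega$-weighted at-risk average $\bar X$. The weight process
that sometimes premultiplies the integrand in this family of equations is
taken as the identity: the derivation from the zero-mean process has no such
weight, and any fixed choice leaves the estimand unchanged. The intercept
function is differenced out, so only $\beta$ is recovered.

**Stage 3b — the extended estimator.** `fit_sun_extended()` parameterizes
$\mu_0(t) = \exp\{B(t)'\alpha\}$ on a B-spline basis and solves, for
$\eta = (\beta, \alpha)$ and $Z_i(t) = (X_i, B(t))$,
$$L(\eta) = \sum_i \int_0^\tau \Big[ Z_i(t) Y_i(t) e^{-Z_i(t)'\eta} -
  S(t) \Big] \Delta_i(t)\, dN_i(t) = 0, \quad
  S(t) = \frac{\sum_j \Delta_j \hat\Omega_j e^{X_j'\hat\gamma} Z_j(t)}
              {\sum_j \Delta_j \hat\omega_j e^{X_j'\hat\gamma}}.$$
The inverse-mean weighting $e^{-Z'\eta}$ is an inverse-variance weighting
under a Poisson-type variance and is what makes the estimator efficient when
outcomes span orders of magnitude. $S(t)$ does not involve $\eta$, so it is
precomputed once per visit time; the Jacobian
$-\sum Z Z' Y e^{-Z'\eta}$ is analytic and negative semidefinite, and Newton
iteration with step-halving converges in a handful of steps.

The marginal mean recovered by the fit is
$E\{Y_i(t) \mid X_i\} = \exp\{B(t)'\hat\alpha + X_i'\hat\beta\}$
(`predict_trajectory()`); note the exponential link — the same multiplicative
structure as the conditional model, with the frailty integrated out.

## The spline basis

Raw B-splines form a partition of unity, so the package keeps an explicit
intercept column and drops the first raw column, giving a full-rank basis of
dimension $K = 1 + (\text{interior knots} + \text{degree})$. Any drop-one
choice spans the same space, so this is a parameterization, not a modelling
choice. Interior knots sit at the $j/(k+1)$ quantiles of the pooled visit
times (type-7 quantiles); the boundary defaults to $(0, \tau)$. Defaults are
cubic splines with 4 interior knots for simulations and 3 for the
moderate-sized case study — quantile placement follows the observed
visit-time distribution, which is the only placement that makes sense when
the visit process itself is random. Basis columns are mean-centered over the
visits before solving (folded back into the intercept afterwards); with
log-scale outcomes spanning $e^{2}$ to $e^{14}$ this keeps the Newton
iteration well conditioned.

## Numerical choices

* Andersen–Gill: `coxph` with Breslow ties, score tolerance $10^{-9}$,
  at most 50 iterations; constant covariate columns are rejected up front
  (they are unidentifiable — absorbed by $\lambda_0$ or $\mu_0$).
* Extended equation: Newton with analytic Jacobian, start $\eta = 0$,
  tolerance $10^{-8}$ on $\max|L|$, at most 100 iterations, step-halving
  when the norm does not decrease; rank of the positive-outcome design is
  checked first and dependent columns are reported by name.
* Relative-effects equation: damped Newton with central-difference Jacobian
  (step $10^{-5}(1 + |\beta|)$), same tolerances.
* Step functions are right-continuous with value 0 before the first jump;
  $\hat\Lambda_0(C_i)$ uses right-continuous lookup, and visits at exactly
  $t = C_i$ are legal ($\Delta_i$ is inclusive).
* Ties across subjects are handled by the Breslow convention throughout.
* Visits with a recorded time but missing outcome stay in the visit counts
  and risk sets (they are genuine assessments) and are excluded only from
  the outcome-level sums.

## The bootstrap

`bootstrap_fit()` resamples subjects with replacement — visits are dependent
within subject, so the subject is the exchangeable unit — and refits the
*entire* pipeline per resample: $\hat\gamma$, $\hat\Lambda_0$, moments, and
the estimator, with spline knots recomputed from the resample's own pooled
visit times so the interval reflects basis variability too. Per-resample
seeds derive from one master seed, so results are bit-reproducible. Percentile
95% intervals are reported on both the coefficient and the exponentiated
(mean-ratio) scale; failed resamples are dropped, with an error if more than
10% fail.

## The simulation engine

`generate_dataset()` emulates a frailty-coupled design: $X \sim$
Bernoulli(1/2) or $N(0, 0.25)$; frailty $\nu = e^{-\log(2.75) g}\nu^*$ with
$g$ the covariate (or its nonnegativity indicator) and $\nu^* \sim U(0.5,
1.5)$ or $U(1.5, 4)$ by group — both branches have $E(\nu \mid X) = 1$;
censoring $C \sim U(1, 1.1\tau)$ truncated at $\tau$; visits from a
homogeneous Poisson process of rate $\nu e^{0.5X}$ on $(0, C]$; outcomes
$\log Y = \log\nu + m_0(t) + X\beta_0 + \varepsilon$ with $\varepsilon \sim
N(-0.0625, 0.1225)$ (so $E e^\varepsilon = e^{-0.00125} \approx 1$; the small
mean offset is kept as stated rather than recalibrated to exact unity).

The default intercept families are, on the log scale, $\log(1+t) + 2(t+1)$,
$\sin(t) + 2(t+1)$ and $\sin(4t)$. The first two grow linearly in $t$, so
outcomes at late follow-up are several orders of magnitude larger than early
ones. That is a deliberate stress regime: the extended estimator's
inverse-mean weighting normalizes the outcomes and keeps its variance
essentially flat in $\tau$, while unweighted estimating equations and
log-link marginal regression are dominated by the few largest late-time
records and lose efficiency as follow-up lengthens — the qualitative ordering
the test suite asserts. The sinusoidal family is bounded and instead stresses
the spline's ability to track rapid fluctuation; with the default quantile
knots none of the estimators recovers $\sin(4t)$'s trajectory well, which is
the known limitation of a fixed low-dimensional basis. The registry accepts
arbitrary functions, so gentler intercepts are one argument away.

Draw order within a replicate is fixed (per subject in id order: covariate,
frailty, censoring time, exponential gaps, outcome errors), and replicate
seeds derive from the scenario's master seed, so every dataset and summary is
reproducible bit-for-bit.

What the generator does *not* emulate: time-varying covariates (excluded by
the model itself), informative censoring, measurement-error correlation
within subject, or discrete/tied visit times. Passing simulations therefore
say nothing about those regimes; the residual diagnostic is the tool for
judging the intercept's functional form on real data.

Simulation summaries in the test suite use 505 replicates per scenario
(matching the convention of reporting empirical standard errors from ~500
draws); bias and ESE are computed per estimator over its completed
replicates, and replicate failures are tracked and flagged if they exceed 5%.

## The marginal comparator

`fit_gee_spline()` fits the same spline-plus-covariates design by a log-link
marginal regression with working independence (the quasi-Poisson score
$\sum Z (y - e^{Z'\theta}) = 0$ over all visit records). Working independence
is the minimal structure that isolates the consequence of *ignoring* the
frailty coupling; under the coupled generator its probability limit for
$\beta$ is shifted by $\log E(\nu^2 \mid X = 1) - \log E(\nu^2 \mid X = 0)$,
a closed form the tests check against. Standard errors for all estimators
come from the pipeline bootstrap, not from model-based formulas.

## Residual diagnostic

For each subject,
$$R_i(t) = \int_0^t \Delta_i(u)\, e^{-Z_i(u)'\hat\eta - X_i'\hat\gamma}
  Y_i(u)\, dN_i(u) - \hat\Omega_i \hat\Lambda_0(C_i \wedge t),$$
and $\mathrm{Res}(t) = n^{-1}\sum_i R_i(t)$ converges to zero in probability
under a correctly specified intercept basis. The package evaluates it on a
default grid of 100 equally spaced points on $[0, \tau]$ (the curve is
piecewise constant between event times, so any grid refinement is
value-preserving at shared points). $\hat\Omega_i$ stands in for the
unobservable $\nu_i^2$. This is a plotting diagnostic by design — no test
statistic is attached, since formal lack-of-fit tests in this setting tend to
be badly powered in one direction or the other. Covariate functional form is
out of scope; the diagnostic targets the intercept.

## Known limitations

* The intercept must be expressible (approximately) on the chosen basis;
  rapidly fluctuating trajectories need either more knots or a
  nonparametric treatment that this package does not provide.
* The closed-form asymptotic variance of the extended estimator involves
  expansions around the infinite-dimensional baseline and is unstable at
  practical sample sizes; the package deliberately offers bootstrap
  inference only.
* Frailty moments are poorly determined for subjects with very few visits
  ($\hat\Omega_i = 0$ whenever $m_i \le 1$); designs with very short
  follow-up lean heavily on the minority of multiply-observed subjects.
* Covariates must vary across subjects and contain no intercept column, and
  the visit process must be conditionally Poisson-like for the moment
  estimators to be consistent.
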