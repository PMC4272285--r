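---
title: "Optimal survey effort under stochastic detectability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal survey effort under stochastic detectability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveyopt)
```

## The model

During active search, detections of a present species are assumed to occur
as a Poisson process with rate $\lambda$, so a single survey of search
length $t$ misses the species with probability $e^{-\lambda t}$. The rate
is not constant: activity, weather, observers and season make $\lambda$
effectively a random variable across visits, with mean $\mu$, standard
deviation $\sigma$, and coefficient of variation $\theta = \sigma/\mu$,
taken to be lognormally distributed. Over $n$ surveys with independent
rates $\lambda_1,\dots,\lambda_n$ the probability of failing to detect is

$$Q \;=\; \exp\!\Big(-\textstyle\sum_i \lambda_i t_i\Big) \;=\; e^{-A},$$

where $A$ is the total expected number of detections. With the budget
constraint $B = n(c + t)$ — each survey paying a fixed non-search time $c$
— and effort divided equally, $A$ has mean $\mu_A = n\mu t$ and variance
$\sigma_A^2 = n\sigma^2 t^2$. The sum of lognormal terms is itself
approximated as lognormal by matching these two moments (the
Fenton–Wilkinson method): $X = \ln A \sim N(m, v)$ with
$v = \ln(1 + \sigma_A^2/\mu_A^2) = \ln(1 + \theta^2/n)$ and
$m = \ln \mu_A - v/2$ (`moment_match()`; the matched mean and variance are
exact to machine precision, a property the tests verify on a grid).

Time units cancel once the budget and cost are expressed in units of the
mean time to first detection, $1/\mu$: with $B' = B\mu$ and $c' = c\mu$,
$\mu_A = B' - nc'$ and everything depends only on $(B', c', \theta)$. The
package validates unit consistency exactly this way — an invariance test
rescales $(\mu, \sigma, B, c)$ jointly and requires identical results to
$10^{-9}$ — and never converts units itself.

## The two objectives

**Expected detection.** $E[Q] = E[\exp(-e^X)]$ has no closed form; it is a
smooth one-dimensional integral, evaluated by Gauss–Hermite quadrature with
120 nodes on the $X$ scale (`expected_q()`). Against adaptive quadrature
the rule agrees to below $10^{-10}$, which is the package's working
tolerance; against Monte Carlo draws from the matched lognormal it agrees
to sampling error. `optimal_n_expected()` enumerates every feasible integer
$n$ (those with $t = B/n - c > 0$) and returns the minimizer of $E[Q]$,
breaking ties toward smaller $n$ — fewer trips at equal performance.
Enumeration over at most $\lceil B/c \rceil - 1$ candidates is exact and
cheap, so it is the reference answer everywhere in the package.

**Satisficing.** A design may instead be judged by the chance that the
realized failed-detection probability beats an acceptable level $Q_c$
(equivalently, that the detection probability exceeds $1 - Q_c$). Because
$Q < Q_c \iff X > X_c$ with $X_c = \ln(-\ln Q_c)$, this assurance has the
closed form $\Pr(Q < Q_c) = \Phi\big((m - X_c)/\sqrt{v}\big)$
(`prob_target()`). `optimal_n_satisficing()` maximizes the equivalent
normal $z$-statistic $(m - X_c)/\sqrt v$ rather than $\Phi(z)$ itself: at
small $\theta$ the probabilities saturate to exactly 1 in double precision
and would tie arbitrarily, while $z$ still ranks designs. Where $\Phi$
distinguishes designs the two argmaxes coincide (a tested equivalence).

**Degenerate branches.** $\theta = 0$ (and $v = 0$) is handled as an
explicit point mass, not a limit: $E[Q] = e^{-(B'-nc')}$ exactly, the
assurance is an indicator, and the cdf of $Q$ is a step at
$e^{-e^m}$ — avoiding $0/0$ in the cdf transform. Arguments $q \in \{0,1\}$
to `q_cdf()` are rejected rather than clamped, since $Q$ is an
open-interval quantity. With no variability a single long visit is optimal,
recovering the classical rule; the tests pin this.

## Closed-form approximations

For the expected-detection objective, applying Laplace's method to the
integral and optimizing the resulting leading-order exponent — equivalently
maximizing $\ln \mu_A - 2v$, whose stationarity condition is free of $c'$ —
gives the positive root of

$$n^2 + 3\theta^2 n - 2\,(B/c)\,\theta^2 = 0, \qquad
n^\ast = \tfrac{3\theta^2}{2}\Big(\sqrt{1 + \tfrac{8B}{9c\theta^2}} - 1\Big),$$

which depends only on the budget-to-cost ratio and $\theta$
(`approx_n_expected()`). It tends to 0 as $\theta \to 0$ (clamped to a
single visit) and grows with both arguments. Because the signature carries
no rate, the continuous root is rounded to the nearest feasible integer.
The approximation is validated against enumeration: it never achieves a
better objective value, costs essentially nothing at moderate variability
(for $B/c = 15$, $c' = 0.5$ the computed losses are $10^{-4}$, $\approx 0$
and $0.022$ probability units at $\theta = 0.5, 1, 3$), and degrades only
in the corner of tiny scaled budgets with large $\theta$, where the
computed worst case on the tested grid is about $0.06$. In the treefrog
case study the approximation prescribes 5 surveys at both abundance
levels, at a computed cost of $0.015$ and $0.0012$ probability units.

For the satisficing objective, maximizing $(m - X_c)/\sqrt v$ in continuous
$n$ under the small-$\theta$ expansion $v \approx \theta^2/n$ yields the
explicit solution

$$n^\ast = \frac{B'}{c'}\left(1 - \frac{2}{W(2B'e^{2 - X_c})}\right),$$

with $W$ the Lambert W function (`approx_n_satisficing()`). The scaled
fixed cost appears only as the leading factor — doubling $c'$ halves the
prescription — and a tougher target (larger $X_c$) prescribes fewer, longer
surveys. Here the continuous value is rounded by comparing the exact
$z$-statistic at its floor and ceiling. Although derived for small
$\theta$, it matches enumeration exactly in both treefrog cases
($\theta = 2.5$) and on over 90% of a $\theta = 0.1$ validation grid.
`solve_implicit_satisficing()` exposes the untruncated first-order
condition $2v\,m' = (m - X_c)\,v'$, solved by bracketed bisection to
$10^{-8}$; when the root is an interior maximum, the integer optimum is its
floor or ceiling.

## Minimum-effort protocols

`min_budget_expected()` and `min_budget_satisficing()` invert the design
problem: the smallest scaled budget whose best achievable performance
(re-optimizing $n$ at every budget) reaches a required level. Both use
bisection to $10^{-6}$ on a bracket $[c' + 10^{-6}, B'_{hi}]$ with the
upper end doubled until the requirement is met — valid because the inner-
optimized performance is monotone in the budget. With $\theta = 0$ the
closed forms $-\ln(1 - p) + c'$ and $-\ln Q_c + c'$ (one visit, one fixed
cost) are returned directly. At $c' = 0$ splitting is free and the curve is
reported at its variance-free limit $1 - e^{-B'}$. For a variable rate
($\theta = 1.5$, $c' = 0.5$, $Q_c = 0.1$) the package computes under 50%
assurance at $B' = 3$ and a minimal budget of about $8.56$ for 90%
assurance — the cost of stochasticity, since a constant rate needs only
$B' = 2.8$. For 98% assurance the computed minimal budget is about
$11.2$.

## The simulation oracle and the moment-matching error

`simulate_q()` draws the $n$ per-survey rates jointly lognormal and forms
$Q$ directly from the sum — the model with no lognormal-sum approximation —
so it is the independent check on the analytic layer, reproducible by seed.
Correlation between visits is imposed on the log-rate scale through a
Gaussian copula, either exchangeable or AR1 with surveys spaced $T/n$
through a season of length $T$; $r$ is the log-scale correlation at lag one
time unit. This is an approximation to a fully specified temporal process,
chosen because it needs only $(r, T)$ and reduces exactly to the
independent and perfectly correlated ends. At $r = 1$ repeat visits carry
no diversification benefit and a single survey becomes optimal; at $r = 0$
the simulated optimum matches the analytic one within the near-optimal
band. `correlation_sensitivity()` tabulates the simulated optimum along an
$r$ grid.

The Fenton–Wilkinson match is exact in its first two moments but not in
distribution, and the package measures rather than assumes its accuracy:
`wilkinson_error()` reports analytic-minus-simulated values for both
objectives. The bias is negligible for $\theta \lesssim 0.8$ (the
oracle-agreement tests run on a 32-point grid there, within
$\max(3\,\mathrm{SE}, 0.01)$), reaches about $0.01$ on the assurance near
$\theta = 1$, and grows to roughly $+0.02$ on $E[Q]$ and $-0.07$ on the
assurance by $\theta = 2.5$. Design conclusions are less affected than
values, because the bias shifts whole curves more than it reorders $n$; a
dedicated test keeps this documented envelope honest.

## Estimating the rate distribution

Two record shapes are supported, mirroring how such data are collected.

**Censored time-to-first-detection** (`fit_time_to_detection()`): within an
observer-by-quadrat search unit, time to first detection is exponential
given that unit's rate; rates vary across units as a lognormal. The random
effect is integrated out by 30-node Gauss–Hermite quadrature (checked
against brute-force Monte Carlo integration to $10^{-3}$) and the marginal
likelihood maximized from two spread starting values, since the likelihood
can be flat near the $\sigma = 0$ boundary. A search ending at the session
length contributes $e^{-\lambda \cdot \text{session}}$. A single unit
cannot identify between-unit spread and falls back, flagged, to the
fixed-rate exponential MLE.

**Repeat-survey counts** (`fit_rate_counts()`): detections per visit are
Poisson with exposure `search_time` and log rate
$\alpha + \beta \ln(\text{abundance}) + \varepsilon$, with a normal
visit-level deviate $\varepsilon$. Here the quadrature is *adaptive* —
nodes recentred at each observation's conditional mode with its curvature —
because a large count shifts the integrand far from the prior mode and a
fixed rule loses several digits. The fit agrees with `lme4::glmer`
(observation-level random effect, `nAGQ = 25`) to $10^{-3}$ in all
parameters in the test suite, with `glmer` serving only as a cross-check.
`predict_rate()` shifts the mean by $\text{abundance}^\beta$, leaving
$\theta$ unchanged. These are maximum marginal likelihood versions of the
hierarchical models one would also fit by MCMC; they capture the same
distributional skeleton with far lighter dependencies, and their Wald
intervals (delta method on the log scale) achieve the intended coverage in
the recovery studies below.

Temporal correlation in the rate is *not* estimated — in sparse survey data
it is barely identifiable — and is instead an input to the simulation
layer.

## Model-free empirical optima

For search-experiment data the package also computes optima with no rate
model at all. With $v$ observer-by-quadrat combinations and search time
$t = B/n - c$, the empirical failure probability is $(y/v)^n$, where $y$
counts combinations *without* a detection by time $t$. (Stated the other
way around — counting detections — the quantity could not be a failure
probability; the package uses the failure count.) `empirical_optimal_n()`
minimizes this over feasible $n$. For the satisficing objective, meeting
$Q_c$ is equivalent to accruing $-\ln Q_c$ expected detections, and
`satisficing_resample()` estimates the probability of doing so by
resampling per-combination empirical rates with replacement — one million
replicates by default, with per-$n$ streams derived from a master seed so
the proportions are comparable across $n$. Both procedures are tested
against exhaustive enumeration on small fixtures, and
`predicted_vs_observed()` summarizes model-vs-data agreement by the OLS
slope and Pearson correlation.

## Synthetic data

`gen_quadrat_experiment()` and `gen_repeat_surveys()` generate both record
shapes from a `scenario_spec()` with known ground truth, reproducibly by
seed; shipped YAML presets (`load_scenario("frog")`, `"plants"`) encode the
two case-study settings (stream transects: $\mu = 0.67$/h at abundance 1,
$\theta = 2.5$, $B = 10$ h, $c = 1$ h, a 90-night season, 29 sites visited
2–9 times; quadrat searches: 14 observers × 9 quadrats, 15-minute
sessions, $\mu \approx 0.55$–$0.56$/min, $\sigma \approx 0.60$–$0.64$). The
frog preset's abundance exponent $\beta = 1.082$ makes the mean rate rise
from 0.67 to 2.2 between abundance 1 and 3, as the fitted case study
reports; its per-site visit counts average 3.2. The generators emulate
lognormal rate variation, censoring, abundance structure, and log-scale
correlation; they do not emulate observer-experience effects, spatial
structure within quadrats, time-to-second-detection, or rate drift within a
season. Passing recovery tests therefore demonstrates correctness of the
estimators under the model, not robustness to real-data features outside
it — the model-free empirical procedures exist precisely for that gap.

## Recovery studies and problem sizes

The always-run test suite uses problem sizes chosen to give each check
real power while keeping the whole suite around a minute of quadrature and
simulation work: 100 simulated datasets per estimator for the recovery
studies (126 censored-time units, or 29 sites with 2–9 visits), requiring
mean-rate bias under 10% and 95%-interval coverage of at least 90%;
$4\times10^4$–$10^6$ replicates for the Monte Carlo agreement and
resampling checks; and exhaustive enumeration (up to $5^4$ outcomes) as
the oracle for the resampling procedures.

## Known limitations

* The lognormal-sum approximation biases both objectives at large $\theta$
  (quantified above); enumerated optima there should be read together with
  `wilkinson_error()` and, if needed, `correlation_sensitivity()`.
* Surveys are equal-length by construction; unequal allocations are out of
  scope.
* The satisficing assurance at moderate budgets can be far below 1 even at
  the optimum — the package reports the achieved assurance so that targets
  can be renegotiated rather than silently missed.
* Empirical optima inherit the sampling noise of the underlying search
  experiment; their resampling uncertainty is visible in the returned
  grids.
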