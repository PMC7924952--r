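---
title: "A five-state model of fracture, refracture, and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A five-state model of fracture, refracture, and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracmsm)
```

## The model

`fracmsm` implements a continuous-time Markov multistate model of bone
health in people aged 60 and over. An individual occupies one of five
states: (1) alive without an incident fracture, (2) first incident
fracture, (3) second fracture, (4) third or further fracture, and (5)
death. Seven transitions are allowed — from each pre-death state either to
the next fracture state or to death — and none go backwards, so the model
is *progressive* and death is *absorbing*.

The engine of everything is the generator matrix $Q$. Its off-diagonal
entries are the transition intensities $q_{rs}$, instantaneous per-year
rates of moving from state $r$ to state $s$; the diagonal is
$q_{rr} = -\sum_{s \ne r} q_{rs}$ so that rows sum to zero. Covariates act
proportionally on each intensity,

$$q_{rs}(z) = \exp\!\left(\alpha_{rs} + \beta_{rs}^\top z\right),$$

where $z$ is the individual's coded deviation from a reference profile and
$\exp(\beta_{rs,k})$ is the hazard ratio of covariate $k$ on that
transition. From $Q$ follow all the risk outputs:

* **Transition probabilities** over a horizon $t$:
  $P(t) = e^{tQ}$, computed by scaling-and-squaring with Padé
  approximation (`Matrix::expm()`). `transition_probability()` returns the
  full row-stochastic matrix; `five_year_matrix()` presents it on the
  percent scale of a published risk table.
* **Sojourn times**: under time-constant intensities the expected stay in
  state $r$ before any exit is $-1/q_{rr}$ (`sojourn_times()`).
* **Cumulative mortality**: $P_{r5}(t)$, nondecreasing in $t$
  (`cumulative_mortality_curve()`).
* **Skeletal age**: a mortality hazard ratio $H$ is translated into an
  effective-age shift of $\log H / \log h$ years, with $h \approx 1.1$ the
  approximate annual proportional growth of mortality risk after age 60;
  skeletal age is chronological age plus that shift (`skeletal_age()`).
  The translation is age-invariant and additive in $\log H$.

```{r}
Q <- build_generator(dubbo_parameters("men"), reference_profile(sex = "male"))
round(100 * transition_probability(Q, 5), 1)
skeletal_age(70, 1.67)
```

## Covariate coding and the reference profile

Published per-transition hazard ratios rarely state their per-unit scale,
so the coding is explicit and configurable (`covariate_coding()`). The
defaults fix the reference ("typical") profile at a 70-year-old woman with
femoral neck BMD T-score $-1.5$, BMI 26.6 kg/m², no fall history, prior
fracture, or comorbidities, and scale continuous covariates as: age per
+5 years at state entry; T-score per SD *lower* (a positive coefficient
means lower BMD is harmful); BMI per +5 kg/m². The age covariate is
*time-variant between states but constant within them*: it is refreshed to
the age at entry of each state, which avoids immortal-time bias without
introducing within-state time dependence (a deliberate simplification;
see Limitations). `piecewise_transition_probability()` is provided for
prediction horizons that cross known intensity changes.

## Likelihood and fitting

Fracture dates (radiology-confirmed) and death dates (registry) are
treated as exactly observed; the default likelihood is therefore the
exact-time one: a sojourn of length $d$ in state $r$ contributes
$-d\sum_s q_{rs}(z)$, plus $\log q_{rs}(z)$ if it ends in an observed
transition. This likelihood factorizes over transitions into independent
inhomogeneous-Poisson terms, so `fit_mle()` optimizes each transition
block separately (BFGS with analytic gradient, started at the closed-form
rate $n_{rs}/T_r$) and takes the covariance from the inverse analytic
observed information, block-diagonal across transitions. Convergence is
declared at a relative log-likelihood change below `1e-12` with a scaled
score below `1e-4`; non-convergence is a loud warning carrying the last
iterate, never silent. A transition with zero observed events sits on the
boundary of the parameter space (rate 0): it is flagged, reported with an
infinite log-scale estimate, and excluded from optimization.

Two degenerate-input rules are fixed by convention: a fracture and death
recorded on the same day are ordered fracture first, and two same-day
fractures collapse into a single state increment (state 4 absorbs all
further fractures). Individuals with fractures predating study entry
enter state 1 with `prior_fracture = 1` — prior fracture is a covariate,
not a state.

A *panel* likelihood (`panel_loglik()`, `fit_mle(likelihood = "panel")`)
is available for visit-based observation: consecutive snapshots contribute
matrix-exponential entries $P_{rs}(\Delta t)$, and a death at a known
registry date contributes the density $\sum_k P_{rk}(\Delta t)\,q_{k5}$.
Whether the original cohort analysis used exact-time or panel likelihood
is not documented; exact-time is the default here because the event dates
are exact, and the panel mode is opt-in. The two conventions differ in one
more way: panel snapshots refresh the age covariate at every visit, while
exact-time records fix it at state entry. The published tables can also be
read as either one joint fit with a sex covariate or two sex-stratified
fits; both are supported (`fit_mle()` with `covariates = "sex"`, or
sex-specific `dubbo_parameters(sex = )` / `fit_mle_stratified()`), and the
two are mutually consistent: the women's typical-profile rates times the
published men-vs-women hazard ratios reproduce the men's rates to printed
precision.

Uncertainty for derived quantities (instantaneous-risk tables) uses the
delta method on the log intensity. Wald intervals throughout; the
hazard-ratio table flags 5%-level significance.

## The synthetic cohort

No individual-level data are distributable, so `simulate_cohort()`
generates cohorts with the *structure* of the motivating population-based
study (the Dubbo osteoporosis cohort): 2046 women and 1205 men aged 60+.
Defaults, fixed once and not tuned afterwards:

* **Baseline covariates** match the published per-sex moments: age
  70 ± 7/6 (women/men, truncated at 60), BMI 26.5 ± 5.1 / 26.8 ± 3.9,
  femoral neck BMD 0.81 ± 0.14 / 0.92 ± 0.15 g/cm² (truncated at 0) with
  T-scores derived through the young-adult reference (mean 1.00/1.04, SD
  0.12), and Bernoulli prevalences for falls (37.9%/26.3%), prior
  fracture (17.5%/11.5%) and six comorbidities. Comorbidities are sampled
  independently — only marginal prevalences are published.
* **True intensities**: the published typical-profile rates, as the
  women's baselines plus a male sex effect equal to the published
  per-transition hazard ratios. Optional BMD and age effects default to
  HR 1.16 per SD lower BMD on all transitions and, since the published
  age hazard ratio of 1.67 never states its unit, an age effect *per 5
  years* at state entry (1.67 on death transitions, 1.25 on fracture
  transitions) — a declared choice, configurable through the coding.
* **Trajectories**: competing exponential clocks per allowed exit,
  evaluated at the profile on state entry; the minimum wins.
* **Censoring**: exponential dropout with rate $\log 2 / 9$ (median
  potential follow-up 9 years, matching the published median),
  administrative censoring 21 years after study start, and entry staggered
  uniformly over a 5-year recruitment window. The real cohort's visit
  schedule and loss-to-follow-up process are not described, so this is a
  declared emulation: it reproduces the 9-year median and the 21-year
  maximum, but its lower quartile (~4 y) is shorter than the published
  interquartile range (5–18 y).

What passing tests on these cohorts show — and do not show: they verify
that the estimator recovers known truth under correct model specification
with independent censoring. They cannot detect problems the generator
does not produce: informative dropout, BMD change over time, time-varying
comorbidities, semi-Markov (duration-dependent) hazards, or cause-specific
mortality.

## Numerical choices

* Intensities are stored as per-year rates; the published
  "instantaneous risk" percentages are rates × 100, converted only at the
  display layer.
* Generator rows must sum to zero within `1e-10`; probability rows within
  `1e-8`; expm round-off negatives below `1e-12` in magnitude are clamped
  to zero.
* `incidence_rate()` uses the exact (Garwood) Poisson interval via
  `stats::poisson.test()`; its conservative coverage is verified by exact
  enumeration in the tests, not only by simulation.
* Calibration (`calibration_table()`) compares a Kaplan–Meier estimate of
  leaving a state within the horizon (unbiased under independent
  censoring, unlike a raw event fraction) with the mean predicted exit
  probability $1 - \exp(-h\sum_s q_{rs}(z))$, stratified by sex, age band
  (default decades from 60), and state.
* The pipeline-closure check asks every fitted typical-profile intensity
  to lie within its Wald interval of the simulating truth *jointly* over
  the 14 sex-by-transition cells, so the allowance uses the
  Šidák-adjusted simultaneous 95% level rather than 14 unadjusted 95%
  intervals (which would fail about half the time by construction).

Problem sizes in the test-suite simulation studies were chosen to be
informative at interactive runtimes: cohorts of 2 000–40 000 subjects for
single-replicate recovery checks, and 200 replicates at the published
cohort size (3 251) for the confidence-interval coverage study.

## Known limitations

Markov, not semi-Markov: hazards do not depend on time already spent in a
state. Age enters only at state entry. Missing-data machinery (the
original analysis imputed ~1.5% missing BMD) is out of scope: inputs are
assumed complete. Lifetime risk is deliberately not computed — the model's
outputs are instantaneous and finite-horizon risks. Cause of death is not
modelled. The published women's fracture incidence (24/1000 PY) is not
derivable from the published counts (632 events / 21 723 PY ≈ 29); the
package reproduces only the arithmetic that is internally consistent.
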