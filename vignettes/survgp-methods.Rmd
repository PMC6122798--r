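---
title: "Discrete-time survival modelling by genetic programming: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-time survival modelling by genetic programming: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(survgp)
```

## The problem

Clinical prediction models for time-to-event outcomes are usually built by
Cox regression, which presumes proportional hazards and a linear predictor.
`survgp` implements an alternative: the model's functional form is *searched
for* by tree-based genetic programming (GP), with survival handled through a
discrete-time hazard formulation. The output is an explicit mathematical
formula — a "white box" — whose fit to censored data is measured by a proper
likelihood.

## The discrete-time hazard model

Follow-up is cut into intervals of width $\Delta$ (default 1 year). The
discrete-time hazard of subject $i$ in interval $j$ is the conditional
probability

$$h(t_{ij}) = P(T_i = j \mid T_i \ge j, X_i),$$

linked to an unbounded log-odds $\varepsilon(X_i, j)$ by the logistic
function $h = 1/(1+e^{-\varepsilon})$. The survival function is the product
of complements, $S(t_j) = \prod_{k \le j}(1 - h_k)$. (Some presentations of
this construction misprint the survival function as a product of the hazards
themselves; that form would start below 1 and contradict $S$ being a
survival probability, so the standard complement-product identity is used
here.)

Censoring is handled by the person-period ("counting process") expansion
(`to_person_period()`): each subject contributes $J_i = \max(1,
\lceil T_i/\Delta \rceil)$ rows, the event indicator sits on the last row
only, and a censored subject's final partial interval is kept as an at-risk,
non-event row. Intervals are half-open $((j-1)\Delta,\, j\Delta]$, so a
follow-up time landing exactly on a boundary belongs to the lower interval —
this is what makes a subject censored at exactly 2 years contribute exactly
two rows. With that expansion the censored-data likelihood is the Bernoulli
likelihood of the event flags, and the GP **fitness** (lower = fitter) is

$$-\sum_i \sum_{j=1}^{J_i} \big[E_{ij}\log h(t_{ij}) +
  (1-E_{ij})\log(1-h(t_{ij}))\big].$$

Hazards are clipped to $[10^{-12}, 1-10^{-12}]$ so the fitness of a
degenerate model is finite rather than infinite; at that bound the clipping
changes a log-likelihood term by at most $\sim 28$ nats, which cannot
reorder two non-degenerate models.

The same likelihood with a *linear* predictor
$\varepsilon = \sum_j \alpha_j D_{ij} + \sum_p \beta_p x_{pi}$ (dummy
indicators $D_j$ for each interval) is an ordinary logistic regression on
the person-period table; `fit_linear_discrete()` fits it by iteratively
reweighted least squares (`stats::glm`), which is the Newton-type algorithm
standard for this model. Intervals without events have no interior MLE for
their $\alpha_j$; these are capped at the clipping bound with a warning
rather than being allowed to drift to $-\infty$.

## The evolutionary search

`steady_state_evolve()` implements untyped, single-objective, steady-state
tree GP:

* **Representation.** A model is an expression tree over
  $+,\ -,\ \times,\ \div,\ \sin,\ \cos,\ \tan,\ \sqrt{},\ \exp,\ \log$,
  with leaves drawn from the covariates, the interval-index terminal `tj`,
  and ephemeral constants $\sim U(-3,3)$ fixed at creation. Depth is capped
  at 63 (a leaf has depth 1).
* **Protected operators.** Division returns 1 when $|b| < 10^{-9}$; $\log$
  maps $x$ to $\log|x|$ with $\log 0 = 0$; $\sqrt{}$ uses $|x|$; $\exp$
  clamps its argument to $[-50, 50]$; $\tan$ clamps its output to
  $[\pm 10^6]$; the outputs of $\times$ and $\div$ are clamped to
  $[\pm 10^{150}]$. The last clamp is what makes the finiteness guarantee
  airtight: inside a depth-63 tree the largest value a chain of unclamped
  additions can build from $10^{150}$-bounded factors is about
  $2^{62} \cdot 10^{150} < 10^{169}$, whose square is still a finite
  double, so no intermediate can reach `Inf` and hence no `NaN`
  (`Inf - Inf`, `0 * Inf`) can arise.
* **Initialisation.** Ramped half-and-half over depths 2–6.
* **Loop.** Sample $k = 7$ members without replacement; the two fittest are
  parents; subtree crossover is applied with probability 0.5 (a child that
  would exceed the depth cap is rejected and replaced by its parent); each
  child is then subtree-mutated with probability 0.5 (depth-capped with
  bounded retries); offspring replace the worst members of the sample only
  if strictly fitter, and an offspring that received no variation at all —
  an exact clone of its parent — is never re-inserted (this keeps a
  variation-free configuration a no-op and slows elite-clone takeover).
  The sample size, parent choice and replacement rule
  are implementation choices — the steady-state scheme itself only dictates
  the loop shape.
* **Termination.** A budget in offspring evaluations (used everywhere in
  the tests, for bit-reproducibility) or wall-clock seconds (production
  default 12 h).
* **Model selection.** The best-of-run model is the member of the final
  population with the lowest fitness on a *holdout* split (default 1/3 of
  the derivation data, stratified on events), not on training data.

Internally each individual is compiled to a flat postfix program evaluated
by a small C++ stack machine; subtrees are contiguous slices of a postfix
program, so crossover and mutation are vector splices. The compiled path and
the R-level recursive evaluator are required by the test suite to agree
exactly, and the public API (`parse_tree()`, `serialize_tree()`,
`evaluate_tree()`, `subtree_crossover()`, `subtree_mutation()`) works on
ordinary R language objects.

The time terminal `tj` is offered to the search like any covariate; it is
not forced into models. Whether a time effect appears in the final model is
an empirical outcome.

## Preprocessing

`run_fit()` winsorises continuous covariates at their 1st/99th empirical
centiles (linear-interpolation quantiles; centile definitions differ between
software, so the convention is stated here) and standardises them to mean 0,
sd 1, both using *training-part* statistics that are embedded in the fitted
model and re-applied automatically to any new data it predicts on.
Standardisation matters for GP because ephemeral constants live on
$[-3, 3]$: on standardised inputs a single constant can plausibly scale or
shift any covariate, which is also why the shipped example model
(`example_evolved_model()`) references its inputs in standardised form
(the `n` suffix).

## Evaluation under censoring

* **Discrimination** (`harrell_c()`): Harrell's concordance with follow-up
  truncated at the horizon $t$ (events after $t$ recoded as censored at
  $t$). A pair is usable only when it is orderable under censoring — the
  member with the strictly shorter observed time had an event; pairs with
  tied observed times are not usable; tied scores count 0.5. These tie
  rules follow the classical definition of the statistic.
* **Calibration** (`calibration_table()`, `hosmer_lemeshow()`): subjects
  ranked by predicted $S(t)$ are cut into $g = 10$ near-equal groups
  (remainder spread over the highest-risk groups). Predicted events per
  group are $n_g \cdot \overline{1-S(t)}$; observed events are
  $n_g \cdot (1-\mathrm{KM}_g(t))$ with the Kaplan-Meier estimate computed
  *within* the group, so censoring before the horizon is handled. The
  statistic $\sum_g (O_g-P_g)^2 / [P_g(1-P_g/n_g)]$ is referred to a
  $\chi^2_{g-1}$ distribution. The binomial-form denominator and
  $df = g-1$ are the conventions consistent with published
  $\chi^2 \to p$ pairs for decile grouping (e.g. $7.93 \to 0.541$,
  $5.18 \to 0.818$, $16.17 \to 0.063$ all match $df = 9$); a simple
  Pearson denominator is available by flag, and both $g$ and $df$ are
  arguments.
* **Curves** (`survival_curve_comparison()`): the cohort mean of model
  $S(t)$ against the Kaplan-Meier estimate with $\pm 2$ Greenwood standard
  errors.

`predict_risk()` composes per-interval hazards only through intervals seen
in training; a horizon beyond them raises an extrapolation error, because a
discrete-time model says nothing about intervals it never observed.

## The synthetic cohort generator

`generate_cohort()` draws covariates, then walks intervals: the event fires
in interval $j$ with probability $h^* = \mathrm{logistic}(\varepsilon^*(X,
j))$; otherwise random loss to follow-up and a per-subject administrative
cutoff compete. Terminal times are jittered uniformly *inside* the terminal
interval, so discretising the generated continuous times with the same
$\Delta$ recovers the simulated interval count exactly — discretisation
tests are deterministic, while the times still look like real follow-up.
Within an interval the earliest of jittered event time, jittered loss time
and cutoff decides the outcome.

`smart_like_spec()` emulates a secondary-prevention cardiovascular cohort:
~29 covariate columns named and shaped after the usual baseline table of
such cohorts (age quartiles 52/60/68, 25% female, smoking/alcohol
categories, blood pressures, lipids, homocysteine, creatinine, intima media
thickness, albuminuria, four vascular-disease site indicators and their
sum score, where an abdominal aneurysm counts two points). Covariates are
drawn independently (the sum score is a deterministic function of its
sites); real joint structure is *not* reproduced. The true log-odds

$$\varepsilon^* = -5.1 + 0.0016\,(\mathrm{AGE}-50)^2
  + 0.55\,\mathrm{HISTCAR2} + 2.2\,(\mathrm{IMT}-0.9)
  + 0.8\,(\mathrm{IMT}-0.9)(\mathrm{HISTCAR2}-2)
  + 0.07\,(\mathrm{HOMOC}-13) + 0.03\,t_j$$

contains one nonlinearity (quadratic age) and one interaction, the two
structures a linear baseline cannot represent without manual coding.
Administrative censoring is staggered as in an enrolment-window study
(cutoff $= 9\,U^{1.2}$ years). The intercept, effect sizes and stagger
exponent were calibrated once, jointly, to the cohort shape this generator
emulates: event fraction $\approx 12\%$, median follow-up $\approx 3.3$
years (maximum 9), and a true-model discrimination of $C \approx 0.74$ at
$t = 3$ — chosen so that *fitted* models can realistically reach the
$C \approx 0.66$–$0.70$ range reported for models developed on cohorts of
this kind, leaving the published "satisfactory performance" floor of 0.6
attainable but not trivial. These are the generator's fixed study
conditions, not tuning knobs.

What passing tests on this generator shows: correct likelihood mechanics,
discretisation, search behaviour and censoring-aware evaluation. What it
cannot show: performance under correlated covariates, missingness,
informative censoring or misspecified marginals — none of which the
generator emulates.

## Numerical and design choices

* Quantiles: type-7 (linear interpolation) throughout.
* Standardisation uses the sample (n−1) standard deviation.
* Stratified splits round the per-stratum allocation, so each part's event
  count is within one subject of exact proportionality.
* Calibration groups break ties in predicted risk by subject order
  (`ties.method = "first"` semantics); group 1 is the highest-risk end and
  absorbs the remainder first.
* Zero-event cohorts: `stratified_split()` falls back to a plain random
  split with a warning; `fit_linear_discrete()` refuses (no interior MLE).
* A calibration group with nobody at risk at the horizon has an undefined
  observed value; it is flagged and the χ² is reported as `NA` rather than
  silently dropped.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; `run_fit()` derives per-run seeds as
  `seed + run`.
* Problem sizes in the shipped checks: the null-calibration study uses 500
  replicates of n = 1000; engine-invariant sweeps run a population of 200
  for 50,000 evaluations on an n = 300 cohort; the end-to-end
  discrimination demonstration uses n = 2000 with a population of 300 and
  30,000–50,000 evaluations. These sizes were chosen as the smallest at
  which the corresponding statistical statements are stable.

## Known limitations

* Single-objective fitness: no complexity penalty, so trees bloat as a run
  proceeds; the depth cap is the only structural brake. Parsimony pressure
  would be the natural extension.
* Steady-state selection can converge prematurely on weak signals — the
  population floods with near-optimal constants before informative subtrees
  are found. Larger populations and longer budgets mitigate this; the
  holdout-based best-of-run selection at least prevents such runs from
  overfitting.
* Baseline covariates only: the person-period format could carry
  time-varying covariates, but neither the generator nor `predict_risk()`
  supports them.
* No competing risks, left truncation, or imputation of missing values —
  the loader rejects missingness outright.
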