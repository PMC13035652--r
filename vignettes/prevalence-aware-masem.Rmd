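---
title: "Prevalence-aware conversion of standardized mean differences for MASEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prevalence-aware conversion of standardized mean differences for MASEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbmasem)
```

## The problem

Meta-analytic structural equation modeling (MASEM) pools study-level
correlation matrices and fits a structural model to the pooled matrix.  When
one variable in the model is dichotomous — disease status, smoking, exposure
— primary studies typically report a standardized mean difference (Cohen's
*d*) rather than a correlation, and the meta-analyst must convert *d* to a
point-biserial correlation $r_{pb}$ before pooling.

The catch is that $r_{pb}$, unlike *d*, depends on the group distribution.
At the population level,

$$\rho_{pb} = \frac{\delta}{\sqrt{\delta^2 + \dfrac{1}{\pi(1-\pi)}}},$$

where $\pi$ is the prevalence of the category coded 1.  $|\rho_{pb}|$ is
maximal at $\pi = .50$ and shrinks towards zero as $\pi$ approaches 0 or 1
(base-rate sensitivity).  A conversion that implicitly assumes a 50/50 split
therefore estimates a different quantity than one that plugs in the true
prevalence, and which one is appropriate depends on the sampling plan of the
primary studies and on what the meta-analyst wants to generalize to.

`pbmasem` implements the full machinery needed to study and use these
conversions in a three-variable mediation model (dichotomous X, continuous
mediator M, continuous outcome Y): the conversions themselves, the
closed-form population values of the induced two-group mixture, a prevalence
adjustment for the correlation between the continuous variables, a one-stage
random-effects maximum-likelihood pooling engine, and a Monte Carlo harness.

## The six conversions

`d_to_rpb()` supports six conversions, differing in (a) whether the group
split is taken from the sample (`p`-based), from a stated prevalence
(`pi`-based), or assumed equal (`equal-groups`), and (b) whether the exact
*t*-based form or its large-sample limit is used:

| label             | radicand added to $d^2$                          |
|-------------------|--------------------------------------------------|
| `p-general`       | $(N^2 - 2N)/(n_1 n_0)$                           |
| `pi-general`      | $1/(\pi(1-\pi)) - 2/(\pi(1-\pi)N)$               |
| `equal-groups`    | $4 - 8/N$                                        |
| `p-large`         | $N^2/(n_1 n_0)$                                  |
| `pi-large`        | $1/(\pi(1-\pi))$                                 |
| `ls-equal-groups` | $4$                                              |

Useful identities, all asserted in the test suite: with $n_1 = n_0$ the
`p-general` and `equal-groups` forms coincide; `pi-general` at $\pi = .50$
equals `equal-groups`; and each general form converges to its large-sample
partner as $N \to \infty$.  Prevalences are accepted only as proportions in
(0, 1); percentage inputs are rejected rather than rescaled, because silently
accepting both units invites hundred-fold errors.

## Population values of the mediation mixture

The data-generating model places the two groups at means
$\pm\delta_M/2, \pm\delta_Y/2$ with unit within-group SDs and a common
within-group correlation $\rho$.  `population_spec()` describes this mixture
(the general implementation allows non-unit SDs; the unit-SD case is the one
used everywhere in the simulation harness), and `population_values()` returns
its closed-form moments, the total M–Y correlation

$$\rho_{YM} = \frac{\pi\big(\rho\sigma_M\sigma_Y + (\mu_{M,1}-\mu_{M,T})(\mu_{Y,1}-\mu_{Y,T})\big) +
 (1-\pi)\big(\rho\sigma_M\sigma_Y + (\mu_{M,0}-\mu_{M,T})(\mu_{Y,0}-\mu_{Y,T})\big)}
 {\sigma_{M,T}\,\sigma_{Y,T}},$$

the population point-biserials, the saturated-model path coefficients
(`beta_mx`, `beta_yx`, `beta_ym` — exactly the OLS coefficients of M on X and
of Y on X and M), and the indirect effect $\beta_{MX}\beta_{YM}$.

```{r}
population_table(c(0.02, 0.10, 0.50))
```

Note how strongly every quantity except the within-group structure depends on
the prevalence: at $\pi = .02$ the X–M point-biserial is .111, at $\pi = .50$
it is .371.

## Adjusting the continuous–continuous correlation

The d-to-$r_{pb}$ conversion corrects the correlations involving X, but the
total correlation between M and Y *also* depends on the group mixture.  When
a study's sample proportion $p$ differs from the prevalence one wants to
generalize to (the typical situation under 1:1 stratified sampling),
`adjust_r_ym()` first inverts the mixture formula to the within-group
correlation

$$r_W = r_{YM}\sqrt{1 + d_M^2\,p(1-p)}\sqrt{1 + d_Y^2\,p(1-p)} - d_M d_Y\,p(1-p)$$

and then re-applies the forward mixture at the target prevalence.  The two
maps are exact inverses, so adjusting to the observation proportion is the
identity, and the composition is consistent with `total_correlation()` to
machine precision (both are property-tested).  The equal-within-group-
correlation assumption is baked in and not relaxed.  An inadmissible
intermediate $|r_W| \ge 1$ — possible when the reported summaries are
mutually inconsistent — is flagged and warned about, never clipped.

```{r}
adjust_r_ym(0.450, 0.80, 0.50, p = 0.50, prevalence = 0.02)
```

## The simulator

`simulate_meta_dataset()` generates one meta-analytic dataset of `k = 30`
primary studies.  Study-level parameters are drawn from
$N([0.80, 0.50, .40], \mathrm{diag}(0.10, 0.10, 0.02))$ — medium-to-large
effects with empirically typical heterogeneity.  Sampling plans:

* **simple** random sampling: total N uniform on the ±20% dropout band
  around the target (800–1200 for target 1000), binomial group split at the
  study's prevalence;
* **stratified** 1:1: each group size uniform on the dropout band around
  half the target;
* **unbalanced** stratified: sample proportion drawn from U(.20, .60);
* **mixed**: thirds of the studies use simple/1000, stratified/26,
  stratified/128.

Twelve of the 30 studies lose one variable (chosen uniformly among X, M, Y),
masking 24 of the 90 correlations (27%).  Conditions 19–21 additionally draw
a per-study subpopulation prevalence from a ±30% uniform band around the
population value.  All 21 shipped conditions are plain-text fixtures
(`load_condition()`), and every stochastic step is reproducible from a seed
via `derive_seed(master, condition, replication)`, so results are independent
of execution order.

Design choices worth stating explicitly: the "maximum dropout of 20%"
narrative is operationalized as the symmetric band $[0.8N_t, 1.2N_t]$ because
that is what the stated 800–1200 bounds for target 1000 imply; group splits
leaving fewer than 2 observations in a group are redrawn (vanishingly rare at
the shipped configurations); within-group correlations outside (−0.99, 0.99)
are redrawn rather than truncated.

What the generator does *not* emulate: confounding or selection into groups,
unequal group variances, non-normal continuous variables, and informative
missingness.  Passing tests therefore demonstrate correct behaviour under
the idealized sampling model, not robustness to those violations.

## The pooling engine

`fit_masem()` fits a one-stage random-effects model to the study-level
correlation vectors $r_i$ (point-biserials from the chosen conversion plus
the untouched $r_{YM}$):

$$r_i \sim N\!\big(S_i\,\rho,\; S_i(V_i + T)S_i^\top\big),
\qquad T = \mathrm{diag}(\tau^2_1, \tau^2_2, \tau^2_3),$$

with $S_i$ the selection matrix of study $i$'s observed positions and $V_i$
its sampling covariance (Olkin–Siotani large-sample form).  The mediation
model is saturated, so the model-implied correlations equal the pooled
$\rho$, and the path coefficients follow in closed form.

Numerical choices:

* $\rho$ is optimized on the $\tanh^{-1}$ scale and $\tau^2$ as a square, so
  the optimization is unconstrained while the estimates respect their
  domains; BFGS with up to five jittered restarts on failure, and the best
  likelihood across successful attempts is kept.
* $V_i$ is evaluated at the sample-size-weighted across-study mean
  correlations (`v_eval = "pooled"`, the default).  Evaluating at each
  study's own observed correlations (`v_eval = "study"`) is available but
  biases the pooled estimates upward when studies are small: an observed
  correlation that lands near ±1 by chance receives a near-zero variance and
  hence an enormous weight.  With target N = 26 the difference is material
  (mean pooled $r_{pb,MX}$ ≈ .41 under study-level evaluation versus ≈ .36
  under pooled evaluation, the latter agreeing with reference results).
* sampling covariances are held fixed during optimization (two-step
  weighting) rather than updated with $\rho$ — standard practice that keeps
  the likelihood well behaved.
* starting values: size-weighted position means for $\rho$, half the
  empirical between-study variance for $\tau^2$.
* positions never observed are dropped from the model and reported `NA`;
  with $\tau^2$ free, each modeled position must be observed in at least two
  studies (with $\tau^2$ fixed, one suffices).
* a fit is flagged non-converged when the optimizer fails on all attempts or
  the pooled correlation matrix is not positive definite.

The engine is verified against three independent oracles: closed-form GLS
pooling when $\tau^2$ is fixed at zero, a dense two-dimensional grid search
on single-position problems, and `metafor::rma.mv` (ML, diagonal
heterogeneity) on complete records.  Delta-method standard errors are
available behind `se = TRUE` but are not part of the evaluation pipeline,
which follows the means/relative-bias design.

## Monte Carlo evaluation

`run_condition()` simulates datasets and fits every requested conversion to
the *same* datasets, then `summarize_condition()` reports means across
converged replications and relative bias
$\mathrm{RB} = 100(\bar\theta - \theta)/\theta$ against two references: the
population values at the condition's prevalence, and the maximum-absolute
values at $\pi = .50$.  The conventional acceptability bounds are 5% for
correlations and paths and 10.25% for the indirect effect (a product of two
paths).

The default problem sizes in the tests and the acceptance script are 200
replications per condition; the Monte Carlo standard error of a mean pooled
correlation at that size is below 0.005 in the shipped conditions, so the
0.01–0.015 comparison bands used there are ≥2-SE bands.  Runs with 2000
replications reproduce the published-scale experiment and are a
`reps = 2000` argument away.

A reliable qualitative finding reproduced by the harness: at $\pi = .02$
under simple random sampling, the equal-groups conversion overestimates the
population X–M point-biserial by more than 200% (it estimates the
$\pi = .50$ maximum instead), while the prevalence-based general conversion
is essentially unbiased.

## Known limitations

* The adjustment formula is specific to the three-variable mediation model;
  nothing here certifies it for larger models.
* Studies that lost variable X carry no Cohen's *d* values, so their
  $r_{YM}$ cannot be adjusted and enters the pooled fit unadjusted.
* The engine's likelihood treats per-study sampling covariances as known;
  with very small studies (N near 26) this is an approximation inherited
  from standard MASEM practice, visible as a few-percent attenuation of the
  pooled correlations in those conditions.
* Convergence failures are retried and reported, but no formal inference is
  offered for the retry process itself.
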