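---
title: "Decomposing EMA response times with a diffusion IRT model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing EMA response times with a diffusion IRT model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emadiff)
```

## The measurement problem

Momentary surveys deliver a handful of affect items several times a day.
The time a respondent spends on each item screen mixes at least three
processes: how accessible the relevant feeling is (fast access, fast
answer), how cautiously the person responds (more caution, slower answer),
and everything that is neither (reading, motor time). Raw response times
therefore confound emotional clarity with careless responding. `emadiff`
separates these with a sequential-sampling measurement model and then
carries the resulting scores through the reliability, validity and
practice-effect analyses such a study requires.

## Model

Each response is modelled as a two-boundary Wiener diffusion with unbiased
starting point and diffusion coefficient 1. The upper boundary is the
affirmative answer. For person-occasion row $p$ and item $h$,

$$\mu_{ph} = \theta_p - v_h, \qquad \alpha_{ph} = \gamma_p / a_h,$$

where $\theta_p$ is the person's momentary drift, $v_h$ the item's
difficulty (drift offset), $\gamma_p$ the person's boundary separation
(response caution) and $a_h$ the item's time pressure. The joint density of
a response and its decision time is the first-passage density of the
process; its choice margin is logistic in $\alpha\mu$. The model embodies
the distance-difficulty principle: expected decision time
$(\alpha/2\mu)\tanh(\mu\alpha/2)$ peaks at $\theta = v_h$ and falls as the
person's state moves away from the item's difficulty in either direction —
people answer fastest when their answer is obvious.

### Numerical evaluation

The density has two classical series representations. The large-time sine
series converges geometrically except near $t = T_{er}$; the small-time
Gaussian-mirror series does the opposite. `ddm_density()` picks whichever
needs fewer terms for a $10^{-12}$ truncation tolerance (hard cap 500
terms), always in log space with the leading exponential factored out so
nothing underflows. The defective CDF integrates the large-time series term
by term against the closed-form choice probability; `sample_response()`
inverts it by bisection (a fine-step Euler random walk is kept internally as
a cross-validation oracle only). Normalization, the logistic choice margin,
the mean-decision-time closed form and sampler/density agreement are all
asserted in the test suite at $10^{-6}$-level tolerances.

## Preprocessing rules

`preprocess_ema()` applies, in order: restriction to the declared item set;
dichotomization of 0-100 ratings at the scale midpoint (0-49 → 0, 50-100 →
1; already-binary items pass through); removal of item records with RTs
strictly above 30 s (a boundary value of exactly 30 s is retained); removal
of occasions with fewer than 2 retained items or with no RT variation (the
model is not estimable from constant RTs). Items are filtered before
occasions; all counts are reported and the pipeline manifest checks
`retained = scheduled - missed - filtered`. Logarithms are natural
throughout. Integer-second RTs are treated as continuous values without
jitter; a dedicated test shows that rounding moves the boundary scores by
less than 0.05 on average at the default configuration.

## Estimation

* **Marginal ML.** Person-occasion rows are exchangeable units;
  $\theta \sim N(0, \omega_\theta^2)$ and
  $\log\gamma \sim N(0, \omega_\gamma^2)$, independent, integrated by a
  tensor Gauss-Hermite grid (15 nodes per dimension by default; the
  examples in the tests use 7 where speed matters). Population means are
  fixed at 0 for identification, so any nonzero generating means are
  absorbed into $v_h$ and $a_h$; recovery is therefore assessed by
  correlation, not level.
* **Nondecision time.** With at most five RTs per row a free $T_{er}$ is
  weakly identified, so it is profiled per row as $\kappa \cdot \min_h t$.
  The default is $\kappa = 0.6$: the row minimum already contains the
  fastest item's decision time, so values much above 0.7 eat into genuine
  decision time and visibly bias the item boundary parameters, while the
  marginal likelihood is nearly flat over 0.5-0.7. $\kappa$ is a visible
  argument and sensitivity to it should be part of any serious application.
* **Scores.** Per-row EAP of $\theta$ and $\log\gamma$ on the same grid.
  The reported drift variable is $\mathrm{mean}_h|\theta - v_h|$ (the EAP
  of $\theta$ plugged into the fold, not the EAP of the fold), then
  log-transformed. Boundary scores more than 5 interquartile ranges below
  the median log boundary are set missing; the rule is configurable.
* **Diagnostics.** `qq_diagnostic()` simulates one RT per observed record
  from the row's posterior-mean parameters and pairs observed with
  simulated percentiles 1-99; `check_unidimensionality()` reports the
  first-factor summary of the tetrachoric correlation matrix (pairwise
  two-step ML using the bivariate normal CDF) as an advisory check.

## Multilevel analyses

All two-level analyses run on one engine: maximum likelihood for the
two-level multivariate normal model with unbalanced cluster sizes,
parameterized by log-Cholesky factors of the within- and between-person
covariance matrices, with the mean profiled out by GLS. Because the
likelihood reduces to a pooled within-cluster scatter plus one term per
distinct cluster size, an objective evaluation is a handful of small-matrix
operations whatever the sample size. Person-level covariates enter as
between-only variables with structurally zero within-person variance.

* **ICC / null model** (`fit_null_model()`): ML (default) or REML; on
  balanced data REML equals the one-way ANOVA closed forms, which the tests
  assert at $10^{-6}$, and the ML branch is cross-checked against an
  independent mixed-model implementation. Standard errors come from the
  observed information with the delta method.
* **Latent covariate regression** (`fit_latent_regression()`): within- and
  between-person paths read off the level covariance matrices. With few
  occasions per person the manifest person-mean regression is provably
  attenuated; the test suite constructs that bias and shows the latent
  between coefficient carries less than a third of it.
* **Correlations and dependent-correlation tests**: level-specific
  correlation matrices with Fisher $z$ transforms; differences between
  correlations sharing a variable are tested with a person-resampling
  bootstrap (1,999 replicates by default). Point estimates come from the
  ML fit; bootstrap replicates use the closed-form MANOVA moment estimator,
  which is consistent and three orders of magnitude cheaper — the bootstrap
  only has to supply a standard error.
* **Mediation** (`fit_mediation()`): drift and boundary enter as
  simultaneous mediators; paths are computed on the predictor's level, so
  the decomposition `total = c' + sum(a*b)` holds exactly at the estimates
  (asserted at $10^{-10}$). Intervals for the indirect effects come from
  Monte-Carlo sampling of the asymptotic distribution of the covariance
  parameters (default $10^5$ draws), which, like the bootstrap, respects
  the skewness of a product of coefficients; a fully Bayesian treatment
  would be asymptotically equivalent here. Binary predictors are
  standardized with respect to the dependent variable only.

## Practice-effect growth models

`fit_negative_exponential()` fits
$y_{ij} = a_j - g_j e^{-r\,occ_{ij}} + e_{ij}$ with bivariate normal
$(a_j, g_j)$ and a common rate. The reported `gain` is the signed change
from the initial level to the asymptote, so a variable that starts high and
practices downward has a negative gain. For fixed $r$ the model is linear
in the random effects, so the rate is profiled over linear mixed-model
fits — exact ML without nonlinear-optimizer fragility. A person-varying
(log-normal) rate is available via `random_rate = TRUE` but is fragile with
weekly EMA designs and off by default. Occasions are coded 0, 1, 2, … in
scheduled prompt order; missed prompts leave gaps (completed-order coding
is a caller-side recode). `compare_gains()` refits both z-scored variables
jointly (per-variable residual variances, correlated person effects, rates
fixed at their single-variable profile estimates — profiling them inside
the joint fit would multiply its cost for little gain) and Wald-tests the
equality of absolute gains.

## What the generator emulates — and what it does not

`synthetic_config()` encodes a one-week, 6-prompts-per-day burst design in
954 persons with 75% completion, 5 dichotomized affect items plus 3 binary
event items, integer-second RTs, variance components giving score ICCs in
the 0.3-0.4 range, opposite-direction work/recovery shifts on drift and
boundary, neuroticism/depression loadings on the person means, and
negative-exponential practice trends of about ±0.8 SD. Defaults worth
explaining:

* **RT scale.** The mean log boundary (1.5) is calibrated so the generated
  records reproduce a mean log RT near 1.4 log-seconds and roughly 1% of
  RTs beyond the 30-s cap — the regime the preprocessing rules were
  designed for.
* **Sign convention for drift effects.** Effect sizes on the drift side
  are stated on the drift-rate axis ($|\theta - v|$), the scale on which
  such effects are reported. Endorsement of negative affect is a minority
  phenomenon, so person drifts sit below the item difficulties and a
  drift-rate decrease maps to an *increase* in signed $\theta$; the
  generator applies the flip internally.
* **Item banks.** Difficulties span about 2 logits; time pressures span
  0.8-1.3 and are deliberately not ordered with difficulty, because the two
  item parameters are only separately identifiable when they are not
  collinear across the bank.
* **Score attenuation.** EAP scores from five items are shrunken and
  noisy: score-level ICCs and within-person regression paths are visibly
  attenuated relative to the generating components (a scored-θ ICC of
  ~0.19 against a latent 0.31 is typical). Passing recovery tests
  therefore says the pipeline recovers what five-item scores *can* carry,
  not that five items measure the latent state without loss. Relatedly,
  the default practice trend parks early-study drifts near the item
  difficulties (that is why RTs start slow), and in that region the
  absolute-drift fold makes small activity shifts sign-ambiguous — the
  mediation sign-recovery test isolates the work mechanism by switching
  the trends off.
* **Not emulated:** time-of-day effects, autocorrelated affect dynamics,
  non-random missingness, reminder-alarm behavior, item-order effects.

## Problem sizes used by the test suite

The tests are sized to run in minutes on one core: density/sampler checks
on analytic grids and 10-50k draws; item recovery on ~2,000 person-occasion
rows (full 15-node quadrature); scoring and diagnostic checks on ~800-row
fits with 7-node quadrature; multilevel recoveries at 300-500 persons with
5-20 occasions; mediation null-coverage over 100 replicates of 60 persons;
growth recoveries at 250-500 persons with 20-30 occasions. The
study-shape preset (40,068 scheduled occasions) is exercised for generation
and preprocessing accounting only.

## Known limitations

* $T_{er}$ profiling is a declared approximation, not an estimate; real
  data with heavy-tailed reading times will leak nondecision time into the
  boundary scores.
* The measurement model assumes a single latent dimension per item set and
  no inter-trial variability parameters.
* Mediation intervals are asymptotic; with very few persons the Monte-Carlo
  intervals inherit the normal approximation of the covariance parameters.
* The dependent-correlation bootstrap resamples persons, so it reflects
  between-person sampling variability; with very short series the
  within-level correlations themselves are noisy.
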