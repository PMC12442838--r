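# emadiff

Response times (RTs) to ecological momentary assessment (EMA) surveys are
easy to log and hard to interpret: a fast answer can mean that an emotion was
highly accessible, or that the respondent barely processed the question.
`emadiff` disentangles these by fitting a **D-diffusion item response theory
(IRT) model** to the binary responses and item-level RTs of brief momentary
affect scales, decomposing each person-occasion into

* a **drift rate** — how fast affective information is accessed and
  accumulated, and
* a **boundary separation** — how much evidence the respondent requires
  before answering (response caution),

and then runs the multilevel analyses a response-process study needs on top
of those scores: test-retest stability (intraclass correlations), latent
covariate regression of observed RTs on the two components, correspondence
of parameters across item sets, 1-1-1 / 2-1-1 multilevel mediation, and
negative exponential practice-effect models. A synthetic-data generator with
exposed ground truth makes every stage testable end to end.

## The model

For person-occasion `p` and item `h`, a response `x` (1 = affirmative) and
its time `t` follow the two-boundary Wiener first-passage density with
unbiased start and unit diffusion,

    h(x, t) = (pi / alpha^2) * exp(alpha * mu * (x - 1/2) - mu^2 (t - Ter) / 2)
              * sum_k k sin(k pi / 2) exp(-pi^2 k^2 (t - Ter) / (2 alpha^2))

with the IRT decomposition

    mu_ph    = theta_p - v_h          (person drift minus item difficulty)
    alpha_ph = gamma_p / a_h          (person caution over item time pressure)

so the marginal choice probability is logistic:
`P(x = 1) = exp(alpha * mu) / (1 + exp(alpha * mu))`. Item parameters
`(v_h, a_h)` and the population variances of `theta` and `log gamma` are
estimated by marginal maximum likelihood (Gauss-Hermite quadrature over both
latent dimensions, compiled density); per-occasion scores are expected
a-posteriori (EAP) values. The drift score reported downstream is the mean
absolute deviation `mean_h |theta - v_h|` — speed of access regardless of
response direction — and scores are log-transformed, mirroring standard
practice.

Occasion-level stability is summarized by `ICC = tau2 / (tau2 + sigma2)`
from a multilevel null model; between-person regressions use the latent
covariate decomposition (manifest person means are biased with few occasions
per person); practice effects follow
`y = asymptote - gain * exp(-rate * occasion)`.

## Worked example

```r
library(emadiff)

cfg <- synthetic_config(n_persons = 150, days = 4, prompts_per_day = 4)
sim <- generate_dataset(cfg, seed = 7)

pp  <- preprocess_ema(sim$records, cfg$items$affect$item_id)
pp
#> EMA preprocessed data: 1819 occasions retained of 1830
#>   items: angry, dejected, frustrated, lonely, stressed
#>   RT-capped records: 99 | occasions removed: 11 (invariant 11, <2 items 0)

fit <- fit_diffusion_irt(pp, n_quad = 7)
fit
#> D-diffusion IRT fit: 5 items, 1819 person-occasion rows
#>   log-likelihood -20779.44 | sd(theta) = 0.670, sd(log gamma) = 0.232
#>   item_id         v     a
#> 1 angry      -0.796 0.227
#> 2 dejected   -0.293 0.178
#> ...

sc <- score_occasions(pp, fit)
fit_null_model(sc, log_gamma, person_id)
#> Multilevel null model for 'log_gamma' (ML): delta = -0.001, tau2 = 0.008, sigma2 = 0.022
#>   ICC = 0.257 (SE 0.029), 150 persons, 1819 occasions

fit_latent_regression(sc, mean_log_rt, log_abs_drift, log_gamma, person_id)
#> Latent covariate regression of mean_log_rt on log_abs_drift + log_gamma
#>   within : beta_std = (-0.338, 0.904), R2 = 0.938
#>   between: beta_std = (-0.183, 0.957), R2 = 0.997

fit_mediation(sc, work, c("log_abs_drift", "log_gamma"), mean_log_rt,
              person_id, predictor_level = "occasion", seed = 7)
#> Multilevel mediation (binary predictor 'work', within level)
#>   total = -0.125, direct c' = 0.003
#>   indirect effects (standardized):
#>       mediator estimate ci_lower ci_upper raw_estimate
#>  log_abs_drift   0.0308 -0.00627   0.0681       0.0113
#>      log_gamma  -0.1586 -0.25693  -0.0594      -0.0582
```

Reading the output: the RT cap and no-variation filters account for every
removed record; the item difficulties `v` order the five affect items from
most to least readily endorsed; the boundary score's ICC of ~0.26 says about
a quarter of its variance is stable between-person differences; drift and
boundary predict observed log RTs in opposite directions at both levels; and
momentary work pushes RTs in two competing directions at once — slower
through reduced drift (positive indirect effect), faster through reduced
caution (negative indirect effect) — exactly the confounding that raw RTs
cannot show.

A tiny example table ships in
`inst/extdata/ema_synthetic_small.csv` (synthetic, generated by this
package) for `read_ema_long()`.

The whole chain — simulate, preprocess, fit both item sets, score, analyze,
write JSON reports and a manifest — is one call:

```r
run_pipeline(list(synthetic = "paper-shape", seed = 7, out_dir = "out"))
```

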