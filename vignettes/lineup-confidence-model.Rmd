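---
title: "Measuring eyewitness confidence at the process level: the lineup confidence model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring eyewitness confidence at the process level: the lineup confidence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mptlineup)
```

## The measurement problem

When an eyewitness picks a face out of a lineup (or rejects the lineup),
the observable response is an ambiguous mixture of latent processes: the
witness may genuinely have detected the culprit's presence or absence, may
have been drawn to a suspect whose photograph stands out (lineup
unfairness), or may simply have guessed. Confidence ratings inherit this
ambiguity: a "very confident" suspect identification means something quite
different when it follows detection than when it follows a lucky guess.
The lineup confidence model measures confidence *conditionally on the
generating process*, so that questions such as "does post-identification
feedback inflate confidence more after guessing than after detection?" can
be asked directly at the process level.

## The two-high-threshold core

The response model is the two-high-threshold (2HT) eyewitness
identification model, a multinomial processing tree (MPT) over the three
response categories of each lineup type. With `dP` the probability of
culprit-presence detection, `dA` culprit-absence detection, `b` biased
suspect selection, `g` guessing-based selection, and `k = 1/lineup size`:

culprit-present lineups:

* P(culprit identification) = `dP + (1-dP) b + (1-dP)(1-b) g k`
* P(filler identification) = `(1-dP)(1-b) g (1-k)`
* P(rejection) = `(1-dP)(1-b)(1-g)`

culprit-absent lineups:

* P(suspect identification) = `(1-dA) b + (1-dA)(1-b) g k`
* P(filler identification) = `(1-dA)(1-b) g (1-k)`
* P(rejection) = `dA + (1-dA)(1-b)(1-g)`

A guessing witness lands on the suspect only `1/k`-th of the time, which
is what separates guessing from biased selection; `b` absorbs lineup
unfairness so the remaining parameters are measured uncontaminated. For
six-person lineups the constant is stored as `.16667` (the convention of
the published analyses this package reproduces); `lineup_design(...,
exact_fraction = TRUE)` switches to exact `1/6`.

## The confidence extension

Every terminal branch is split into low/moderate/high confidence by a
binary cascade whose parameters depend only on the latent process:
detection (`c_d*`, shared between culprit-presence and culprit-absence
detection), biased selection (`c_b*`), guessing-based selection (`c_g*`)
and guessing-based rejection (`c_gr*`). Because a witness who fails to
detect cannot tell culprit-present from culprit-absent lineups, the
non-detection blocks are shared between the two trees of a condition.

The cascade is *high-first*: the first split parameter is the probability
of high confidence, the second the probability of moderate given
not-high, so

```
c_H = x1,   c_M = (1 - x1) * x2,   c_L = (1 - x1) * (1 - x2).
```

High-first ordering is a deliberate design choice: it makes the
probability of high confidence a single model parameter, so that the
substantive hypotheses ("high confidence is more likely after detection
than after guessing", "feedback raises high confidence") are single
equality constraints with the degrees of freedom those tests are expected
to have (2 within conditions, 1 across conditions). A low-first cascade
would represent high confidence as a product of two parameters and could
not express these tests as parameter equalities.
`binary_to_trichotomous()` and `trichotomous_to_binary()` convert between
the two scales, with first-order delta-method standard errors propagated
from the fit covariance.

## The two-condition base model

`lineup_base_model()` instantiates two copies of the confidence model,
one per post-response feedback condition (negative, positive), and
equates `b` and `dA` across conditions — both are properties of the
lineup materials, not of the witness's post-response state. That yields 4
trees x 9 categories, 32 independent proportions, 22 free parameters, and
a goodness-of-fit test on 10 degrees of freedom:

```{r}
model <- lineup_base_model()
n_free_parameters(model)
mpt_df(model)
```

The bundled data set (`lineup_feedback_counts()`) contains the observed
frequencies of a large validation experiment: 1565 participants, each
responding to two culprit-present and two culprit-absent six-person
lineups, receiving negative feedback on one lineup of each type and
positive feedback on the other, then rating confidence on a 0-100 scale
binned as low (0-30), moderate (31-70) and high (71-100)
(`categorize_confidence()`; edges inclusive as stated, configurable).

```{r}
counts <- lineup_feedback_counts()
fit <- mpt_fit(model, counts, n_starts = 10, seed = 1)
fit
```

## Estimation

`mpt_fit()` minimizes the likelihood-ratio statistic

```
G^2 = 2 * sum_i n_i * log(n_i / e_i),    e_i = N_tree * p_i(theta),
```

equivalent to multinomial maximum likelihood (zero cells contribute zero;
expected probabilities are floored at 1e-300 before taking logs). Each of
`n_starts` uniform-random starting vectors is run through three stages:

1. **EM.** Whenever the parameter map contains no shrinkage products, the
   classical MPT EM update (expected branch counts in the E-step, a ratio
   of counts in the M-step) is iterated to 1e-9. EM is monotone and keeps
   parameters interior, which removes the boundary traps plain
   quasi-Newton optimization can fall into from extreme random starts.
2. **Quasi-Newton.** BFGS on the log-odds scale with an analytic gradient
   (convergence tolerance 1e-14 on relative G^2).
3. **Newton polish with boundary snapping.** Newton steps (analytic
   gradient, finite-difference Hessian) drive the gradient below 1e-10, so
   independent starts agree to ~1e-10 in the estimates; a parameter whose
   likelihood keeps improving towards 0 or 1 is snapped to the exact
   boundary if that does not worsen G^2, and flagged. On the bundled data
   one parameter (the moderate-versus-low split following biased selection
   under positive feedback) is such a boundary estimate, so its standard
   error deserves the usual one-sided caution.

Standard errors come from the inverse observed information matrix of the
multinomial log-likelihood at the optimum (central differences of the
analytic score). Observed rather than expected information is the
default choice; at this sample size the two are practically
indistinguishable. A singular information matrix is reported as a
non-identifiability warning rather than an error.

`identifiability_check()` refits the model from many independent random
starts (the published analysis used 1000) and reports the maximum spread
of the estimates; an identified model at desk-scale data yields spreads
around 1e-10.

## Hypothesis tests

`mpt_nested_test()` compares nested models by `delta G^2` with degrees of
freedom equal to the difference in free-parameter counts; both models are
fitted by independent multi-start optimization (not profile likelihood),
and a tiny negative difference within optimizer tolerance is clamped to
zero. `lineup_test_catalog()` runs the full published battery: four
process contrasts on high confidence (df = 2: the equality is imposed
within each feedback condition simultaneously), four feedback effects on
high confidence (df = 1), and the two selectivity checks on `dP` and `g`
(df = 1).

## The shrinkage reparameterization

To compare feedback effects *across* processes, each high-confidence
parameter under negative feedback is removed and re-expressed as
`s * reference` with `s` in [0, 1] and the reference taken from the
positive-feedback condition (`mpt_shrinkage()`). Dimensionality is
unchanged (one parameter leaves the roster, one enters), so when the
implied order constraint `c_H,neg <= c_H,pos` is inactive at the maximum
the reparameterized model fits exactly as well as the base model, and the
`s` parameters quantify, per process, how much negative feedback deflates
high confidence. If the data violate the order constraint the shrinkage
parameter hits its boundary at 1, the fit is worse than the base model,
and `lineup_shrinkage_analysis()` flags `equal_fit = FALSE`.

One convention deserves explicit mention. For detection, biased selection
and guessing-based rejection the reference is the same process's
positive-feedback parameter. For guessing-based *selection* the default
reference is the positive-feedback guessing-based-*rejection* parameter.
This is the convention of the original validation study's deposited model
equations, and it is what this package's published-value checks
reproduce; it is harmless for model fit (the reference only rescales the
shrinkage parameter, leaving the induced probabilities free), and the two
guessing processes have statistically indistinguishable high-confidence
profiles under positive feedback, which makes either reference a
reasonable yardstick. `g_reference = "guess-selection"` switches to the
literal same-process reading, under which the guessing-selection
shrinkage estimate becomes the plain ratio of the two
guessing-selection parameters (about .31 rather than .24 on the bundled
data, with the detection contrast at about 49.9 rather than 73.8).

## Simulation and design analysis

`simulate_frequencies()` draws one multinomial per tree;
`parameter_recovery()` wraps the full simulate-fit-SE pipeline and
reports bias, RMSE and 95% Wald coverage. The generator emulates exactly
what the model assumes — independent multinomials at the model
probabilities, one response per participant per tree, no
participant-level heterogeneity, no carry-over between the four lineups
of a session. Passing recovery and calibration tests therefore validate
the engine and the design size, not those substantive assumptions; real
data can violate them (e.g. witness heterogeneity or trial-order
effects), and the package deliberately does not model random effects.

`minimal_detectable_w()` performs the analytic sensitivity analysis: the
smallest Cohen's `w` detectable by a chi-squared test with noncentrality
`lambda = N_eff * w^2`. Responses are treated as independent
observations, so the bundled design's effective N is 1565 x 4 = 6260,
giving a minimal detectable effect of about `w = .046` (alpha = beta =
.05, df = 1) for the critical feedback tests. Fixing alpha, power and df
pins `lambda` (12.995 for .05/.95/1), so `w` scales as `sqrt(lambda/N)`.

## Problem sizes used in the validation suite

The package's own test suite fits the 22-parameter base model at the
bundled design size throughout: the 1000-repeat identifiability check, a
200-replicate parameter-recovery study at the fitted estimates (interior
parameters unbiased within Monte-Carlo error, mean Wald coverage in the
90-98% band), and a 500-replicate type-I-error calibration of the
G^2 test at the .05 level (expected rejection rate .05 +/- .03).
Calibration replicates use 2 random starts per fit — with the EM stage a
single start is already reliable, and the doubled start only guards the
tail — while recovery replicates keep the 10-start fitting default.

## Limitations

* Aggregated frequencies only: no hierarchical/random-effects MPT or
  Bayesian estimation; participant heterogeneity biases are not captured.
* One designated suspect per lineup; no showups, no position effects.
* The EQN interface covers products of parameters, complements and
  constants; shrinkage products cannot be serialized to EQN.
* Boundary estimates carry Wald standard errors with the usual one-sided
  caveat; profile or bootstrap intervals are not implemented.
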