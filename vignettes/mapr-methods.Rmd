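---
title: "Measuring health with preference responses: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health with preference responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maprmod)
```

## The measurement problem

A patient is shown descriptions of hypothetical health states and asked,
for each one, a single question: *is this state better or worse than your
own health?* Collecting these binary preferences over a set of comparator
states positions the patient's own health status and the values of the
comparator states on one latent quality-of-health scale. Unlike valuation
methods that ask healthy respondents to imagine illness (standard gamble,
time trade-off), every judgment here is made by a patient against their own
lived health, which removes a large class of adaptation and reference-point
biases and turns valuation into a genuine patient-reported measurement.

maprmod implements this multi-attribute preference response (MAPR)
framework in two variants:

* the **holistic** variant, a Rasch model in which every comparator state
  `i` carries its own value `beta_i`;
* the **attribute-parameterized** variant, a linear logistic test model
  (LLTM) in which the comparator states are described by a classification
  system (J attributes with `n_j` ordered levels, e.g. EQ-5D-3L) and each
  state value is a sum of attribute-level weights.

## Model

Let `theta_p` be the latent health status of person `p` and `beta_i` the
latent value of comparator state `i`. The response `Y_ip = 1` (person
prefers own health over state `i`) occurs with probability

    pi_ip = exp(theta_p - beta_i) / (1 + exp(theta_p - beta_i)),

i.e. `logit(pi_ip) = theta_p - beta_i`. Three assumptions carry the model:
unidimensionality (one latent scale), monotonicity (`pi` increases in
`theta - beta`), and local independence (responses are independent given
`theta_p`). The deterministic limit of this model is the Guttman scale, and
`guttman_scalogram()` reports how far a data set is from that limit.

The attribute-parameterized variant writes, for a state with levels
`x = (x_1, ..., x_J)`,

    beta = f(x) = sum_j alpha_{j, x_j},      alpha_{j,1} = 0,

with dummy coding of the non-reference levels and no intercept
(`build_design_matrix()`). The reference constraint anchors the scale: the
perfect-health state has value exactly 0, and more negative values mean
worse states. Because `f` is defined on the whole classification system,
a fitted LLTM values *every* describable state (243 for EQ-5D-3L), not only
the states shown to respondents. Interactions between attributes can be
added as dummy products; identification requires fewer free weights than
fitted states.

## Estimation

**Item side (CML).** The raw score `R_p = sum_i Y_ip` is a sufficient
statistic for `theta_p`, so conditioning each person's likelihood on
`R_p` removes the person parameters entirely — no assumption about the
person distribution is needed, which matters because real patient
populations are skewed, not normal. The conditional likelihood involves the
elementary symmetric functions `gamma_r(eps)`, `eps_i = exp(-beta_i)`,
which `esf_gamma()` evaluates with the summation recursion in log space
(the difference algorithm is numerically unstable; the log-space recursion
is accurate for item sets far larger than any preference study uses — the
tests check exact agreement with subset enumeration up to `I = 12` and
stability for values spanning `e^±400`).

`fit_rasch_cml()` solves the estimating equations — observed item margins
equal their conditional expectations — by damped Newton–Raphson on the
sum-to-zero parameterization, starting at `beta = 0`, halving steps
whenever the conditional log-likelihood would decrease, and declaring
convergence when the largest score-equation residual falls below `1e-8`
(at most 100 iterations, both user-configurable). Standard errors come
from the inverse conditional information, whose off-diagonal terms use the
leave-two-out symmetric functions. `fit_mapr_cml()` maximizes the same
conditional likelihood with `beta = W alpha` chain-ruled through the
design matrix; with one free dummy per non-reference item it reproduces
the Rasch fit exactly (a reparameterization), which the tests assert to
`1e-6`.

Two facts about the data decide whether these estimates exist:

* persons with extreme raw scores (0 or `I`) carry no information and are
  excluded (they are flagged, never silently lost);
* the matrix must be *well conditioned*: every bipartition of the items
  must be crossed by some person's (1, 0) response pair.
  `check_well_conditioned()` tests the equivalent strong connectivity of
  the directed item graph and returns a violating bipartition as a
  witness; `make_well_conditioned()` iterates witness removal, which is
  the practical remedy when very severe states are unanimously judged
  worse than everyone's own health.

**Person side (ML).** With `beta` fixed at its CML estimate (a deliberate
two-step simplification: the item-side sampling error is not propagated),
`fit_persons_ml()` solves `R_p = sum_i pi_i(theta)` and reports
`se = 1 / sqrt(sum_i P_i (1 - P_i))`. Each item contributes at most 0.25
to that information sum, so `se >= sqrt(1 / (0.25 I))` always: precision is
capped by the number of comparators, and comparators close to the person's
own status are the most informative. That inequality is also the design
rationale for the adaptive variant: `select_adaptive_comparators()` picks
the `k` bank states nearest in value to the person's own (composed) value,
balanced above and below where possible, ties broken by bank order.
Extreme scorers get `±Inf` point values and an `extreme` flag; weighted
likelihood shrinkage is intentionally not applied.

## Anchoring — the one thing to never mix up

A conditional likelihood fixes only differences of values, so every fit
carries an explicit anchoring: sum-to-zero (Rasch default), a chosen
reference item (`anchor = "item"`), or the perfect-health reference of the
LLTM. Absolute values from differently anchored fits are not comparable —
only differences and orderings are — and the JSON exports record the
anchoring so that downstream comparisons re-anchor first (as
`lr_test_nested()` does implicitly by comparing likelihoods, not values).

## Diagnostics

`andersen_test()` refits the model within person score groups (default
split: at or below the median raw score versus above — the split rule is a
parameter, since no canonical choice exists) and compares group and pooled
conditional log-likelihoods: `2[sum_g l_g - l_pooled]` is asymptotically
chi-square with `(G-1)(I-1)` df under a fitting model. Items constant
inside any group are dropped from all groups first, with a message.
Simulation under the model at `I = 6`, `P = 300` puts the empirical
rejection rate at nominal 0.05 within (0.03, 0.08) — the calibration block
in the test suite recomputes this over 500 replicates.

`lr_test_nested()` compares the holistic and attribute-parameterized fits
on identical data (enforced by a data fingerprint):
`2(l_Rasch - l_LLTM)` with `df = (I - 1) - q`. For 17 comparator states
against the 10 main-effect EQ-5D-3L weights, `df = 6`. A significant
statistic says the attribute levels do not fully describe the states; the
correlation between the two fits' item values says how much that matters
practically.

`guttman_scalogram()` sorts persons by raw score and items by column total
(stable sort; ties keep input order) and counts cells deviating from the
ideal staircase for each row's raw score — a swapped response pair
produces two misfit cells. This definition makes the count zero exactly
when the sorted matrix is a perfect Guttman pattern.

## The simulator and what passing its tests does (not) show

`simulation_scenario()` defaults emulate a small valuation study: 163
respondents judging a fixed set of 17 EQ-5D-3L states whose true values
are composed from the package's example weights (`eq5d3l_weights()`),
with person health statuses drawn from a negated log-normal
(`theta = -rlnorm(meanlog = 1, sdlog = 1)`): the bulk of patients sits in
fair-to-good health near the top of the scale with a long tail of severe
statuses, bounded above by perfect health, and the spread covers the whole
severity continuum so even the worst comparator states receive occasional
better-than-own responses. Responses are independent Bernoulli draws from
the model probability; each person has a deterministic seed substream, so
enlarging the sample never reshuffles earlier persons.

The generator produces data *under the model*: complete matrices, local
independence, no response biases. Recovery and calibration results
therefore validate the estimators and tests, not the behavioural
assumptions — adaptation, fatigue, ordering effects, and tied or missing
responses in real studies are all outside what a green test suite can
demonstrate. Ranking-based designs are supported through
`rankings_to_binary()`, which converts best-to-worst rankings (dropping
auxiliary cards such as "dead") into the binary matrix; it refuses tied
rankings rather than guessing.

Validation problem sizes, chosen to make Monte-Carlo noise negligible
relative to the tolerances while keeping the suite quick: grid-search
oracle agreement at `P = 60`, parameter recovery at `P = 2000` (attribute
weights within 0.35 of truth, Spearman of implied state values above
0.95, item values within 0.15), Andersen calibration over 500 replicates,
nested-LR null distribution over 200 replicates.

## Numerical and edge-case choices

* ESFs in log space throughout; `log(exp(a) + exp(b))` guarded for `-Inf`.
* Probabilities are total functions on the extended reals;
  `theta = beta = ±Inf` returns 0.5 by the `theta`-limit convention.
* Ties in predicted preferences (`own == comparator`) predict "prefer own"
  (probability 0.5 in the model; a deterministic rule is needed for
  agreement tables); configurable via `tie =`.
* Kappa's degenerate case (chance agreement 1) is reported as undefined
  rather than 0/0.
* Within-attribute monotonicity of fitted weights is *checked and
  reported* (`monotone` field), never enforced — an unconstrained fit that
  violates ordering is a finding, not an error.
* Missing responses are rejected at construction: the conditional
  machinery assumes complete matrices, and non-ignorable missingness would
  bias the estimates in ways the package does not model.

## Limitations

Marginal maximum likelihood and Bayesian estimation are not provided; the
scale is relative (no anchoring at "dead", so values are not directly
usable as QALY weights without a separate rescaling exercise); polytomous
or multidimensional responses are out of scope; and the adaptive design is
simulated and analyzed per person but no full adaptive-administration data
pipeline (varying item sets in one CML fit) is included.
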