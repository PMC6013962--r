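# maprmod

Health-state valuation from patients' own preference judgments.

A patient is shown hypothetical multi-attribute health states (e.g.
EQ-5D-3L descriptions such as `33221`) and answers one question per state:
*is this better or worse than your own health?* maprmod estimates, from
these binary responses, the values of the comparator states and each
patient's own health status on a single latent scale — the
multi-attribute preference response (MAPR) measurement framework.

## The models

With `theta_p` the health status of person `p` and `beta_i` the value of
comparator state `i`, responses follow the Rasch model

```
P(Y_ip = 1) = exp(theta_p - beta_i) / (1 + exp(theta_p - beta_i)),
```

where `Y_ip = 1` means "own health preferred". This **holistic** variant
gives every state its own `beta_i`. The **attribute-parameterized**
variant (an LLTM) instead composes state values from dummy-coded
attribute-level weights,

```
beta_i = sum_j alpha_{j, x_ij},   alpha_{j,1} = 0,
```

so a fitted model values *every* state of the classification system
(243 for EQ-5D-3L), including states never shown.

Item-side estimation is conditional maximum likelihood: conditioning on
the raw score `R_p = sum_i Y_ip` (sufficient for `theta_p`) eliminates the
person parameters, so no assumption about the — typically skewed —
person distribution is needed. The conditional likelihood is evaluated
through elementary symmetric functions computed with a log-space summation
recursion, and maximized by damped Newton–Raphson. Person parameters are
estimated in a second ML step with `Var(theta) = 1 / sum_i P_i (1 - P_i)`.
Diagnostics include Andersen's likelihood-ratio test, the nested
Rasch-vs-LLTM likelihood-ratio test, a response-matrix conditioning check
with witness bipartitions, and Guttman scalogram summaries. A seeded
simulator generates data under either variant, including adaptive
comparator selection and ranking-task conversion.

## Worked example

Simulate a study of 163 respondents judging 17 fixed EQ-5D-3L comparator
states, reduce to an estimable item set, and fit both variants:

```r
library(maprmod)

sim <- simulate_responses(simulation_scenario(n_persons = 163, seed = 42))
sim$data
#> Preference response matrix: 163 persons x 17 comparator states
#>   raw scores 0..17; 13 person(s) with extreme scores

reduced <- make_well_conditioned(sim$data)
reduced$dropped_items        # severest states, unanimously judged worse
#> [1] "33323" "33333"

rasch <- fit_rasch_cml(reduced$data)
mapr  <- fit_mapr_cml(reduced$data, system = eq5d3l())
mapr
#> Attribute-parameterized MAPR (LLTM) model, conditional ML
#>   15 items, 10 free weights, 144 persons used; conditional logLik = -428.310
#>   within-attribute level ordering of weights: monotone
#>                       alpha    se
#> mobility:2           -0.378 0.238
#> mobility:3           -3.228 0.384
#> self_care:2          -1.559 0.217
#> self_care:3          -3.600 0.345
#> usual_activities:2   -0.464 0.230
#> usual_activities:3   -1.528 0.250
#> pain_discomfort:2    -0.940 0.216
#> pain_discomfort:3    -3.511 0.247
#> anxiety_depression:2 -1.417 0.217
#> anxiety_depression:3 -3.222 0.235
```

Each `alpha` is the drop in latent value for moving an attribute from "no
problems" to the named level (perfect health `11111` is anchored at 0, so
more negative = worse). Does the 10-weight description capture the 15
state values?

```r
lr_test_nested(rasch, mapr)
#> likelihood-ratio test of nested conditional likelihoods
#>   LR statistic = 3.531, df = 4, p = 0.473
```

No evidence against the attribute model here, so its composed values can
stand in for the holistic ones. Person estimation and valuation of
arbitrary states:

```r
head(fit_persons_ml(reduced$data, mapr$implied_beta), 3)
#>   person raw_score      theta  se_theta extreme
#> 1     P2        14  0.6978969 1.1034479   FALSE
#> 2     P3         9 -2.7394762 0.8081344   FALSE
#> 3     P4        10 -2.1070147 0.7830625   FALSE

round(predict(mapr, c("11111", "21111", "33221")), 3)
#>  11111  21111  33221
#>  0.000 -0.378 -8.232
```

A command-line wrapper over the same pipeline is installed at
`inst/cli/mapr` (`simulate`, `fit-rasch`, `fit-mapr`, `persons`,
`diagnose`, `convert-rankings`, `values`); every run writes a manifest
with input checksums and the seed next to its outputs.

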