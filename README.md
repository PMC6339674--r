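# irtvalid

Psychometric validation of polytomous item banks with graded response
models and simulated computerized adaptive testing.

## What this is for

Before an item bank — a calibrated set of Likert-type questions measuring
one construct, such as social participation or physical function — can be
administered as a computerized adaptive test (CAT), it has to be shown
that an item response theory (IRT) model actually fits: the items must
measure one dominant dimension, be locally independent given that
dimension, have monotone response functions, fit the parametric model
item by item, work the same way across demographic groups, and deliver
reliable scores with few items. `irtvalid` implements that whole
workflow as composable R functions plus one orchestrating pipeline, and
ships a synthetic-cohort generator so every stage can be exercised and
tested without access to survey data.

The measurement model is the logistic Graded Response Model. Item *i*
with *m* ordered categories has slope *a<sub>i</sub>* and increasing
thresholds *b<sub>i1</sub> < … < b<sub>i,m−1</sub>*; the probability of
category *k* or higher is

> P\*<sub>ik</sub>(θ) = 1 / (1 + exp(−a<sub>i</sub>(θ − b<sub>ik</sub>)))

and category probabilities are differences of adjacent boundary curves
(logistic metric, no 1.7 constant). Scores are reported as T-scores,
T = 10θ + 50; Fisher information I(θ) gives SE(θ) = 1/√I(θ) and
reliability 1 − SE².

The stages:

| Stage | Method | Convention |
|---|---|---|
| Unidimensionality | one-factor ULS fit + eigenvalue ratio on the polychoric matrix | CFI/TLI > 0.95, RMSEA < 0.06, SRMR < 0.08, ratio > 4, first factor ≥ 20% |
| Local independence | residual correlations after the one-factor fit | \|r\| ≤ 0.20 |
| Monotonicity | Mokken scaling: Loevinger H, rest-score step curves | item H ≥ 0.30, scale H ≥ 0.50 |
| Model fit | GRM by marginal maximum likelihood (EM), S-X² per item | S-X² p > 0.001 |
| Invariance | ordinal logistic regression DIF, McFadden pseudo-R² change | ΔR² < 0.02 |
| Reliability | post-hoc CAT replay, maximum-information selection | SE 3 on the T metric or 12 items |

## Worked example

```r
library(irtvalid)

design <- simulation_design(n_persons = 500, n_items = 20, seed = 42)
bank   <- sample_bank(design)
sim    <- simulate_responses(bank, design)
bank
#> <item_bank> 20 items, 5 categories, slopes in [2.68, 4.75]
sim$rm
#> <response_matrix> 500 persons x 20 items, covariates: age, gender,
#>   education, region, ethnicity, language

report <- run_pipeline(sim$rm,
                       config = pipeline_config(dif_groupings = c("age", "gender")))
report
#> <validation_report>
#>   one-factor fit: CFI 1.000, TLI 1.000, RMSEA 0.000, SRMR 0.015
#>   eigenvalue ratio: 41.2 (first factor 82.3% of variance)
#>   scalability: H = 0.79 (items 0.68-0.84)
#>   item fit: 0 item(s) flagged at p < 0.001
#>   DIF (age): 0 item(s) flagged
#>   DIF (gender): 0 item(s) flagged
#>   standard CAT: mean 5.0 items, 98% reliability >= 0.90
```

Reading the report: the one-factor model reproduces the polychoric
correlations almost exactly (CFI near 1, SRMR 0.015 — unsurprising, the
data were generated unidimensional), the eigenvalue ratio of 41 is far
above the conventional cutoff of 4, scale H of 0.79 is a strong Mokken
scale, no item misfits at the p < 0.001 level, no DIF is flagged for age
or gender, and a simulated adaptive test reaches reliability ≥ 0.90 for
98% of respondents using 5 items on average instead of all 20.

Individual scoring works the same way outside the pipeline:

```r
est <- score_theta(sim$rm$responses[1, ], bank, "ML")
est
#> <theta_estimate> ML theta = -0.097 (SE 0.126), 20 items
t_score(est$theta)          # 49.0
reliability_from_se(est$se) # 0.984
```

`write_report(report, "report.json")` serializes everything;
`read_report()` round-trips it.

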