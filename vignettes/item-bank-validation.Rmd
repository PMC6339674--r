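---
title: "Validating polytomous item banks: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating polytomous item banks: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`irtvalid` implements the standard psychometric validation workflow for an
item bank of ordered-category (Likert) items, the kind of analysis done
before an item bank is released for computerized adaptive testing (CAT) in
health-outcome measurement. This vignette explains the models each stage
uses, the assumptions behind them, the tunable parameters and their
defaults, and the design decisions taken where the methodology leaves room.

## The measurement model

Responses are modelled with the logistic Graded Response Model (GRM). Item
$i$ with $m$ ordered categories has a slope $a_i > 0$ and strictly
increasing thresholds $b_{i1} < \dots < b_{i,m-1}$ on the latent trait
$\theta$. The probability of responding in category $k$ or above is

$$P^{*}_{ik}(\theta) = \frac{1}{1 + e^{-a_i(\theta - b_{ik})}},$$

with $P^*_{i0} = 1$ and $P^*_{im} = 0$, so category probabilities are
differences of adjacent boundary curves,
$P_{ik} = P^*_{i,k-1} - P^*_{ik}$. The metric is logistic **without** the
historical 1.7 scaling constant; this matters when comparing slopes across
software, because a slope of 3.9 here corresponds to roughly 2.3 on the
normal-ogive metric. The trait is scaled to mean 0, SD 1 in the reference
population, with an effective range of $-4$ to $4$; scores are reported as
T-scores, $T = 10\theta + 50$.

Fisher information is additive over items,
$I(\theta) = \sum_i \sum_k (\partial P_{ik}/\partial\theta)^2 / P_{ik}$,
the standard error of measurement is $SE(\theta) = 1/\sqrt{I(\theta)}$,
and reliability at a trait level is $1 - SE^2$. An SE of 0.316 is
reliability 0.90; 0.548 is 0.70.

## Stages and their criteria

**Unidimensionality.** A one-factor model is fitted to the polychoric
correlation matrix. Polychorics use the classical two-step estimator:
thresholds from inverse-normal cumulative marginals, then each pairwise
correlation by maximizing the contingency-table likelihood over
$[-0.999, 0.999]$; bivariate-normal rectangle probabilities come from a
one-dimensional Gauss–Legendre reduction (64 nodes, accurate to ~1e-10).
The factor model is fitted by unweighted least squares (ULS), and indices
use $\chi^2 = (n-1)F_{\min}$ with the independence baseline: CFI, TLI,
RMSEA $= \sqrt{\max(\chi^2 - df, 0)/(df(n-1))}$, and SRMR (root mean
squared off-diagonal residual). Conventional cutoffs are CFI/TLI $> 0.95$,
RMSEA $< 0.06$, SRMR $< 0.08$, plus an exploratory screen: the
first-to-second eigenvalue ratio above 4 with the first factor carrying at
least 20% of the variance. Two caveats are deliberate: robust/scaled
(mean-and-variance-adjusted) test statistics are **not** computed, so the
RMSEA here is not comparable to values from scaled WLSMV estimation, which
are known to run high on skewed health-outcome data; and non-positive
definite polychoric matrices are eigenvalue-smoothed (negative eigenvalues
raised to 1e-6, rescaled to unit diagonal) before fitting. If the baseline
model is degenerate ($\chi^2_B \le df_B$, e.g. an identity matrix) CFI is
clamped to 1 and flagged.

**Local independence.** Residual correlations (observed minus
model-implied) above 0.20 in magnitude flag possibly locally dependent
pairs.

**Monotonicity (Mokken scaling).** Loevinger's $H_{ij}$ divides the
observed inter-item covariance by the maximum attainable under the two
observed marginals (the comonotonic coupling, i.e. covariance of the two
sorted vectors); items pool to $H_i$ and the scale to $H$. Benchmarks:
every $H_i \ge 0.30$, scale $H \ge 0.50$. Monotonicity of item-step
response functions is checked on rest-score groups: groups of at least
`minsize` persons (default $\max(\lfloor n/10 \rfloor, 50)$, boundaries
only at distinct rest-score values), with a decrease in
$P(X_i \ge k \mid \text{group})$ between adjacent groups counted as a
violation only beyond a tolerance of 0.03. The tolerance operationalizes
what is traditionally a visual inspection; it guards against small-sample
noise and was fixed before any data were examined, not tuned.

**GRM estimation.** Marginal maximum likelihood via EM: the E-step puts
posterior weights on a fixed rectangular quadrature grid (49 equally
spaced nodes on $[-6, 6]$, standard-normal prior, deterministic and
adequate for slopes up to about 5); the M-step maximizes each item's
expected complete-data log-likelihood by BFGS over
$(\log a,\; b_1,\; \log \Delta b)$ — an unconstrained parameterization
that enforces positivity and ordering without constrained optimization.
Convergence is declared when the largest parameter change falls below
1e-4 (or at 500 cycles); the marginal log-likelihood is asserted
non-decreasing every cycle. Categories never observed in the sample are
collapsed into their neighbour with a warning, and
`collapse_categories()` maps the data onto the fitted coding for
downstream stages. The prior is fixed at N(0,1); no latent-density
estimation is attempted.

**Scoring.** ML maximizes the pattern likelihood on $[-4, 4]$; all-lowest
or all-highest patterns have no interior maximum and are clamped to the
bound with an explicit flag (so reports can count or exclude them). EAP
(posterior mean, used for DIF because every person gets a finite, stable
score) and MAP are available. ML/MAP standard errors come from
$1/\sqrt{I(\hat\theta)}$, EAP's from the posterior SD.

**Item fit (S-X²).** For each item, persons are cross-classified by rest
score and category; expected counts under the fitted model use the
Lord–Wingersky summed-score recursion and quadrature. Sparse cells are
collapsed in two passes (adjacent rest-score rows by expected row mass,
then adjacent category cells within rows), always toward the nearer
distribution tail with ties toward lower scores; the floor is an expected
count of 1 per cell. The statistic is referred to chi-square with
$df = \sum_s (K_s - 1) - m$, independent cells minus the item's free
parameter count — a subtraction that presumes the bank was estimated from
the same sample, which is why the type-I calibration test refits the
model on every replicate. Items are flagged at $p < 0.001$; items whose
table collapses below $df = 1$ are reported untestable, never flagged.

**DIF.** Per item, three nested proportional-odds models:
$y \sim \theta$, $y \sim \theta + g$, and
$y \sim \theta + g + \theta g$, fitted with `MASS::polr` (each model
started from the previous one's solution so the log-likelihoods nest
numerically; a ridge-stabilized direct maximization backstops
non-convergence under separation). The criterion is an effect size, not a
test: McFadden's pseudo-$R^2$ change of at least 0.02 between the outer
models flags the item, classified uniform or non-uniform by which
component carries the change. No multiple-testing correction is applied,
by design. Multi-level groupings enter as an ordinal code when the levels
are ordered (education) and as a dummy block otherwise (region,
ethnicity); age uses a median split ($\le$ median vs above, computed on
the analysis sample). Optional purification re-scores the trait from
unflagged items until the flag set stabilizes.

**CAT simulation.** Post-hoc replay: each respondent's full recorded
response vector is replayed against the bank, items chosen by maximum
information at the current estimate, starting with the most informative
item at $\theta = 0$. Standard stopping: SE of 3 on the T metric
($SE_\theta \le 0.3$, reliability just above 0.90) or 12 items, no
minimum; a fixed-length mode (8 items by default) mirrors short-form
length. While the administered pattern is all-extreme the interim ML
estimate is pinned at the relevant bound so selection can proceed;
stopping is checked after each response, so one administered item is the
logical minimum — observed minima of 2–3 items arise from the data, not a
rule. Ties in information break toward the lower item index,
deterministically.

## The synthetic cohort generator

No respondent-level data ship with the package; every test runs on
generated cohorts. The generator emulates a general-population survey of
a high-discrimination participation bank: $\theta \sim N(0, 1)$; 35
five-category items with slopes uniform on $[2.4, 4.8]$ and thresholds
uniform on $[-2.5, 0.6]$, sorted with a minimum gap of 0.05 so no category
is near-degenerate; demographic labels (age $\sim N(51, 17^2)$ truncated
to 18–95, 52.4% female, education 29/43/28, region 10/20/20/50, ethnicity
77/13/10) drawn to Dutch general-population proportions as labels only —
they carry no response effect unless DIF is injected. Ceiling effects are
emulated by shifting the generating trait mean (bisection on the
model-implied expectation) until the expected fraction of all-extreme
response patterns hits a target (7.7% for the ability-like default),
rather than by shifting thresholds, which would change the bank's
interpretation. Injected DIF adds a threshold shift (uniform) and/or a
slope multiplier (non-uniform) for the focal group only.

What the generator does **not** emulate: multidimensional structure,
response styles (e.g. acquiescence), longitudinal dependence, item
non-response, or informative sampling. Passing tests on these cohorts
therefore show that the machinery is correct under the model, not that
any real instrument satisfies the model.

## Problem sizes and numerical choices

The test-suite and acceptance runs use cohorts of about 1000 respondents
and banks of 10–35 items — the scale at which the sampling behavior of
every statistic is already visible while a full run stays in the minutes
range. Type-I calibration of S-X² uses 60 refitted null replicates of a
10-item bank at $n = 1000$ (binomial bounds at the 0.001 level); DIF power
uses 24 replicates of a 0.6-theta-unit uniform shift at 1000 per group.
Quadrature is rectangular and fixed; the polychoric optimizer tolerance is
1e-6 with boundary estimates (e.g. comonotonic pairs) reported at
$\pm 0.999$ and flagged non-converged; Heywood loadings are clamped at
0.999 with a warning; EM M-steps that fail to improve keep the current
parameters so the likelihood cannot decrease.

## Known limitations

- Fit indices are unscaled ULS quantities; they are not comparable to
  scaled WLSMV output, and RMSEA in particular should not be interpreted
  against cutoffs derived for scaled estimators.
- The S-X² chi-square reference is approximate; with known (not
  estimated) parameters the df correction overstates significance.
- DIF screening assumes the proportional-odds structure within groups and
  uses EAP scores as the matching variable; heavy DIF contamination of
  the matching score is only partially addressed by purification.
- The CAT replay assumes complete recorded response vectors and does not
  model exposure control or content balancing.
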