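---
title: "Hybrid OLR/IRT DIF detection for dyadic informant data: models, decisions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid OLR/IRT DIF detection for dyadic informant data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a child's health-related quality of life (HRQoL) is rated both by the
child and by a parent proxy, disagreement between the two reports mixes two
very different things: genuine differences in the perceived construct, and
*differential item functioning* (DIF) — items that two respondents at the
same level of the underlying trait answer with different probabilities
because they read the item differently. Before comparing or combining
parent and child scale scores, the items should be screened for DIF, and
scale-level comparisons should be repeated with DIF-affected items
handled explicitly.

`difdyad` implements this workflow for polytomous Likert instruments,
with the 23-item, four-subscale PedsQL 4.0 Generic Core Scales layout
shipped as the default (`pedsql_spec()`).

## The hybrid OLR/IRT procedure

Each subscale is analysed separately with its own latent trait; a
multidimensional treatment of the correlated subscales is out of scope.
The engine (`run_hybrid_dif()`) alternates two standard models:

**Matching trait.** Samejima's graded response model (GRM) gives, for item
$j$ with discrimination $a_j > 0$ and ordered thresholds
$b_{j1} < \dots < b_{j,K-1}$,

$$P(Y_j \ge k \mid \theta) = \frac{1}{1 + e^{-a_j(\theta - b_{jk})}},$$

with category probabilities as differences of adjacent cumulative curves.
The model is calibrated on the pooled two-group data by marginal maximum
likelihood (EM), and each respondent is scored by the expected a
posteriori (EAP) trait estimate under a standard normal prior.

**Per-item DIF testing.** Conditioning on the estimated trait, three
nested proportional-odds models are fitted per item:

$$\text{logit}\, P(Y_i \ge k) = \alpha_k + \beta_1\,\text{trait}
 \;[+\; \beta_2\,\text{group}\;[+\; \beta_3\,\text{trait}\times\text{group}]]$$

Uniform DIF is the group main effect ($\beta_2 \ne 0$, Model 1 vs
Model 2) and non-uniform DIF the trait-by-group interaction
($\beta_3 \ne 0$, Model 2 vs Model 3); both are tested by likelihood-ratio
chi-square statistics with one degree of freedom. Two magnitude measures
accompany the tests: the McFadden pseudo-$R^2$ difference between the
nested models, and the Crane–van Belle–Larson (CvBL) proportionate change
$|(\beta_1^{(1)} - \beta_1^{(2)})/\beta_1^{(1)}|$ of the trait
coefficient. An item whose non-uniform test fires is classified
non-uniform even when the uniform test also fires.

**Purification.** Flagged items contaminate the matching trait, so the
GRM is refitted with group-specific parameters for the currently flagged
items (implemented by expanding each flagged item into two per-group
pseudo-items), all respondents are re-scored, and all items re-tested.
This repeats until two successive iterations flag the same set. The
alternative reading of the procedure — dropping flagged items from trait
estimation instead of recalibrating them per group — is available as a
config option. If the flag set oscillates between two states until
`max_iter`, the union is reported with status `"unstable"` rather than
silently picking one state.

## Monte Carlo empirical thresholds

Logistic-regression DIF tests are known to exceed their nominal type-I
error, most severely when the groups differ on the trait itself — exactly
the situation in parent–child data. `empirical_thresholds()` therefore
derives per-item decision thresholds under a no-DIF null matched to the
observed data: the pooled calibration's item parameters (shared between
groups, hence DIF-free by construction) generate simulated responses *at
each respondent's observed EAP trait*, preserving group sizes and the
groups' trait distributions. Each replicate is re-analysed in a single
pass — trait re-estimated, all five statistics computed per item; there is
nothing to purify under the null, and in expectation purification is a
no-op there. An alternative mode drawing null traits from a normal
distribution is available as a config switch.

Thresholds are order statistics of the `nrep` null draws: with
$k = \lfloor \alpha\,(\mathrm{nrep}+1) \rfloor$, the $k$-th smallest null
p-value (for the two chi-square tests) and the $k$-th largest null draw
(for the two $\Delta R^2$ measures and the CvBL change). A fresh null
statistic then exceeds its threshold with probability exactly
$k/(\mathrm{nrep}+1)$ — $10/1001 \approx 0.01$ at the default
`nrep = 1000`, `alpha = 0.01`, and $1/101$ in the scaled-down
`nrep = 100` mode used by the test suite. An interpolating sample
quantile would be anticonservative at small `nrep`. The $\Delta R^2$
thresholds genuinely differ across items because they depend on each
item's category distribution — the reason a single fixed cutoff is not
used. The CvBL threshold is reported descriptively alongside uniform
flags; it does not gate them (whether the original analyses gated on it
is ambiguous, so gating is left to a config switch).

Fit failures inside a replicate are logged and the replicate redrawn, up
to a retry budget, after which the simulation errors out.

## Scale scoring, agreement, and DIF-corrected scores

Raw responses 0–4 (0 = never a problem) are reverse-scaled to 0–100 by
$(4 - \text{raw}) \times 25$, so higher scores mean better HRQoL.
Subscale scores are means of transformed answered items; the total score
is the mean over all answered items (not the mean of subscale means), and
a score is undefined when fewer than half of its items were answered — a
near-moot rule given the 5% missing-item eligibility filter, under which
a respondent missing more than 5% of items is excluded together with the
dyad partner (the pipeline pairs both members, so an incomplete dyad
cannot be analysed).

Cross-informant agreement per subscale uses the paired t-test, the
pooled-SD effect size $|\bar x_1 - \bar x_2| / \sqrt{(s_1^2+s_2^2)/2}$
with Cohen labels (half-open intervals $[0,0.2)$ negligible, $[0.2,0.5)$
small, $[0.5,0.8)$ medium, $\ge 0.8$ large), and the intraclass
correlation in its two-way, single-measurement, absolute-agreement form
(ICC(A,1)), labelled poor $< 0.40$, moderate $[0.40, 0.60]$, good
$(0.60, 0.80]$, excellent $> 0.80$. The printed conventional cutoffs
leave gaps (0.40/0.41, 0.60/0.61); the label function closes each gap at
the lower edge so it is total. A consistency-form ICC is available as a
switch. When every paired difference is identical the t statistic is
undefined; the convention is $p = 1$ for a common difference of zero and
$p = 0$ otherwise.

DIF-corrected scores implement the cancellation idea: at the scale level
two uniform-DIF items pushing in opposite directions offset each other,
so only *uncancelled* uniform items bias the scale score.
`cancellation_partition()` pairs uniform-flagged items of opposite
$\beta_2$ sign greedily (largest $|\beta_2|$ first) and marks the
unpaired remainder for removal; non-uniform items are never removed by
this rule, and removing *all* uniform items instead is a config switch
(the narrower uncancelled-only reading is the default). When every item
of a subscale is removed, the corrected score does not exist and the
report row says so instead of printing a number. The sign convention is
fixed package-wide: the group is coded 0/1 with the reference level
first alphabetically (unless pinned), and $\beta_2 > 0$ means the coded-1
group endorses higher categories at equal trait, so opposite signs mean
opposite DIF directions.

## Numerical choices

* **Quadrature**: 49 equally spaced nodes on $[-4, 4]$ with normalised
  standard-normal weights, shared between fitting and EAP scoring. EAP
  estimates agree with brute-force integration on a 10× finer grid to
  well below $10^{-3}$.
* **EM**: starting values $a = 1$ and thresholds from the observed
  cumulative category frequencies; convergence when the largest absolute
  parameter change drops below $10^{-4}$ (at most 500 iterations); the
  marginal log-likelihood is asserted non-decreasing at every iteration.
  The M-step reuses the proportional-odds Newton solver (a GRM item in
  slope–intercept form *is* a weighted cumulative-logit regression on the
  quadrature nodes).
* **Identification**: the trait prior is standard normal in the pooled
  calibration; group trait differences are absorbed by the data.
* **Sparse categories**: an observed category with fewer than 5 responses
  in either group is collapsed with its neighbour before fitting (the
  smaller neighbour first), with the mapping retained; this prevents
  unstable extreme thresholds in small runs.
* **Proportional-odds fits**: full Newton–Raphson on
  $(\alpha_1..\alpha_{K-1}, \beta)$ with analytic gradient and Hessian,
  step-halving (which also guards the ordering of the cumulative
  probabilities, since an inadmissible step yields a non-positive
  category probability and is rejected), and a ridge fallback for
  near-singular Hessians. Fits match `MASS::polr` to more than 4
  decimals; `polr` is used only as a test oracle.
* **Trait estimator**: EAP rather than ML/WLE, because it is defined for
  perfect and empty-category response patterns. The trait enters the OLR
  models as estimated, without further centring; the interaction column
  is the plain product.
* **Missing responses**: left out of the likelihood (GRM) and the fitted
  rows (OLR) by default. Within-group item-mean imputation (rounded to a
  valid category) is available as `impute = "mean"`, but rounding imputed
  ordinal categories is a distortion the likelihood-based default
  avoids.

## The synthetic dyad generator

Real questionnaire data of this kind are typically not redistributable,
so `generate_dyads()` provides the statistical structure the analysis
assumes: dyad members' traits are bivariate normal with correlation
`rho` (default 0.5, matching the small-to-moderate parent–child
agreement typical of HRQoL studies) and a mean shift of the child
relative to the parent (default −0.25 on the trait scale: children tend
to report slightly fewer problems than parent proxies). Item parameters
default to discriminations evenly spaced over 1.2–2.0 with thresholds
spread within $[-2.5, 2.5]$ — informative items typical of
patient-reported-outcome scales. Uniform DIF is injected as a common
threshold shift `delta` for the child group (location DIF, mapping onto
$\beta_2$) and non-uniform DIF as a discrimination ratio `gamma`
(mapping onto $\beta_3$); `delta = 0, gamma = 1` is the no-DIF null.
`preset_scenarios()` fixes the study conditions used throughout the
tests: five-item scales at 500 dyads for the null, single-uniform
(`delta = 0.6`), opposite-pair (`±0.6`) and single-non-uniform
(`gamma = 2`) scenarios, and a 23-item, four-subscale, 573-dyad layout
mirroring a realistic field-study size. Missingness beyond MCAR is not
simulated.

What the generator does *not* emulate: parent and child responses are
conditionally independent given the bivariate trait (no shared-method
effects), subscale traits are generated independently per analysis, and
response styles (acquiescence, extreme responding) are absent. Passing
tests on these data show the machinery is correct and calibrated under
the model's own assumptions, not that real parent–child data satisfy
those assumptions. Treating the two dyad members as independent groups
reproduces the analysis design this package implements; the dependency
between paired informants is a known limitation of that design, surfaced
here rather than fixed.

## Problem sizes used by the shipped checks

The packaged calibration checks run at deliberately scaled sizes chosen
to keep the full suite in the minutes range while leaving the binomial
error bands meaningful: Monte Carlo thresholds at `nrep = 100`
($k = 1$), type-I calibration pooled over 5 items × 200 independent null
datasets against one threshold table, power at 200 replicates of the
single-uniform scenario, GRM parameter recovery at $n = 1000$ with 10
items. The `nrep = 1000` default of `empirical_thresholds()` remains the
recommended analysis setting.

## Known limitations

* One trait per subscale; no multidimensional IRT.
* Dyad members treated as independent groups (see above).
* No anchor-item mechanism besides purification itself.
* Likelihood-ratio tests only (no Wald/score variants), matching the
  analysis design.
* The Monte Carlo null conditions on estimated (EAP) traits and fitted
  parameters; at small samples this parametric-bootstrap approximation
  inherits their estimation error.
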