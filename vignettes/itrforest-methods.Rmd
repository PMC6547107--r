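---
title: "Methods: individualized treatment rules with treatment muting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized treatment rules with treatment muting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`itrforest` implements a post hoc precision-medicine reanalysis pipeline for
two-arm randomized trials with 1:1 allocation. Given baseline covariates,
randomized arm `A` (1 = intervention, 0 = control) and follow-up outcomes, it

1. constructs scaled clinical **rewards** from outcome change scores,
2. **multiply imputes** missing baseline covariates,
3. fits a **reinforcement-learning-tree (RLT) regression forest** of the
   reward on covariates plus `A`,
4. reads an **individualized treatment rule (ITR)** off the forest's
   counterfactual predictions, with a third *muted* group for participants
   whose predictions do not depend on `A` at all,
5. estimates the **value** of the rule by normalized inverse probability
   weighting (IPW) with bootstrap confidence intervals, and
6. **profiles** the resulting subgroups on baseline variables with
   Benjamini–Hochberg multiplicity adjustment.

A calibrated synthetic-cohort generator with known potential outcomes
supports validation of every stage.

# Rewards

All rewards are oriented so that larger is better and are built from change
scores between baseline and the 18-month follow-up.

* **HbA1c**: reward is the *decrease* `hba1c_0 - hba1c_18`, clipped to
  `[-5, +5]` before use, so a 1-point improvement scores `+1`.
* **Quality of life** (0–100 scale): reward is the increase
  `qol_18 - qol_0`, clipped to `[-30, +30]`.
* **BMI z-score**: participants ending at or below the overweight threshold
  `1.04`, or improving relative to baseline, receive reward `0`; otherwise
  the reward is the (negative) linear penalty `-(bmiz_18 - max(bmiz_0, 1.04))`.
* **Hierarchical composite**: a lexicographic tiering. Participants with
  follow-up HbA1c at or above 9.0% fall in tier 0 and score their HbA1c
  reward; of the rest, those with follow-up QoL below 70 fall in tier 1 and
  score `1 +` their QoL reward; everyone else scores `2 +` their BMI-z
  reward. Each tier's offset exceeds the previous tier's maximum, so tier
  membership dominates any within-tier difference.

Before model fitting, rewards and continuous covariates are standardized to
zero mean and unit variance (constant columns map to zero with a warning).
The treatment indicator enters the design matrix unstandardized and is
deliberately placed in the **last** column (see the tie-break rule below).

# The RLT forest

The forest (`rlt_forest()`) averages `n_trees = 100` regression trees, each
grown on a 0.8-fraction row subsample drawn without replacement. Trees are
grown by the reinforcement-learning-tree recipe rather than CART:

**Embedded importance.** At each node an *embedded ensemble* of
`embedded_trees = 20` shallow CART trees (`embedded_depth = 2`) is fit on
0.632-fraction row subsamples of the node's data. Every candidate variable
is offered to every embedded tree — restricting candidate sets here would
only add variance to the importance ranking, which is the sole product of
the ensemble. Variable importance is the mean, over embedded trees, of the
increase in out-of-bag squared error when that variable's out-of-bag values
are permuted (a variable unused by a tree contributes exactly zero for that
tree).

**Importance gate.** A candidate's importance is kept only if the one-sided
t statistic of its per-tree permutation deltas exceeds
`importance_gate = 4`; otherwise it is set to exactly zero and the variable
cannot be chosen at this node. The gate exists because the muted group is
defined by *exact* counterfactual equality: a single noise split on `A`
anywhere in any of the 100 trees removes a region from the muted set.
Treating each node as a hypothesis test, a gate of 4 keeps the per-node
false-positive rate near `3e-5`, small against the roughly `10^3`–`10^4`
node tests a default forest performs, while a 3-SE gate would not be.

**Statistical tie-break toward covariates.** After gating, candidates are
ranked by importance. The top candidate keeps first place only if it is
*decisively* better than every other gated-in candidate — the paired t
statistic of the per-tree importance differences must exceed the same gate.
Candidates that are statistically indistinguishable from the top form a tie
set resolved to the **lowest column index**. This matters because under a
pure covariate-by-treatment interaction the permutation importances of the
covariate and of `A` are equal in expectation, so the data cannot order
them; either split order fits the training data equally well, but splitting
`A` first destroys the muted-region structure the method is designed to
recover. Placing `A` last in the design makes the tie-break defer treatment
splits to be as deep and localized as the data allow, without ever
overriding a genuine, statistically clear win by `A`.

**Progressive muting.** After a split, the bottom
`ceiling(muting_rate * |remaining|)` candidates by importance (ties muted
from the highest index down) are removed from the children's candidate
sets; the split variable itself is never muted at its own node. With
`muting_rate = 0.3`, deep nodes see progressively fewer variables, and `A`
can be muted out of entire subtrees — the mechanism behind the muted group.

Nodes stop splitting below `min_node_size = 10` rows or when no gated
candidate admits a valid cutpoint. Cutpoints are midpoints between adjacent
observed values; rows route left when `x <= cutpoint`.

**Degenerate CART mode.** With `muting_rate = 0`, `embedded_trees = 1`,
`subsample_frac = 1` and one tree, the embedded step reduces to exact
best-single-split variance reduction and the fit reproduces a greedy CART
tree — an oracle equivalence exercised in the test suite.

# From forest to rule

For each participant, `counterfactual_rewards()` predicts the forest twice,
with `A` forced to 1 and to 0, giving `r1` and `r0`. The assignment is
`intervention` if `r1 > r0`, `control` if `r0 > r1`, and **muted** if
`r1 == r0` exactly — which occurs precisely when `A` lies on no routing path
for that participant in any tree. Comparison is exact (`tol = 0`): the two
predictions traverse identical node sequences whenever `A` is off-path, so
no floating-point slack is needed or wanted.

The rule is estimated independently on each of `m = 11` imputed datasets and
combined by **plurality vote**; ties go to muted, the conservative label.

# Value estimation

The value of a rule `d` is estimated with the normalized (ratio) IPW
estimator

$$\hat v(d) = \frac{\sum_i \mathbf{1}\{A_i = d_i\}\, w_i R_i}
                   {\sum_i \mathbf{1}\{A_i = d_i\}\, w_i},
\qquad w_i = \frac{A_i}{p} + \frac{1 - A_i}{1 - p},$$

with `p = 0.5` under 1:1 randomization. The ratio form keeps `v_hat` inside
the observed reward range and makes three identities exact: `d == A` returns
the plain mean reward, and the constant rules return the within-arm means.
Muted participants follow their observed arm by default (`muted = "observed"`),
so the estimated rule is always fully concordant-evaluable; `muted = "exclude"`
drops them instead. Confidence intervals for `v(d) - v(all-intervention)`
and `v(d) - v(all-control)` are percentile bootstrap over participants
(`B = 200` by default; the rule is held fixed, not refit, in each
replicate).

# Subgroup profiling

Baseline variables are compared across the three groups with ANOVA
(continuous), Kruskal–Wallis (skewed counts) or chi-square tests
(categorical; Fisher's exact when any expected cell count falls below 5),
followed by Benjamini–Hochberg adjustment across variables and pairwise
tests of each group against the intervention group. Summaries print as
`mean (SD)`, `median (IQR)` or `n (%)` by variable kind. If a labelling has
fewer than two non-empty groups, tests degrade gracefully to descriptives.

# The synthetic generator

`generate_cohort()` draws baseline covariates from moment-matched truncated
or interval-censored normal parents (solved numerically at build time of the
spec object, not hard-coded), negative-binomial hypoglycemia counts, and
categorical demographics. Follow-up outcomes are baseline plus a common
drift, plus a treatment effect determined by an `effect_spec`: an ordered
list of strata, each keyed to an interval of one covariate, that must tile
`(-Inf, Inf]`. Both potential outcomes are generated for every participant
and stored in a `potential` attribute alongside a `truth` stratum column, so
tests can compute generator-truth values and rule-recovery rates exactly.
Missingness is MCAR by default with an optional MAR mechanism keyed to an
observed covariate; the continuous-glucose-monitoring completeness flag and
follow-up outcomes have separate rates feeding the eligibility filter.

The generator's calibration targets are baseline means (HbA1c 9.6%, QoL
81.2, BMI z 0.73) verified at `n = 200,000` in the acceptance suite and by
`scripts/acceptance.R`. The generator is a *validation instrument*: it makes
no claim to reproduce any particular trial's joint distribution, correlation
structure, or treatment-effect surface.

# Numerical choices

* All C++ randomness uses R's own RNG stream, so `set.seed()` makes every
  stage — generator, imputation, forest, bootstrap — exactly reproducible,
  and the pipeline derives independent sub-seeds per stage so that changing,
  say, the bootstrap replicate count cannot perturb the assignments.
* Imputation is chained equations with predictive mean matching (`k = 5`
  donors) for continuous and count variables and multinomial draws for
  categorical ones, run for `n_cycles = 10` sweeps from a marginal initial
  fill.
* Trees are stored as flat node matrices and serialize to JSON for
  round-trip persistence.

# Limitations

* The IPW identities and unbiasedness hold for rules that are functions of
  baseline covariates only. When the evaluated arm vector depends on the
  observed arm — as it does for muted participants under
  `muted = "observed"`, who are concordant by construction — those
  participants enter the normalized estimator with twice the effective
  weight of participants whose concordance is random. The resulting value is
  a well-defined weighted summary, but it is not an unbiased estimate of the
  population regime "muted participants are randomized"; use
  `muted = "exclude"` when a pure covariate-only rule value is needed.
* No sample splitting or cross-fitting: the rule is estimated and valued on
  the same data, so bootstrap intervals for `v(d̂)` carry optimism; the
  coverage guarantees exercised in the tests hold for *fixed* rules.
* The muted group is defined by exact prediction equality under the fitted
  forest — it is a statement about the estimated model, not a sharp null
  hypothesis test of zero individual effect.
* The IPW estimator assumes the randomization probability is known and
  constant; observational use would require estimated propensities and is
  out of scope.
* Chained-equation imputation assumes missing at random given the observed
  covariates.
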