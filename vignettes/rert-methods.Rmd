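---
title: "Representative regression trees: model, procedure and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representative regression trees: model, procedure and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rert)
```

## The problem

Endometrial-carcinoma patients clinically staged as early (disease confined
to the uterine corpus) are surgically restaged as advanced in roughly a
fifth of cases.  A preoperative risk model that combines serum biomarkers
(HE4 in pmol/L, CA125 in U/mL) with routine clinical covariates can support
the choice between conservative and radical surgery — but clinicians need
an *interpretable* rule with explicit cut-offs, not a black-box score.

`rert` implements a two-step procedure for this setting:

1. **Driver screening.** A random forest of regression trees is grown on
   all covariates and each covariate's *Total Decrease in Node Impurity*
   (TDNI) is computed; rescaled to a 0–100 relative scale, covariates
   above a cutoff (default 60) are called drivers.
2. **Representative tree.** An ensemble of `B` trees is grown, one per
   histotype-stratified bootstrap sample, each pruned by cross-validated
   cost-complexity selection.  Every candidate is scored by the AUC of its
   predictions on the full cohort, and the best performer is returned as
   the REpresentative Regression Tree (RERT) — a single flow-chart whose
   leaves carry event relative frequencies.

## The tree model

Trees are *regression* trees on a 0/1 outcome.  Node impurity is the
squared-error (ANOVA) deviance

$$ I(t) = \sum_{i \in t} (y_i - \bar y_t)^2 = n_t\, p_t (1 - p_t), $$

with $p_t$ the positive fraction, and every leaf predicts
$\hat y = n_{\text{pos}}/n$ exactly — the relative frequency of events
among its members.  This choice (rather than Gini/entropy classification)
makes the leaf values directly readable as risks and gives two exact
conservation identities that the test suite asserts on every fit:
$\sum_{\text{leaves}} n_\ell \hat y_\ell = n_{\text{pos}}$, and on
complete data $I(\text{root}) = \sum_{\text{leaves}} I(\ell) +
\sum_{\text{splits}} \Delta$.

Splits maximize the impurity decrease $\Delta$ over all covariates, with

* thresholds restricted to midpoints between consecutive distinct observed
  values (so reported cut-offs look like 78.05, never a data point);
* ordered categoricals split on their level index; nominal categoricals
  searched through the within-level-mean ordering, which is exact for
  squared error;
* splits scored on **observed** values only; cases missing the split
  covariate are routed with the child holding the majority of observed
  members, and that direction is frozen into the model (full surrogate
  splits are deliberately out of scope — the simple rule is deterministic
  and testable);
* ties in $\Delta$ (within $10^{-9}$) resolved to the covariate earlier in
  schema order, then the smaller threshold, so fits are reproducible
  bit-for-bit.

### Pruning and cross-validated selection

Weakest-link pruning repeatedly collapses the internal node with the
smallest link strength
$g(t) = \bigl(I(t) - \sum_{\ell \text{ below } t} I(\ell)\bigr) /
(|\text{leaves below } t| - 1)$, producing a strictly nested subtree
sequence indexed by increasing $\alpha$.  `select_subtree_cv()` estimates
the cross-validated squared error of each $\alpha$ with outcome-stratified
`v`-fold CV (default `v = 10`; folds are seeded, classes spread as evenly
as counts allow, and `v = n` degenerates to exact leave-one-out).  Fold
trees are grown and pruned independently and evaluated at the
geometric-mean representative $\alpha$ of each interval.  The selected
subtree minimizes CV error; ties go to the smaller subtree, then the
smaller $\alpha$ index.

Growing defaults (`min_split = 20`, `min_leaf = 7`, `max_depth = 30`,
`cp = 0.01`) follow the conventions of recursive-partitioning practice at
cohort sizes of a few hundred; only `v = 10` is fixed by the procedure's
definition, and all are exposed in `grow_params()`.

## Selection versus honest evaluation

The apparent AUC of the selected candidate (`selection_auc`) is a maximum
over `B` draws and is optimistically biased, on pure-noise data typically
0.6–0.8.  `fit_rert()` therefore also reports an honest estimate: the
entire `B`-candidate selection is rerun inside each of `eval_folds`
outcome-stratified folds and every row is scored by the representative
tree of the fold that held it out (`cv_scores`, `cv_auc`).  Both numbers
are exposed deliberately — the apparent AUC is the selection criterion,
the nested-CV AUC is the performance claim.  The acceptance suite
demonstrates the gap on pure-noise cohorts (n = 300, B = 100, 20 seeds, a
size chosen to make the Monte-Carlo band tight while keeping the
simulation inexpensive): nested-CV AUC stays near 0.5 while the apparent
selection AUC exceeds it.

Other procedure details:

* Bootstrap samples are drawn within each histotype stratum (sample size
  equal to the stratum size), so stratum counts are preserved exactly on
  every draw; the mean unique-row fraction matches the classical
  $1 - 1/e \approx 0.632$ level.
* A bootstrap sample containing a single outcome class is discarded and
  redrawn under an incremented sub-seed, so the ensemble always has
  exactly `B` members.
* Sub-seeds derive from `(seed, b)` through a Lehmer-style congruential
  fold (`derive_seed()`), so candidate `b`'s result does not depend on
  `B`.
* Best-AUC ties resolve to the candidate with fewer leaves (parsimony),
  then the lower replicate index.
* `consensus_report()` summarizes how strongly the high-AUC candidates
  (default AUC > 0.80) agree on the root covariate and threshold — the
  stability observation that motivates returning a single representative.

## The evaluation harness

`roc_auc()` computes the tie-corrected Mann–Whitney AUC from midranks;
the ROC curve itself is built from the threshold sweep, and the test suite
checks that its trapezoid area equals the rank form to $10^{-12}$.
Operating points come from the Youden index $J = \text{sens} +
\text{spec} - 1$ maximized over midpoint thresholds with $\pm\infty$
sentinels; ties take the smallest threshold (favoring sensitivity), and
predictions are positive when score $\geq$ threshold.  Confusion metrics
with zero denominators are returned as `NaN` with an explicit flag, never
silently.

Paired AUCs are compared by the DeLong test (midrank placement values,
normal reference, two-sided; self-comparison returns p = 1 by convention)
and by a stratified paired bootstrap (normal approximation to the
replicate distribution of the AUC difference).  Association tests follow
standard nonparametric practice: Wilcoxon–Mann–Whitney for a quantitative
covariate across two groups (exact enumeration when both groups have at
most 8 observations and no ties, tie-corrected normal approximation
otherwise), Kruskal–Wallis beyond two groups, Pearson chi-squared without
continuity correction for two categoricals, all after excluding missing
values and without multiplicity correction.  The logistic baseline is a
main-effects ML fit with listwise deletion (a linear model cannot route
missing values the way the trees do); deletion counts, non-convergence
and quasi-separation are reported, never silent.

## The synthetic cohort generator

The study data this package was designed around are not publicly
deposited, so `generate_cohort()` emulates their *structure* and every
empirical claim in the package is made on that emulator:

* **Marginals** fitted to published summary statistics of a 293-patient
  cohort: log-normal biomarkers (HE4: median 76 pmol/L, sdlog 0.834;
  CA125: median 17.3 U/mL, sdlog 1.313 — both matching the reported
  medians and upper percentiles), normal age (63 ± 9 years) and BMI
  (27 ± 5.5 kg/m²), Poisson children (λ = 1.8), Bernoulli binaries at the
  reported proportions, a four-level biopsy grading, and a
  254:39 endometrioid/non-endometrioid histotype stratum.
* **Correlation** between log-HE4 and log-CA125 imposed exactly at 0.49
  through a Gaussian copula on the log scale (for log-normal marginals the
  copula correlation *is* the log-scale Pearson correlation).
* **Outcome** drawn from a planted threshold-interaction tree mirroring
  the reference flow-chart: root HE4 at 78, then clinical stage, BMI at
  31.5 and HE4 at 135, with leaf probabilities {0.07, 0.95, 0.04, 0.90}.
  The one leaf the chart does not print is solved in closed form
  (`p = 0.4888`) so the expected prevalence equals the reported 99/293;
  the solution uses the exact leaf-region probabilities under the
  independent marginals.
* **Missingness** completely at random, per covariate, at the reported
  missing fractions (e.g. contraception 87/293).  MCAR is a deliberate
  simplification: no missingness mechanism is documented for the original
  data, and MCAR keeps recovery experiments unconfounded.

What the emulator does **not** reproduce: the conditional structure among
covariates (e.g. the HE4–age association), informative missingness, and
any cohort idiosyncrasies.  Green tests therefore certify the machinery —
exact identities, oracle equivalence, calibration, recovery under a known
truth — not the original cohort's headline numbers, which are documented
as non-reproducible expectations.

### The recovery benchmark and identifiability

`recovery_benchmark_config()` plants the deterministic rule
*y = 1 iff (HE4 ≥ 78 and advanced stage) or (HE4 ≥ 135 and BMI < 31.5)*
with 10% label noise.  This rule admits several tree representations of
identical predictive value: a tree rooted at HE4 = 135, or at clinical
stage, can express the same partition with one or two extra nodes.  Which
root is *greedily* optimal depends on the covariate marginals.  Under the
study-emulator marginals (advanced stage ≈ 15%), the population
impurity-gain ordering puts the HE4-135 cut first, so "recovering the
78 root" is not a property a correct implementation can have there.  The
benchmark marginals are therefore chosen so the 78 cut dominates: with
advanced-stage probability 0.7 and HE4 sdlog 0.35, the population gain of
the 78 split exceeds that of both the stage split and the 135 split by a
factor of about three, which makes the planted root the unique greedy
optimum with a comfortable sampling margin at n = 300.  The benchmark is
an identifiability construction, not a clinical emulation, and is kept
separate from `default_study_emulator()`.

## Numerical choices and degenerate inputs

* Gain and CV-error ties use absolute tolerances ($10^{-9}$ and
  $10^{-12}$) so independently computed quantities classify ties the same
  way; impurities are computed from integer positive counts
  ($I = s - s^2/n$), keeping the identities exact to rounding.
* Single-class cohorts grow to a root-only tree (prediction 0 or 1) —
  a valid model, not an error; AUC on single-class labels *is* an error.
* A forest in which no tree ever splits yields all-zero TDNI with a
  warning flag rather than a 0/0 rescale.
* All randomness flows from user-supplied seeds; reruns of
  `run_two_step()` with the same configuration produce byte-identical
  artifacts, which the test suite asserts.

## Problem sizes used in the simulations

Simulation-based checks run at n = 300 cohorts with B = 100–200 bootstrap
candidates and 20 outer seeds, forests at 200 trees, calibration checks at
n = 10000 — sizes at which the Monte-Carlo bands in the tests are
comfortably tight while the whole suite stays inexpensive.  The procedure
itself defaults to B = 1000 and 10000 forest trees for real analyses.

## Known limitations

* No surrogate splits: heavy, informative missingness on a key covariate
  will degrade the trees more than it would a surrogate-aware CART.
* The representative tree is a single draw from a selection distribution;
  `consensus_report()` quantifies, but does not remove, that variability.
* The bootstrap AUC comparison uses a normal approximation rather than
  percentile intervals.
* The logistic baseline's listwise deletion means its metrics are
  computed on a subset of rows whenever covariates are missing; deletion
  counts are reported so the comparison can be read accordingly.
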