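---
title: "Learning and evaluating a REBOA prescription policy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning and evaluating a REBOA prescription policy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reboatree)
```

## The problem

Resuscitative endovascular balloon occlusion of the aorta (REBOA) is a
catheter-based hemorrhage-control intervention for patients in hemorrhagic
shock. Whether it helps or harms is contested: observational registries show
much higher mortality among REBOA recipients, but those patients are also
far sicker, so the raw comparison is confounded. `reboatree` implements an
observational prescriptive-analytics workflow for this decision: it
estimates, for every patient, the counterfactual 24-hour mortality under
each action, learns an interpretable binary policy tree that assigns REBOA
or no REBOA by trauma-bay physiology, and evaluates that policy off-policy
on a held-out half of the data. Because the national trauma registry this
kind of study uses is access-restricted, the package ships a synthetic
cohort generator with known ground truth, so the whole pipeline is testable
end to end.

## Cohort construction

`apply_study_filters()` reproduces a registry-style attrition chain: adults
(age strictly over 16) with blunt mechanism arriving in hemorrhagic shock
(arrival systolic blood pressure at most 90 mmHg, inclusive, or at least 4
units of red cells within 4 hours, inclusive), excluding inter-facility
transfers and records missing age or length of stay. Each exclusion is
attributed to a single criterion, in order, in an auditable attrition log.
Treatment is labelled by `label_reboa()` from timed ICD-10 procedure codes
(the five standard REBOA codes, configurable) within 4 hours of arrival.

`derive_features()` restricts the model matrix to covariates knowable in
the trauma bay — demographics, admission physiology, first-hour procedures,
primary-survey injury flags, facility attributes — and warns about and
excludes anything else, so information acquired after the treatment
decision (injury severity scores, later transfusion volumes, length of
stay) cannot leak into the models. An unobtainable blood pressure is
encoded as a missing numeric plus an explicit `sbp_unobtainable` indicator:
obtainability itself is clinically informative (profound shock) and must be
available as a split variable in its own right.

## Imputation

Missing covariates are filled by a deterministic k-nearest-neighbour
imputer (`fit_imputer()` / `impute_table()`): distances are standardized
Euclidean over the numerics co-observed between the target row and a donor
pool of fully complete training rows; numeric gaps take the mean of the
`k = 10` nearest donors, categorical gaps the donor-set mode with a
lexicographic tie-break; rows with no usable distance fall back to training
medians/modes. Observed cells are never altered. The imputer is fitted on
the training half only; the evaluation half gets its own imputer as part of
the test-side re-estimation described below. kNN was chosen because it is
deterministic, leakage-controllable, and swappable behind this interface;
nothing downstream depends on the imputation method beyond completeness.

## Doubly-robust rewards

For covariates $x$, treatment $T \in \{0, 1\}$ and 24-hour death
$y \in \{0, 1\}$, `fit_nuisance()` fits a propensity model
$\hat\pi(x) = \hat P(T = 1 \mid x)$ and outcome models
$\hat\mu_t(x) = \hat P(y = 1 \mid x, T = t)$ as `ranger` probability
forests, cross-fitted over 5 folds stratified on the joint $(T, y)$ classes
so that no record is scored by a forest trained on it. The per-patient
doubly-robust reward is

$$\Gamma_i(t) = \hat\mu_t(x_i) + \frac{\mathbf 1\{T_i = t\}\,
(y_i - \hat\mu_t(x_i))}{\hat\pi_t(x_i)},$$

with $\hat\pi_1 = \hat\pi$ and $\hat\pi_0 = 1 - \hat\pi$. Lower is better
(mortality scale); the arm not received is exactly the plug-in prediction.
The sample mean of $\Gamma(t)$ is consistent for the population mean
counterfactual mortality if either nuisance model is correct.

Three defaults matter and are deliberate:

* **Propensity clipping `eps = 0.05`.** Out-of-fold propensities are
  clipped to $[\varepsilon, 1 - \varepsilon]$ before division. At
  $\varepsilon = 0.01$ a single treated survivor in a low-propensity region
  carries a weight of 100, and in our recovery experiments the tree
  optimizer reliably found and exploited such records, prescribing REBOA to
  low-risk subgroups on noise; at $0.05$ the single-record influence is
  capped at 20 and recovery of the planted policy rose from 80% to 96%
  agreement. The bound is configurable.
* **`mtry` = half the covariate count.** The classification rule of thumb
  ($\sqrt p$) leaves the outcome forests over-smoothed toward each arm's
  marginal mortality when only a handful of the ~25 covariates carry the
  severity signal; the DR residual then divides exactly that smoothing bias
  by a small propensity. Raising `mtry` measurably removed the bias in the
  ground-truth comparisons.
* **Balanced class weights for the propensity forest** compensate the
  extreme treatment imbalance; at the prevalences used for testing their
  effect is minor.

## The policy tree

`grow_policy_tree()` minimizes

$$J(\text{tree}) = \frac 1 n \sum_i \Gamma_i(a(\text{leaf}(x_i)))
+ \texttt{cp} \cdot \#\text{splits}$$

by greedy recursive partitioning: each leaf prescribes the action with the
lower mean reward among its training rows (ties to no REBOA — the
conservative clinical default, and a determinism guarantee), and a split is
accepted only if it strictly lowers $J$ while both children keep
`min_samples_leaf` rows. Numeric candidate thresholds sit between each
selected type-1 quantile (an observed value) and the next distinct observed
value, so the induced partitions depend only on ranks and are invariant
under monotone transforms; categorical features use one-level-versus-rest
memberships; every numeric split carries an explicit side for missing
values, chosen during search by the objective. Candidate thresholds are
computed once per feature from the full training data and reused at every
node, which bounds runtime and makes the exhaustive oracle below search the
same space.

`local_search()` then refines the tree with strict-improvement moves:
(a) collapse a subtree to its best leaf, (b) re-optimize an internal
node's split holding both child subtrees fixed (the candidate minimizing
the routed cost is applied only if every leaf keeps `min_samples_leaf`;
otherwise the move is skipped), and (c) re-split a leaf where depth budget
remains. Because greedy growth is myopic at the root, the search also
restarts from alternative root splits, re-growing the children greedily:
all roots are tried when the number of candidates times the sample size
fits a fixed work budget, otherwise the top eight by single-split
objective. On small instances with depth at most 2 this restart phase is
exhaustive over roots, and greedy depth-1 children already scan every
split, so the optimizer provably attains the exhaustive optimum there —
the property the test suite checks against `brute_force_optimal_tree()`,
a guarded full enumeration (n ≤ 500, ≤ 4 features, ≤ 8 thresholds,
depth ≤ 2). The returned objective never exceeds the input objective.

`grid_search_hyperparams()` scores each hyperparameter setting by k-fold
cross-validated mean prescribed reward on the training half and breaks
ties toward simpler trees (smaller depth, then larger `cp`, then larger
leaves). The pipeline default grid crosses depth {2, 3}, minimum leaf
{50, 150}, and `cp` {0, 5e-5}.

## Off-policy evaluation

The cohort is split 50:50, stratified on $(T, y)$ so that neither half is
starved of the rare treated cases. The tree is learned on the training
half. `estimate_test_rewards()` then refits the entire nuisance stack —
imputer, propensity, outcome models, DR combination — from the test half
alone, and `evaluate_policy()` scores the tree against those rewards; a
`role` attribute set by `split_cohort()` guards against accidentally
passing the training half. Per record, `prescribed` is $\Gamma(a)$ under
the tree's action; `arr = original − prescribed`, reported overall, by
observed-treatment group, and per terminal leaf, with n-weighted leaf rows
reconstructing the overall row exactly (an identity the tests check to
1e-12).

Two conventions exist for the `original` (observed-assignment) risk, and
the choice matters:

* `"observed"` (default): the observed outcome $y$, so each group's
  original risk is its empirical mortality rate — the comparison usually
  published. It involves no inverse-propensity weight.
* `"dr"`: $\Gamma(T_i)$, the same estimator as `prescribed`. This makes a
  policy identical to the observed assignments evaluate to ARR exactly 0,
  which is attractive as an internal contrast. But restricted to the rare
  treated stratum, $\Gamma(1)$ divides outcome-model error by propensities
  near the clip bound; in our synthetic experiments the stratum mean sat
  at 0.18 against an observed treated mortality of 0.63, so group-level
  reports under this convention can be dominated by amplified model bias.
  It remains available for the self-comparison property and for users with
  well-calibrated nuisances.

In the leaf table (`format_leaf_table()`), probabilities are printed to 3
decimals and the ARR columns are computed from unrounded values and rounded
last, so a printed ARR can differ in its final digit from the subtraction
of the printed probabilities.

## The synthetic cohort generator

`generate_cohort()` draws encounters from a mechanism built around a latent
severity factor $z$: low blood pressure, low GCS, absent pulse, injuries,
and early transfusions all load on $z$, pulseless patients are mostly
unresponsive (GCS 3) with unmeasurable pressure, and the propensity of
treatment rises with the same observed severity features — reproducing the
confounding pattern (sicker patients treated more) the DR machinery must
undo. Treatment and outcome intercepts are calibrated by root-finding so
the configured marginal treatment prevalence (default 0.008, matching the
registry rate; boosted to 5–10% in most tests because sub-percent
prevalence needs very large n for stable nuisance fits) and baseline
mortality (default 0.21) hold exactly in expectation. Treatment shifts the
log-odds of death by `effect_benefit` (≤ 0, default −1.5) inside a
physiology-defined subgroup — by default absent pulse, GCS below 6, and SBP
below 68 mmHg, with an unobtainable SBP counting as qualifying since the
ground-truth rule must be total — and by `effect_harm` (≥ 0, default +0.8)
outside it. Covariate marginals (age around a median of 50, SBP median low
80s, binary injury prevalences of a few to twenty percent) are loosely
matched to published blunt-trauma hemorrhagic-shock cohorts.

Missingness is MAR by default: each covariate's masking probability is
modulated by severity through $2\,\mathrm{logit}^{-1}(z)$, whose mean over
a standard normal is exactly 1, so the configured marginal rate is
preserved; an MCAR option exists. Planted filter failures are drawn as
disjoint categories (each failing exactly one inclusion criterion), so the
attrition log's exclusion counts equal the planted counts exactly.

What the generator does **not** emulate: real registries have cluster
structure by facility, informative (MNAR) missingness, coding error in
procedure timestamps, secular trends over years, and treatment effects that
need not follow a crisp axis-aligned subgroup. Passing the recovery tests
therefore shows the pipeline works when its assumptions hold — ignorability
given the trauma-bay covariates, overlap, and a tree-representable effect
structure — not that those assumptions hold in any particular registry.

## Problem sizes and determinism

The test suite runs the estimator-unbiasedness check at n = 20,000 over 10
seeds (randomized treatment at 50% prevalence, including deliberate
single-model misspecifications), optimizer-versus-oracle on 30 random
instances of n = 200, policy recovery at n = 20,000 with 5% prevalence
scored on an independent draw, and the overuse scenario at n = 12,000
split 50:50 over 10 seeds with confounding at half strength — overlap is an
identifiability precondition, not a convenience — comparing the estimated
treated-group ARR with the ground truth within three Monte-Carlo standard
errors. The acceptance script runs the full pipeline at n = 20,000 and a
prevalence-calibration draw at n = 50,000. Every stage is deterministic
given its seed (forests run single-threaded with fixed seeds; all
tie-breaks are specified), and rerunning a pipeline configuration
reproduces byte-identical artifacts.

## Known limitations

Point estimation only: no confidence intervals on ARR or leaf effects.
Binary actions only. The optimizer is a strengthened greedy/local-search
procedure, not a global mixed-integer solver: beyond the regimes covered by
the oracle tests, optimality is bounded empirically, not guaranteed. Group-
and leaf-level evaluation under rare treatment remains sensitive to
outcome-model extrapolation wherever treated and untreated covariate
distributions barely overlap — no estimator escapes that — and the
generator's defaults deliberately keep enough overlap for the method to be
identifiable.
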