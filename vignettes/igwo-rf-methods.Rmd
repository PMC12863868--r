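---
title: "Grey-wolf-optimized random forests: models, calibration, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-wolf-optimized random forests: models, calibration, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`igwohealth` tunes random-forest classifiers for pediatric
health-status prediction with an improved grey wolf optimizer and
explains the tuned model with Shapley values. This vignette documents
the underlying models, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the numerical and
design choices made where more than one reasonable option existed.

## The optimizer

### Pack search

A population of `N` candidate vectors ("wolves") moves through the
normalized unit cube `[0,1]^d`. After every evaluation the three best
members become the leaders (alpha, beta, delta); every wolf is pulled
toward each leader through

\[
D_k = |C_k \cdot X_k - X|, \qquad X_k' = X_k - A_k \cdot D_k,
\qquad X(t+1) = \mathrm{repair}\!\left(\tfrac{1}{3}\sum_k X_k'\right),
\]

with coefficient vectors \(A = 2a\,r_1 - a\) and \(C = 2 r_2\), where
\(r_1, r_2 \sim U[0,1]\) are drawn independently per leader and
dimension. Working in the normalized cube rather than raw
hyperparameter units keeps these updates scale-free across a mixed
integer/continuous domain whose ranges differ by orders of magnitude;
decoding to classifier settings happens only at fitness evaluation.

### The three improvements

* **Dynamic weight.** \(a = 2 - 2t/T\) decays linearly from 2 to 0, so
  \(|A|\) can exceed 1 early (exploration: wolves overshoot leaders)
  and shrinks below 1 late (exploitation). The ablation variant
  "without dynamic weight" substitutes the constant \(a = 1\) — the
  schedule's mean — because an off-state is otherwise undefined and a
  constant \(a\) keeps \(A\) bounded. Two knobs reported alongside the
  protocol, a "dynamic weight factor" of 0.9 and an
  "exploration–exploitation balance factor" of 0.8, correspond to no
  equation of the update rules; they are stored on the config for
  fidelity but are inert.
* **Elite opposition-based learning.** For the top
  \(\lceil 0.10\,N \rceil\) members, an opposite candidate
  \(X_{new} = X_{best} + F (X_{worst} - X_{best})\), \(F \sim U[0,1]\),
  is generated. This interpolates toward the worst member rather than
  reflecting through the box center as classical opposition
  (\(1 - x\)) would; the rule is implemented as stated, with classical
  reflection available via `opposition_style = "reflect"`. An opposite
  replaces the current worst member only when strictly better (greedy
  acceptance). Opposition elites (top 10%) and retention elites (top
  20%) share a single ranking pass per iteration.
* **Elite retention.** The top \(\lceil 0.20\,N \rceil\) of a
  generation is guaranteed survival; remaining slots go to the best
  updated candidates. Independently of retention, a best-so-far
  archive records the optimum, so the reported best fitness is
  monotone under every component ablation. The "without elite
  retention" variant keeps the archive (it is bookkeeping, not search
  behaviour) but stops injecting elites into the next generation.

### Termination

The search stops at the iteration cap `T` (default 100), or early when
the best-fitness series changes by less than `convergence_tol`
(default `1e-5`) for `patience` consecutive steps. The exported
`check_termination()` contract uses a single-step plateau
(`patience = 1`); the optimizers default to `patience = 5` because the
best-so-far series is monotone and frequently flat for one step long
before convergence — a one-step rule would stop most runs at the
second iteration. Runs that must honour a fixed evaluation budget
(for example the grid-oracle equivalence checks, which compare a
270-evaluation search against exhaustive enumeration) set
`patience = T` so the plateau rule never cuts the budget; this is a
property of those fixed-budget experiments, chosen when they were
designed.

Leader and argmax ties are broken by the lower member index, making
seeded runs bit-reproducible. Each run splits its master seed into
named streams (`init`, `updates`, `opposition`, `levy`), so switching
one component off does not shift the draws any other component
consumes — ablation variants differ only where they should.

### Baselines and feature selection

`pso_optimize()` is canonical global-best PSO with inertia weight
\(\omega = 0.7\) and accelerations \(c_1 = c_2 = 1.5\) (the protocol
states only \(\omega\); the accelerations are the common textbook
values). `random_search()` draws uniform candidates with a row-major
stream so a smaller budget's draws are a prefix of a larger one's,
making best-fitness monotone in the budget. `select_features()` runs
the same pack search over `[0,1]^p` with positions thresholded at 0.5
into feature masks; initialization is perturbed by Mantegna Levy
flights (stability index 1.5, step scale 0.1 of the cube) and each
wolf's move length is rescaled by a Cauchy mutation whose scale decays
as \(1 - t/T\), clipped to \([0, 2]\) — the named mechanisms carry no
stated parameters, so these are the package's choices. A mask that
thresholds to all zeros is repaired by activating one uniformly random
feature.

## The fitness

\[
F(\theta) = \sum_{k=1}^{K} \mathrm{Accuracy}_k - \lambda\,
\mathrm{Complexity}(\theta), \qquad K = 5,\ \lambda = 0.01,
\]

a **sum** over stratified folds, as stated, not a mean
(`mean_mode = TRUE` averages instead, for comparison with conventions
that do). The complexity term's functional form is the package's
choice: `n_trees/200 + max_depth/15`, the bound-normalized sum —
bounded on (0, 2], monotone in both drivers of model size, matching
the stated intent of penalizing oversized ensembles and deep trees. A
second printed coefficient, \(\alpha = 0.001\), attaches to no term
and is stored inert. Folds are stratified and seeded (default seed
42); a class with fewer members than folds raises a stratification
error rather than silently producing single-class folds.

The classifier contract is an ensemble of depth-capped trees on
bootstrap resamples with per-split feature subsampling at rate
`p_features` and minimum leaf size 5; prediction is majority vote and
the class-1 score is the fraction of trees voting 1. Tree growth is
delegated to `ranger` (single-threaded, seeded); `min.node.size`
plays the minimum-leaf-size role. The minimum leaf size is a fixed
setting rather than a searched dimension: the search domain defines
exactly three dimensions, while the reported leaf size of 5 appears
among the tuned values — treating it as fixed reconciles the two.
Whether `p_features` and a reported "feature subset size = 8" are the
same quantity is unstated; the package exposes the ratio, and
`8/24 ≈ 0.33` is the count conversion on the 24-feature cohort.

## The synthetic cohort generator

The generator emulates the composition of a three-hospital pediatric
examination dataset so the pipeline can be exercised without private
data: 1852 children, exactly 1402 healthy and 450 subhealthy (75.7% /
24.3%), subgroup sizes 187 (obesity), 93 (lipid abnormality), 86
(respiratory allergy), 84 (hypertension), 846 males / 1006 females,
ages on [3, 12] with mean 7.2, and 3.2% of feature cells missing
completely at random. Counts are assigned **exactly**, not sampled,
so the printed cohort arithmetic reproduces bit-exactly; missingness
uses an exact-count rule (`round(rate · n · 24)` cells drawn without
replacement, never the label). Age is drawn from a truncated normal
whose pre-truncation mean is solved numerically so the
post-truncation mean equals 7.2 (the SD lands slightly below 2.3 and
is reported, not forced).

Twenty feature columns follow the study instrument's three domains;
the instrument names 24 features but lists 20, so four documented
synthetic-only placeholders (sleep quality score, BMI-for-age
percentile, household income proxy, indoor humidity) complete the
layout. Physiological features are age-dependent normals; weight is
derived as `bmi · height_m²`, so the BMI identity holds exactly on
complete rows. Subgroups are planted as mean shifts — obesity pushes
BMI above the 19.8 kg/m² anchor, lipid abnormality moves the lipid
panel, respiratory allergy raises PM2.5 and traffic exposure,
hypertension raises blood pressure. Class effects on the behavioral
and environmental features are calibrated so that **BMI, daily
exercise time and PM2.5 exposure are the three strongest signals, in
that order** (standardized shifts ≈ 1.7, 1.2, 1.1), which makes the
attribution ranking a testable calibration property. Dietary habits
(3 levels) and smoking exposure (2 levels) are generated categorical
to exercise one-hot encoding. Effect sizes are package constants in
`generate_cohort()`; any recalibration must preserve the
recoverability properties (held-out accuracy ≥ 0.85 at config
(150, 12, 0.33); BMI first by mean |SHAP| in ≥ 4/5 seeds).

What the generator does **not** emulate: the real data's joint
correlation structure beyond these planted effects, non-MCAR
missingness, longitudinal trajectories, measurement error models, or
site effects. Passing tests therefore demonstrate that the pipeline
recovers known planted structure under realistic size, imbalance and
missingness — not that it reproduces the clinical dataset's numbers.

## Preprocessing

The chain is chained-equations imputation → Tukey-fence winsorization
→ stratified split → min-max scaling → one-hot encoding.

* **Imputation** initializes missing cells with the column mean
  (mode for categoricals), then sweeps each incomplete column five
  times, regressing it linearly on all other columns (categoricals:
  nearest-centroid assignment on the standardized numeric profile).
  Conditionals are deliberately lightweight and deterministic — the
  method is named upstream, its conditionals are not — so no seed is
  needed. Imputation and winsorization run on the full table before
  splitting, matching the upstream order of operations; scaling
  parameters are then fit on the training rows only and applied to
  test (the standard leakage guard, adopted where the upstream
  protocol is silent). The listed chain would also admit encoding
  before splitting; since the categorical level sets are fixed and
  known, the two orders produce identical encodings.
* **Winsorization** detects outliers with Tukey fences
  (`Q1 − 1.5·IQR`, `Q3 + 1.5·IQR`) but caps at the column's 1st/99th
  percentiles — exactly the stated (unusual) combination; capping at
  the fences themselves is available via `cap_at_fences = TRUE`.
  Percentiles use linear interpolation between order statistics
  (type 7), the estimator being unstated upstream. On
  normally-distributed columns the operation is idempotent because
  the 99th percentile sits inside the upper fence.
* **Splitting** apportions `round(0.7·n)` training rows across
  classes by largest remainder, so per-class proportions differ from
  the cohort's by less than one row: 1402/450 at 70% gives exactly
  981 + 315 = 1296 training and 556 test rows.

## Shapley attribution

The value function is the interventional (marginal) expectation: for
a sample `x` and subset `S`, `f(S)` averages the model score over
background rows with the features in `S` taken from `x`. The exact
enumerator applies the classical weights `|S|!(d−|S|−1)!/d!` over all
`2^d` subsets (guarded at d ≤ 15) and satisfies efficiency —
`φ₀ + Σφᵢ` equals the model score — to numerical precision. The
permutation-sampling estimator averages marginal contributions along
random orderings, is unbiased for the exact values, and batches all
composites of a sample into a single model call for speed. For the
24-feature cohort, sampled mode is the default; exact mode serves as
the oracle on small models. Contributions of one-hot indicator
columns are summed back to their source feature
(`collapse_encoded_phi()`) before ranking; importance is the mean
|φ| over samples, ties broken lexicographically.

The pairwise interaction index is the weighted second difference
`f(S∪{i,j}) − f(S∪{i}) − f(S∪{j}) + f(S)` with weights
`|S|!(d−|S|−2)!/(d−1)!`, i.e. the symmetric pairwise interaction with
both ordered halves combined, so a pure product model `x₁x₂`
evaluated at (1,1) against background (0,0) has interaction 1. A
claimed identity decomposing the interaction as
`φᵢφⱼ + E[∂²f]` is not used: it is dimensionally inconsistent
(products of contributions do not share units with contributions) and
matches no axiomatic definition; the standard index replaces it as a
deliberate substitution.

## Experiment harness

`run_tuning()` chains simulate/load → preprocess → IGWO tuning via the
CV fitness → final forest at the leader's configuration → test
metrics; repetitions re-run the optimizer under derived seeds on the
same cohort and splits and report mean ± SD (the upstream protocol
does not state whether its SDs are across folds or runs, so per-fold
accuracies are also exposed via `per_fold_accuracy`-based paired
tests). `run_ablation()` freezes one cohort and split and varies only
the component flags; `run_comparison()` adds a PSO-tuned forest, a
fixed-configuration forest (100 trees, depth 10, sqrt features), and
optionally logistic regression and an RBF SVM, with paired fold-wise
t statistics under Bonferroni adjustment. Every result embeds its
resolved configuration and seeds, so re-running from the embedded
config reproduces it bit-exactly.

## Problem sizes used by the test and acceptance suites

The package defaults are the full budgets (population 30, 100
iterations, the n = 1852 cohort, 5 folds). The shipped test suite
exercises unit behaviour on down-scaled cohorts (n = 250–400) and
reduced budgets (population 5–15, 3–20 iterations), and the
end-to-end checks use the `fast` budgets (population 8, 10
iterations) on the full cohort with 32-permutation, 15-background
attributions over 30 test samples — sizes chosen so the whole suite
runs on a single CPU in minutes while keeping every statistical
property it asserts comfortably away from its threshold.

## Known limitations

* The synthetic generator supports calibration properties (signal
  recovery, importance ordering), not reproduction of any clinical
  dataset's metric values; headline numbers on synthetic cohorts
  should not be read as clinical performance.
* The dynamic-weight schedule is algebraically identical to the
  standard linear decrease of the base algorithm; what distinguishes
  the "improved" schedule from the baseline is ambiguous upstream,
  and the package implements the printed formula with the constant
  mean as its off-state.
* Chained-equations conditionals are linear/nearest-centroid by
  design; strongly non-linear missingness mechanisms are out of
  scope, as are multiple-imputation pooling and non-MCAR sensitivity
  analyses.
* Exact Shapley enumeration is exponential and guarded at 15
  features (12 for interactions); beyond that, only the sampled
  estimator is available.
* Fitness evaluation is sequential; parallel evaluation and other
  metaheuristics (GA, DE) are out of scope.
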