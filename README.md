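# igwohealth

Grey-wolf-optimized random forests for pediatric health risk
stratification.

## The problem

Pediatric health screening increasingly pools physical-examination
indicators (height, weight, BMI, blood pressure, lipids, ...),
environmental exposures (PM2.5, noise, traffic density, green
coverage) and behavioral habits (exercise, sleep, screen time, diet)
into a single at-risk / healthy classification. Random forests handle
this kind of mixed, moderately sized tabular data well, but their
performance hinges on hyperparameters — ensemble size, tree depth, the
per-split feature sampling rate — that are usually hand-tuned.
`igwohealth` tunes them with an **improved grey wolf optimizer
(IGWO)** and explains the resulting model with **Shapley values**, so
the pipeline is both accurate and auditable. Because clinical
examination records are private, the package ships a calibrated
synthetic cohort generator that reproduces the statistical structure
of a multi-hospital pediatric dataset (n = 1852, 75.7% healthy / 24.3%
subhealthy, four diagnostic subgroups, 3.2% missing entries), making
every stage testable end to end.

## The method

The grey wolf optimizer moves a pack of N candidate vectors through
the normalized search cube, steered by the three best solutions
(alpha, beta, delta). For each wolf and each leader k:

    D_k = | C_k · X_k − X |,    X_k' = X_k − A_k · D_k,
    X(t+1) = repair( (X_α' + X_β' + X_δ') / 3 )

with coefficient vectors `A = 2a·r1 − a`, `C = 2·r2`, `r1, r2 ~
U[0,1]`. Three improvements define the IGWO variant:

1. **dynamic weight** — the inertia weight decays linearly,
   `a = 2 − 2t/T`, trading early exploration (|A| > 1) for late
   exploitation;
2. **elite opposition-based learning** — for the top 10% of the pack,
   opposite candidates `X_new = X_best + F·(X_worst − X_best)`,
   `F ~ U[0,1]`, are injected when they beat the current worst member;
3. **elite retention** — the top 20% of each generation survives into
   the next unconditionally.

Candidates decode into forest settings `n_trees ∈ [50, 200]`,
`max_depth ∈ [5, 15]`, `p_features ∈ (0.3, 0.8]` and are scored with a
cross-validated, complexity-penalized fitness

    F(θ) = Σ_{k=1..5} Accuracy_k − λ · Complexity(θ),   λ = 0.01,

where `Complexity(θ) = n_trees/200 + max_depth/15`. The tuned model is
interpreted with exact (subset-enumeration) or permutation-sampled
Shapley values, plus a pairwise interaction index. PSO and uniform
random search are available as baselines, and an experiment harness
runs component ablations and model comparisons on identical splits.

## Worked example

```r
library(igwohealth)

# simulate a down-scaled cohort and preprocess it
spec <- scaled_cohort_spec(400, seed = 7)
cohort <- generate_cohort(spec)
print(cohort)
#> Synthetic cohort: 400 children, 303 healthy / 97 subhealthy (75.8% healthy)
#>   24 features, 307 masked entries (3.20%)

prep <- preprocess_cohort(cohort)   # impute, winsorize, split, scale, encode
prep$report$split_sizes
#> train  test
#>   280   120

# tune the forest with IGWO on the training split
space <- default_space()
fc <- fitness_config()
fit_fn <- function(v) cv_fitness(decode(space, v), prep$train$X, prep$train$y, fc)
opt <- igwo_optimize(fit_fn, space,
                     optimizer_config(population_size = 10, max_iterations = 10,
                                      seed = 7))
print(opt)
#> IGWO result: best fitness 4.669769 after 10 iterations (120 evaluations)
print(opt$best_config)
#> RF config: n_trees = 91, max_depth = 12, p_features = 0.7139, min_samples_leaf = 5

# final model and held-out metrics
model <- train_rf(opt$best_config, prep$train$X, prep$train$y, seed = fc$seed)
str(evaluate_classifier(model, prep$test$X, prep$test$y))
#> List of 6
#>  $ accuracy : num 0.925
#>  $ precision: num 0.812
#>  $ recall   : num 0.897
#>  $ f1       : num 0.852
#>  $ auc_roc  : num 0.971
#>  $ kappa    : num 0.802

# Shapley attribution of the tuned model
ex <- explain_tuned_model(prep, opt$best_config, n_explain = 25,
                          n_background = 15, n_permutations = 32, seed = 7)
head(rank_importance(collapse_encoded_phi(ex$phi)), 5)
#>             feature importance
#> 1               bmi 0.13548352
#> 2     exercise_time 0.12508791
#> 3 total_cholesterol 0.08409341
#> 4     pm25_exposure 0.06657601
#> 5     triglycerides 0.03664194
```

The best fitness 4.67 is a sum of five fold accuracies (≈ 0.935 each)
minus the complexity penalty. On the held-out 30%, the tuned forest
reaches 92.5% accuracy against a 75.8% majority-class floor, and the
attribution recovers the cohort's planted risk drivers: BMI first,
daily exercise time second.

A thin command-line wrapper over the same functions lives at
`inst/cli/igwohealth.R`:

```sh
Rscript inst/cli/igwohealth.R simulate --seed 7 --out out/
Rscript inst/cli/igwohealth.R tune --fast --seed 7 --out out/
Rscript inst/cli/igwohealth.R ablate --fast --seed 7 --out out/
```

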