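# Small cohorts and reduced budgets keep the harness tests quick; the
# full-budget behaviour is exercised by the acceptance suite.

small_cfg <- function(seed = 3, repetitions = 1, n = 250) {
  experiment_config(
    cohort = tiny_cohort_spec(seed = seed, n = n),
    optimizer = optimizer_config(population_size = 5, max_iterations = 3,
                                 seed = seed),
    repetitions = repetitions,
    seed = seed
  )
}

test_that("experiment configs validate variants and parse YAML", {
  expect_error(experiment_config(variants = c("full", "bogus")), "bogus")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "cohort:",
    "  n: 120",
    "  class_counts: {healthy: 91, subhealthy: 29}",
    "  subgroup_counts: {obesity: 12, lipid: 6, respiratory: 6, hypertension: 5}",
    "  sex_counts: {male: 55, female: 65}",
    "optimizer:",
    "  population_size: 4",
    "  max_iterations: 2",
    "fitness:",
    "  lambda: 0.02",
    "repetitions: 2",
    "seed: 9",
    "fast: false"
  ), path)
  cfg <- experiment_config_from_yaml(path)
  expect_equal(cfg$cohort$n, 120L)
  expect_equal(cfg$optimizer$population_size, 4L)
  expect_equal(cfg$fitness$lambda, 0.02)
  expect_equal(cfg$repetitions, 2L)
})

test_that("tuning runs end-to-end, reports SD 0 for one repetition, and reproduces", {
  cfg <- small_cfg(seed = 5)
  r1 <- run_tuning(cfg)
  expect_s3_class(r1$best_config, "rf_config")
  expect_true(all(r1$metrics_sd == 0))
  expect_true(r1$metrics_mean[["accuracy"]] > 0.5)
  expect_equal(nrow(r1$per_rep), 1)
  r2 <- run_tuning(cfg)
  expect_identical(r1$per_rep, r2$per_rep)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$seeds, r2$seeds)
})

test_that("ablation produces one aligned row per variant on shared splits", {
  cfg <- small_cfg(seed = 7, repetitions = 1)
  ab <- run_ablation(cfg)
  expect_equal(nrow(ab$table), 4)
  expect_setequal(ab$table$variant,
                  c("full", "no_dynamic_weight", "no_elite_opposition",
                    "no_elite_retention"))
  expect_true(all(ab$table$accuracy_sd >= 0))
  # every variant runs against the identical frozen cohort and split seed
  splits <- lapply(ab$results, function(r) {
    stratified_split(generate_cohort(tiny_cohort_spec(seed = 7, n = 250)),
                     cfg$train_fraction, seed = cfg$fitness$seed)
  })
  expect_identical(splits[[1]], splits[[4]])
  expect_identical(ab$split, splits[[1]])
  expect_error(run_ablation(experiment_config(variants = "full")), "2 variants")
})

test_that("the full variant is competitive on a multimodal landscape (reported)", {
  sp <- hp_space(list(
    list(name = "u", kind = "continuous", lower = 0, upper = 1),
    list(name = "v", kind = "continuous", lower = 0, upper = 1)
  ))
  best_of <- function(components, seed) {
    igwo_optimize(rastrigin_fitness, sp,
                  optimizer_config(population_size = 12, max_iterations = 15,
                                   seed = seed, components = components))$best_fitness
  }
  variants <- c("full", "no_dynamic_weight", "no_elite_opposition",
                "no_elite_retention")
  means <- vapply(variants, function(v) {
    comp <- igwohealth:::variant_components(v)
    mean(vapply(1:5, function(s) best_of(comp, s), numeric(1)))
  }, numeric(1))
  behind <- names(means)[means > means[["full"]] + 1e-9]
  if (length(behind)) {
    message("full variant behind: ", paste(behind, collapse = ", "),
            " (soft ablation check)")
  }
  expect_length(means, 4)
})

test_that("model comparison covers the requested rows with paired statistics", {
  cfg <- small_cfg(seed = 11, n = 250)
  cmp <- run_comparison(cfg)
  expect_setequal(cmp$table$model, c("igwo_rf", "pso_rf", "standard_rf"))
  expect_named(cmp$paired_tests, c("pso_rf", "standard_rf"))
  for (pt in cmp$paired_tests) {
    expect_true(is.finite(pt$p_bonferroni) || pt$p_bonferroni %in% c(0, 1))
    expect_gte(pt$p_bonferroni, pt$p - 1e-12)
  }
  # the fixed-config baseline needs no optimizer budget
  expect_equal(cmp$results$standard_rf$best_config$n_trees, 100L)
  expect_equal(cmp$results$standard_rf$best_config$max_depth, 10L)
  if (cmp$table$accuracy[cmp$table$model == "igwo_rf"] <
      cmp$table$accuracy[cmp$table$model == "standard_rf"]) {
    message("tuned forest behind the fixed baseline at this budget (soft check)")
  }
})

test_that("repetition aggregation reports mean and SD over reruns", {
  cfg <- small_cfg(seed = 13, repetitions = 2)
  r <- run_tuning(cfg)
  expect_equal(nrow(r$per_rep), 2)
  expect_equal(unname(r$metrics_mean[["accuracy"]]),
               mean(r$per_rep$accuracy))
  expect_equal(unname(r$metrics_sd[["accuracy"]]), sd(r$per_rep$accuracy))
  expect_length(unique(r$seeds), 2)
})

test_that("explained tuned models rank the planted drivers of risk", {
  co <- generate_cohort(tiny_cohort_spec(seed = 17, n = 300))
  prep <- preprocess_cohort(co)
  ex <- explain_tuned_model(prep, rf_config(80, 10, 0.4), n_explain = 12,
                            n_background = 10, n_permutations = 24, seed = 17)
  expect_equal(nrow(ex$phi), 12)
  phi24 <- collapse_encoded_phi(ex$phi)
  expect_equal(sort(colnames(phi24)), sort(cohort_feature_names()))
  imp <- rank_importance(phi24)
  expect_true("bmi" %in% head(imp$feature, 5))
})

test_that("paired fold test handles identical and shifted inputs", {
  z <- paired_fold_test(c(0.9, 0.8, 0.85), c(0.9, 0.8, 0.85))
  expect_equal(z$t, 0)
  expect_equal(z$p_bonferroni, 1)
  shifted <- paired_fold_test(c(0.9, 0.92, 0.91, 0.93), c(0.8, 0.82, 0.81, 0.83),
                              n_comparisons = 3)
  expect_gt(shifted$t, 0)
  expect_lte(shifted$p_bonferroni, 1)
  expect_equal(shifted$mean_diff, 0.1)
})
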