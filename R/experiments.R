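#' Experiment configuration
#'
#' Bundles everything an end-to-end run needs: the cohort source (a
#' [cohort_spec()] or a CSV path written by [write_cohort()]), the
#' optimizer and fitness settings, the ablation variant set, the number
#' of repeated runs, and the master seed. `fast = TRUE` switches the
#' optimizer to desk-scale budgets (population 8, 10 iterations) for
#' quick runs; the defaults are the full budgets (population 30, 100
#' iterations).
#'
#' @param cohort a `cohort_spec` or path to a cohort CSV.
#' @param optimizer an [optimizer_config()].
#' @param fitness a [fitness_config()].
#' @param variants ablation variant names, drawn from `full`,
#'   `no_dynamic_weight`, `no_elite_opposition`, `no_elite_retention`.
#' @param repetitions repeated tuning runs per variant/model (>= 1).
#' @param train_fraction training split fraction, default 0.7.
#' @param seed master seed.
#' @param fast use reduced search budgets.
#' @param out_dir optional directory for artifacts (traces, tables).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              optimizer = optimizer_config(),
                              fitness = fitness_config(),
                              variants = c("full", "no_dynamic_weight",
                                           "no_elite_opposition",
                                           "no_elite_retention"),
                              repetitions = 1, train_fraction = 0.7,
                              seed = 1, fast = FALSE, out_dir = NULL) {
  stopifnot(repetitions >= 1)
  known <- c("full", "no_dynamic_weight", "no_elite_opposition",
             "no_elite_retention")
  bad <- setdiff(variants, known)
  if (length(bad)) {
    stop("unknown variant name(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  }
  structure(
    list(cohort = cohort, optimizer = optimizer, fitness = fitness,
         variants = variants, repetitions = as.integer(repetitions),
         train_fraction = train_fraction, seed = as.integer(seed),
         fast = isTRUE(fast), out_dir = out_dir),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' Recognized top-level keys: `cohort` (either `csv: <path>` or
#' [cohort_spec()] fields), `optimizer`, `fitness` (fields of the
#' respective constructors), `variants`, `repetitions`,
#' `train_fraction`, `seed`, `fast`, `out_dir`.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
experiment_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort$csv)) {
    y$cohort$csv
  } else if (!is.null(y$cohort)) {
    co <- y$cohort
    # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it back
    names(co)[names(co) %in% c("FALSE", "F")] <- "n"
    for (k in c("class_counts", "subgroup_counts", "sex_counts", "age_range")) {
      if (!is.null(co[[k]])) co[[k]] <- unlist(co[[k]])
    }
    do.call(cohort_spec, co)
  } else {
    cohort_spec()
  }
  args <- list(cohort = cohort)
  if (!is.null(y$optimizer)) args$optimizer <- do.call(optimizer_config, y$optimizer)
  if (!is.null(y$fitness)) args$fitness <- do.call(fitness_config, y$fitness)
  for (k in c("variants", "repetitions", "train_fraction", "seed", "fast",
              "out_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(experiment_config, args)
}

variant_components <- function(variant) {
  switch(variant,
    full = c(dynamic_weight = TRUE, elite_opposition = TRUE, elite_retention = TRUE),
    no_dynamic_weight = c(dynamic_weight = FALSE, elite_opposition = TRUE,
                          elite_retention = TRUE),
    no_elite_opposition = c(dynamic_weight = TRUE, elite_opposition = FALSE,
                            elite_retention = TRUE),
    no_elite_retention = c(dynamic_weight = TRUE, elite_opposition = TRUE,
                           elite_retention = FALSE),
    stop("unknown variant: ", variant)
  )
}

resolve_cohort <- function(cohort) {
  if (inherits(cohort, "cohort_table")) return(cohort)
  if (inherits(cohort, "cohort_spec")) return(generate_cohort(cohort))
  if (is.character(cohort)) return(read_cohort(cohort))
  stop("cohort must be a cohort_spec, cohort_table, or CSV path")
}

resolve_optimizer <- function(cfg, components = NULL, seed = NULL) {
  oc <- cfg$optimizer
  if (cfg$fast) {
    oc$population_size <- 8L
    oc$max_iterations <- 10L
  }
  if (!is.null(components)) oc$components[names(components)] <- components
  if (!is.null(seed)) oc$seed <- as.integer(seed)
  oc
}

rep_seeds_for <- function(seed, repetitions) {
  s <- rng_stream(seed)
  stream_do(s, function() sample.int(.Machine$integer.max, repetitions))
}

metric_row <- function(m) {
  data.frame(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
             f1 = m$f1, auc_roc = m$auc_roc, kappa = m$kappa)
}

aggregate_metrics <- function(per_rep) {
  mean_row <- colMeans(per_rep)
  sd_row <- if (nrow(per_rep) > 1) apply(per_rep, 2, stats::sd) else
    stats::setNames(rep(0, ncol(per_rep)), colnames(per_rep))
  list(mean = mean_row, sd = sd_row)
}

tune_once <- function(prep, space, oc, fc, method = c("igwo", "pso")) {
  method <- match.arg(method)
  fitness_fn <- function(v) {
    cv_fitness(decode(space, v), prep$train$X, prep$train$y, fc, space)
  }
  if (method == "igwo") {
    igwo_optimize(fitness_fn, space, oc)
  } else {
    pso_optimize(fitness_fn, space, oc)
  }
}

finalize_and_score <- function(config, prep, fc) {
  model <- train_rf(config, prep$train$X, prep$train$y, seed = fc$seed)
  list(model = model,
       metrics = evaluate_classifier(model, prep$test$X, prep$test$y))
}

#' Tune, finalize and evaluate on a cohort
#'
#' The full workflow: resolve the cohort (simulate or load), preprocess
#' with train-fitted transforms, tune the forest's hyperparameters with
#' IGWO on the training split via the cross-validated penalized fitness,
#' train the final forest at the leader's configuration, and report the
#' test-set metric set. With `repetitions > 1` the optimizer is re-run
#' under derived seeds on the same cohort and splits, and metrics are
#' aggregated as mean and SD.
#'
#' @param cfg an [experiment_config()].
#' @param components optional component-flag override (used by
#'   [run_ablation()]).
#' @return Object of class `experiment_result`: `metrics_mean`,
#'   `metrics_sd`, `per_rep` (one metric row per repetition),
#'   `best_config` (from the first repetition), `traces`, `seeds`, and
#'   the resolved `config` for audit reproduction.
#' @export
run_tuning <- function(cfg, components = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  cohort <- resolve_cohort(cfg$cohort)
  prep <- preprocess_cohort(cohort, cfg$train_fraction, seed = cfg$fitness$seed)
  space <- default_space()
  seeds <- rep_seeds_for(cfg$seed, cfg$repetitions)

  per_rep <- NULL
  traces <- list()
  best_config <- NULL
  for (r in seq_len(cfg$repetitions)) {
    oc <- resolve_optimizer(cfg, components, seed = seeds[r])
    opt <- tune_once(prep, space, oc, cfg$fitness, "igwo")
    fin <- finalize_and_score(opt$best_config, prep, cfg$fitness)
    per_rep <- rbind(per_rep, metric_row(fin$metrics))
    traces[[r]] <- opt$trace
    if (r == 1) best_config <- opt$best_config
  }
  agg <- aggregate_metrics(per_rep)
  structure(
    list(model = "igwo_rf", metrics_mean = agg$mean, metrics_sd = agg$sd,
         per_rep = per_rep, best_config = best_config, traces = traces,
         seeds = seeds, config = cfg),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment result (", x$model, "), ", nrow(x$per_rep),
      " repetition(s)\n", sep = "")
  m <- rbind(mean = x$metrics_mean, sd = x$metrics_sd)
  print(round(m, 4))
  invisible(x)
}

#' Component ablation study
#'
#' Runs one tuning pass per requested variant with a shared cohort,
#' shared train/test split and aligned repetition seeds, so variants
#' differ only in the component flags. Returns per-variant results and
#' an ablation table (one row per variant).
#'
#' @param cfg an [experiment_config()] with at least 2 variants.
#' @return List of class `ablation_result` with `results` (named list
#'   of `experiment_result`), `table` (data frame of mean/SD metrics per
#'   variant), and `split` (the shared row indices).
#' @export
run_ablation <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (length(cfg$variants) < 2) stop("ablation needs at least 2 variants")
  cohort <- resolve_cohort(cfg$cohort)
  cfg$cohort <- cohort  # freeze: every variant sees the same table
  results <- list()
  for (v in cfg$variants) {
    results[[v]] <- run_tuning(cfg, components = variant_components(v))
    results[[v]]$model <- v
  }
  tab <- do.call(rbind, lapply(names(results), function(v) {
    r <- results[[v]]
    data.frame(variant = v,
               accuracy = r$metrics_mean[["accuracy"]],
               accuracy_sd = r$metrics_sd[["accuracy"]],
               f1 = r$metrics_mean[["f1"]],
               f1_sd = r$metrics_sd[["f1"]],
               auc_roc = r$metrics_mean[["auc_roc"]],
               auc_roc_sd = r$metrics_sd[["auc_roc"]])
  }))
  split <- stratified_split(cohort$label, cfg$train_fraction,
                            seed = cfg$fitness$seed)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(cfg$out_dir, "ablation.csv"),
                     row.names = FALSE)
  }
  structure(list(results = results, table = tab, split = split, config = cfg),
            class = "ablation_result")
}

#' Paired fold-wise comparison of two accuracy vectors
#'
#' Paired t statistic on per-fold (or per-seed) metric differences, with
#' Bonferroni adjustment across the supplied number of comparisons.
#'
#' @param a,b equal-length numeric vectors of paired metrics.
#' @param n_comparisons number of simultaneous comparisons for the
#'   Bonferroni correction, default 1.
#' @return List with `t`, `p`, `p_bonferroni`, `mean_diff`.
#' @export
paired_fold_test <- function(a, b, n_comparisons = 1) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a - b) < 1e-12) {
    zero <- abs(mean(a - b)) < 1e-12
    return(list(t = if (zero) 0 else Inf * sign(mean(a - b)),
                p = if (zero) 1 else 0,
                p_bonferroni = if (zero) 1 else 0,
                mean_diff = mean(a - b)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       p_bonferroni = min(1, tt$p.value * n_comparisons),
       mean_diff = mean(a - b))
}

per_fold_accuracy <- function(config, X, y, fc) {
  fold <- stratified_folds(y, fc$folds, fc$seed)
  vapply(seq_len(fc$folds), function(k) {
    tr <- fold != k
    fit <- train_rf(config, X[tr, , drop = FALSE], y[tr], seed = fc$seed)
    mean(predict(fit, X[!tr, , drop = FALSE], type = "class") == y[!tr])
  }, numeric(1))
}

#' Model comparison on identical splits
#'
#' Compares the IGWO-tuned forest against a PSO-tuned forest and a
#' fixed-configuration forest (100 trees, depth 10, sqrt feature
#' sampling) on the same cohort, splits and seeds. Optionally adds
#' plain logistic regression and an RBF support vector machine as
#' conventional baselines. Reports test metrics per model plus paired
#' fold-wise t statistics (IGWO vs each competitor) with Bonferroni
#' adjustment.
#'
#' @param cfg an [experiment_config()].
#' @param include_baselines also fit logistic regression and (if the
#'   `e1071` package is installed) an SVM, default FALSE.
#' @return List of class `comparison_result` with `table`, `results`,
#'   and `paired_tests`.
#' @export
run_comparison <- function(cfg, include_baselines = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  cohort <- resolve_cohort(cfg$cohort)
  prep <- preprocess_cohort(cohort, cfg$train_fraction, seed = cfg$fitness$seed)
  space <- default_space()
  seeds <- rep_seeds_for(cfg$seed, cfg$repetitions)
  fc <- cfg$fitness

  run_model <- function(name, get_config) {
    per_rep <- NULL
    first_config <- NULL
    for (r in seq_len(cfg$repetitions)) {
      config <- get_config(seeds[r])
      fin <- finalize_and_score(config, prep, fc)
      per_rep <- rbind(per_rep, metric_row(fin$metrics))
      if (r == 1) first_config <- config
    }
    agg <- aggregate_metrics(per_rep)
    structure(
      list(model = name, metrics_mean = agg$mean, metrics_sd = agg$sd,
           per_rep = per_rep, best_config = first_config, seeds = seeds,
           config = cfg),
      class = "experiment_result"
    )
  }

  p <- ncol(prep$train$X)
  fixed_cfg <- rf_config(100, 10, sqrt(p) / p, check = FALSE)
  results <- list(
    igwo_rf = run_model("igwo_rf", function(s) {
      tune_once(prep, space, resolve_optimizer(cfg, seed = s), fc, "igwo")$best_config
    }),
    pso_rf = run_model("pso_rf", function(s) {
      tune_once(prep, space, resolve_optimizer(cfg, seed = s), fc, "pso")$best_config
    }),
    standard_rf = run_model("standard_rf", function(s) fixed_cfg)
  )

  baseline_rows <- list()
  if (include_baselines) {
    glm_fit <- stats::glm(y ~ ., family = stats::binomial(),
                          data = cbind(y = prep$train$y, prep$train$X))
    glm_score <- stats::predict(glm_fit, newdata = prep$test$X, type = "response")
    glm_pred <- as.integer(glm_score > 0.5)
    cm <- compute_metrics(confusion_counts(prep$test$y, glm_pred))
    cm$auc_roc <- auc_roc(prep$test$y, glm_score)
    cm$kappa <- cohen_kappa(confusion_counts(prep$test$y, glm_pred))
    baseline_rows$logistic <- cm
    if (requireNamespace("e1071", quietly = TRUE)) {
      sv <- e1071::svm(x = as.matrix(prep$train$X),
                       y = factor(prep$train$y, levels = c(0, 1)),
                       kernel = "radial", cost = 1, probability = TRUE)
      pr <- stats::predict(sv, as.matrix(prep$test$X), probability = TRUE)
      sc <- attr(pr, "probabilities")[, "1"]
      pd <- as.integer(as.character(pr))
      cm <- compute_metrics(confusion_counts(prep$test$y, pd))
      cm$auc_roc <- auc_roc(prep$test$y, sc)
      cm$kappa <- cohen_kappa(confusion_counts(prep$test$y, pd))
      baseline_rows$svm <- cm
    }
  }

  fold_acc <- lapply(results, function(r) {
    per_fold_accuracy(r$best_config, prep$train$X, prep$train$y, fc)
  })
  others <- setdiff(names(fold_acc), "igwo_rf")
  paired <- lapply(others, function(m) {
    paired_fold_test(fold_acc$igwo_rf, fold_acc[[m]],
                     n_comparisons = length(others))
  })
  names(paired) <- others

  tab <- do.call(rbind, c(
    lapply(names(results), function(m) {
      r <- results[[m]]
      data.frame(model = m,
                 accuracy = r$metrics_mean[["accuracy"]],
                 f1 = r$metrics_mean[["f1"]],
                 auc_roc = r$metrics_mean[["auc_roc"]],
                 kappa = r$metrics_mean[["kappa"]])
    }),
    lapply(names(baseline_rows), function(m) {
      b <- baseline_rows[[m]]
      data.frame(model = m, accuracy = b$accuracy, f1 = b$f1,
                 auc_roc = b$auc_roc, kappa = b$kappa)
    })
  ))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(cfg$out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  structure(list(table = tab, results = results, baselines = baseline_rows,
                 paired_tests = paired, config = cfg),
            class = "comparison_result")
}

#' Tune, then attribute the tuned model on test samples
#'
#' Convenience wrapper used by the command-line `explain` step: trains a
#' forest at a configuration (tuned or given), then computes sampled
#' Shapley attributions for a subset of test rows against a background
#' drawn from the training rows, and the resulting importance ranking.
#'
#' @param prep output of [preprocess_cohort()].
#' @param config an [rf_config()].
#' @param n_explain number of test rows to attribute, default 40.
#' @param n_background background rows sampled from the training split,
#'   default 25.
#' @param n_permutations permutations per sample, default 64.
#' @param seed integer seed.
#' @param fc a [fitness_config()] (forest seed).
#' @return List with `model`, `phi`, `importance` (ranked data frame).
#' @export
explain_tuned_model <- function(prep, config, n_explain = 40,
                                n_background = 25, n_permutations = 64,
                                seed = 1, fc = fitness_config()) {
  model <- train_rf(config, prep$train$X, prep$train$y, seed = fc$seed)
  s <- rng_stream(seed)
  bg_idx <- stream_do(s, function() {
    sample.int(nrow(prep$train$X), min(n_background, nrow(prep$train$X)))
  })
  ex_idx <- stream_do(s, function() {
    sample.int(nrow(prep$test$X), min(n_explain, nrow(prep$test$X)))
  })
  score_fn <- function(X) predict(model, X, type = "score")
  att <- explain_samples(score_fn, prep$test$X[ex_idx, , drop = FALSE],
                         prep$train$X[bg_idx, , drop = FALSE],
                         mode = "sampled", n_permutations = n_permutations,
                         seed = seed)
  list(model = model, phi = att$phi, base = att$base,
       importance = rank_importance(att$phi))
}

#' Aggregate one-hot contribution columns back to their source feature
#'
#' Shapley contributions of the indicator columns of a categorical
#' feature are summed into a single contribution for the feature, so
#' importance rankings compare the original 24 features.
#'
#' @param phi samples x encoded-features contribution matrix.
#' @param feature_names the original feature names.
#' @return A samples x features contribution matrix.
#' @export
collapse_encoded_phi <- function(phi, feature_names = cohort_feature_names()) {
  cols <- colnames(phi)
  owner <- vapply(cols, function(cn) {
    hit <- feature_names[startsWith(cn, paste0(feature_names, "")) &
                           vapply(feature_names, function(f) {
                             cn == f || startsWith(cn, paste0(f, "_"))
                           }, logical(1))]
    if (length(hit)) hit[which.max(nchar(hit))] else cn
  }, character(1))
  agg <- vapply(unique(owner), function(f) {
    rowSums(phi[, owner == f, drop = FALSE])
  }, numeric(nrow(phi)))
  matrix(agg, nrow = nrow(phi), dimnames = list(NULL, unique(owner)))
}
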