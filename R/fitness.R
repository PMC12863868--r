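#' Fitness evaluation settings
#'
#' Controls the cross-validated fitness used during tuning: the number
#' of stratified folds K, the complexity-penalty weight lambda, and the
#' seed governing fold assignment and forest growth. `alpha_reg` is an
#' additional regularization coefficient reported alongside lambda in
#' the source protocol; it is stored for completeness but attached to no
#' term of the fitness.
#'
#' @param folds number of CV folds K (>= 2), default 5.
#' @param lambda complexity-penalty weight (>= 0), default 0.01.
#' @param alpha_reg reserved regularization coefficient, default 0.001 (inert).
#' @param seed integer seed for fold assignment and tree growth, default 42.
#' @param mean_mode if TRUE, report the mean of fold accuracies instead of
#'   the sum (for comparison with conventions that average; default FALSE —
#'   the fitness is the sum over folds).
#' @return An object of class `fitness_config`.
#' @export
fitness_config <- function(folds = 5, lambda = 0.01, alpha_reg = 0.001,
                           seed = 42, mean_mode = FALSE) {
  stopifnot(folds >= 2, lambda >= 0)
  structure(
    list(
      folds = as.integer(folds), lambda = lambda, alpha_reg = alpha_reg,
      seed = as.integer(seed), mean_mode = isTRUE(mean_mode)
    ),
    class = "fitness_config"
  )
}

#' Complexity penalty of a forest configuration
#'
#' Penalizes oversized ensembles and deep trees:
#' `n_trees / upper(n_trees) + max_depth / upper(max_depth)`, where the
#' upper bounds come from the search space. Ranges over (0, 2] on the
#' default domain and is monotone in both arguments.
#'
#' @param config an [rf_config()].
#' @param space the `hp_space` supplying the normalizing upper bounds
#'   (default [default_space()]).
#' @return A single number in (0, 2].
#' @export
complexity_penalty <- function(config, space = default_space()) {
  stopifnot(inherits(config, "rf_config"), inherits(space, "hp_space"))
  nms <- vapply(space$dims, `[[`, character(1), "name")
  up <- function(name) space$dims[[match(name, nms)]]$upper
  config$n_trees / up("n_trees") + config$max_depth / up("max_depth")
}

#' Stratified fold assignment
#'
#' Shuffles indices within each class under the seed and deals them
#' round-robin into K folds, so every fold carries both classes whenever
#' each class has at least K members.
#'
#' @param y binary label vector (0/1).
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in 1..k, same length as `y`.
#' @export
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  fold <- integer(length(y))
  s <- rng_stream(seed)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop("stratification error: class ", cls, " has fewer members (",
           length(idx), ") than folds (", k, ")")
    }
    idx <- stream_do(s, function() sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated, complexity-penalized fitness
#'
#' The tuning objective: the SUM of held-out accuracies over K stratified
#' folds minus `lambda` times the complexity penalty,
#' `F(theta) = sum_k Accuracy_k - lambda * Complexity(theta)`.
#' With `mean_mode` the accuracy term is averaged instead of summed.
#'
#' @param config an [rf_config()].
#' @param X numeric feature matrix or data frame (no missing values).
#' @param y binary label vector (0/1).
#' @param fc a [fitness_config()].
#' @param space space supplying penalty normalization (default
#'   [default_space()]).
#' @return The fitness value (larger is better).
#' @export
cv_fitness <- function(config, X, y, fc = fitness_config(),
                       space = default_space()) {
  stopifnot(inherits(fc, "fitness_config"))
  X <- as.data.frame(X)
  y <- as.integer(y)
  if (anyNA(X)) stop("X must not contain missing values; impute first")
  if (nrow(X) < fc$folds) stop("need at least K rows for K-fold fitness")
  fold <- stratified_folds(y, fc$folds, fc$seed)
  acc <- numeric(fc$folds)
  for (k in seq_len(fc$folds)) {
    tr <- fold != k
    fit <- train_rf(config, X[tr, , drop = FALSE], y[tr], seed = fc$seed)
    pred <- predict(fit, X[!tr, , drop = FALSE], type = "class")
    acc[k] <- mean(pred == y[!tr])
  }
  total <- if (fc$mean_mode) mean(acc) else sum(acc)
  total - fc$lambda * complexity_penalty(config, space)
}

#' Train a random forest at a given configuration
#'
#' Grows an ensemble of `n_trees` depth-capped trees on bootstrap
#' resamples, sampling `round(p_features * ncol(X))` features per split,
#' with minimum leaf size `min_samples_leaf`. Prediction is by majority
#' vote over trees; the class-1 score of a row is the fraction of trees
#' voting 1. Tree growth is delegated to `ranger` (single-threaded,
#' seeded, so runs are bit-reproducible).
#'
#' @param config an [rf_config()].
#' @param X numeric feature matrix or data frame without missing values.
#' @param y binary labels (0/1); both classes must be present.
#' @param seed integer seed for tree growth.
#' @return An object of class `rf_model` with a `predict` method.
#' @export
train_rf <- function(config, X, y, seed = 42) {
  stopifnot(inherits(config, "rf_config"))
  X <- as.data.frame(X)
  if (anyNA(X)) stop("X must not contain missing values; impute first")
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("y has a single class; cannot train a classifier")
  mtry <- max(1L, min(ncol(X), as.integer(round(config$p_features * ncol(X)))))
  yf <- factor(y, levels = c(0L, 1L))
  fit <- ranger::ranger(
    x = X, y = yf,
    num.trees = config$n_trees,
    mtry = mtry,
    max.depth = config$max_depth,
    min.node.size = config$min_samples_leaf,
    seed = seed,
    num.threads = 1,
    verbose = FALSE
  )
  structure(
    list(fit = fit, config = config, feature_names = colnames(X), seed = seed),
    class = "rf_model"
  )
}

#' Predict from a tuned forest
#'
#' @param object an `rf_model` from [train_rf()].
#' @param newdata feature matrix/data frame with the training columns.
#' @param type `"class"` for 0/1 majority-vote labels, `"score"` for the
#'   fraction of trees voting class 1.
#' @param ... unused.
#' @return Numeric vector of labels or scores.
#' @export
predict.rf_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks training columns: ", paste(missing_cols, collapse = ", "))
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  pr <- predict(object$fit, data = newdata, predict.all = TRUE, num.threads = 1)
  votes <- pr$predictions            # n x num.trees, entries are level codes
  lev1 <- match("1", levels(object$fit$predictions))
  if (is.na(lev1)) lev1 <- 2L
  score <- rowMeans(votes == lev1)
  if (type == "score") score else as.integer(score > 0.5)
}

#' @export
print.rf_model <- function(x, ...) {
  cat("Random forest (majority vote):\n")
  print(x$config)
  invisible(x)
}

#' Confusion counts for binary predictions
#'
#' Class 1 (the at-risk / subhealthy label) is the positive class.
#'
#' @param y_true,y_pred binary 0/1 vectors of equal length.
#' @return Named vector `(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  c(
    tp = sum(y_true == 1 & y_pred == 1),
    tn = sum(y_true == 0 & y_pred == 0),
    fp = sum(y_true == 0 & y_pred == 1),
    fn = sum(y_true == 1 & y_pred == 0)
  )
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Precision or recall with a zero denominator is reported as 0 with a
#' warning (no positive predictions, or no positive cases).
#'
#' @param counts named vector from [confusion_counts()].
#' @return List with `accuracy`, `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  total <- tp + tn + fp + fn
  if (total <= 0) stop("confusion counts sum to zero")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0")
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(
    accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    f1 = f1
  )
}

#' Cohen's kappa from confusion counts
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed agreement and `p_e` the agreement expected from the marginal
#' label frequencies. Informative under class imbalance. When `p_e = 1`
#' (both marginals degenerate) the statistic is reported as 1 for perfect
#' agreement and 0 otherwise, with a warning.
#'
#' @param counts named vector from [confusion_counts()].
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  n <- tp + tn + fp + fn
  if (n <= 0) stop("confusion counts sum to zero")
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  if (pe >= 1) {
    warning("expected agreement is 1; kappa degenerate")
    return(if (po == 1) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with midranks for tied scores;
#' equal to the trapezoidal area under the ROC curve, and invariant to
#' strictly monotone transforms of the scores.
#'
#' @param y_true binary 0/1 labels; both classes must be present.
#' @param scores numeric class-1 scores.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) stop("labels and scores differ in length")
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class is absent")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric set of a classifier on labelled data
#'
#' @param model an `rf_model` (or any object whose `predict` honours
#'   `type = "class"` and `type = "score"`).
#' @param X features.
#' @param y binary labels.
#' @return List with accuracy, precision, recall, f1, auc_roc and kappa.
#' @export
evaluate_classifier <- function(model, X, y) {
  pred <- predict(model, X, type = "class")
  score <- predict(model, X, type = "score")
  counts <- confusion_counts(y, pred)
  m <- compute_metrics(counts)
  m$auc_roc <- auc_roc(y, score)
  m$kappa <- cohen_kappa(counts)
  m
}
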