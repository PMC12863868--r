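#' Chained-equations imputation
#'
#' Fills missing entries by iterated conditional modelling: missing
#' cells are initialized with the column mean (mode for categorical
#' columns), then for a fixed number of cycles each incomplete column is
#' modelled on all other columns and its missing entries replaced by the
#' model's predictions. Continuous columns use a linear regression fit
#' on the originally observed rows; categorical columns use
#' nearest-centroid assignment (the level whose mean profile of the
#' other numeric columns is closest). Observed entries are never
#' altered, and the conditionals are deterministic, so the result is
#' reproducible without a seed.
#'
#' @param x a `cohort_table` or a data frame with NAs.
#' @param cycles number of sweeps over the incomplete columns, default 5.
#' @return The same type as `x`, with no missing entries.
#' @export
mice_impute <- function(x, cycles = 5) {
  is_cohort <- inherits(x, "cohort_table")
  df <- if (is_cohort) x$features else as.data.frame(x)

  miss <- vapply(df, function(col) mean(is.na(col)), numeric(1))
  if (any(miss >= 1)) {
    stop("column(s) entirely missing: ",
         paste(names(df)[miss >= 1], collapse = ", "))
  }
  if (any(miss >= 0.5)) {
    stop("column(s) more than 50% missing: ",
         paste(names(df)[miss >= 0.5], collapse = ", "))
  }
  if (all(miss == 0)) return(x)

  obs_mask <- !is.na(df)
  incomplete <- names(df)[miss > 0]

  mode_of <- function(col) {
    tab <- table(col)
    names(tab)[which.max(tab)]
  }
  # mean/mode initialization
  for (nm in incomplete) {
    nas <- is.na(df[[nm]])
    if (is.numeric(df[[nm]])) {
      df[[nm]][nas] <- mean(df[[nm]], na.rm = TRUE)
    } else {
      df[[nm]][nas] <- mode_of(df[[nm]][!nas])
    }
  }

  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  for (cycle in seq_len(cycles)) {
    for (nm in incomplete) {
      nas <- !obs_mask[, nm]
      others <- df[, setdiff(names(df), nm), drop = FALSE]
      if (is.numeric(df[[nm]])) {
        fit_df <- cbind(.y = df[[nm]], others)
        fit <- stats::lm(.y ~ ., data = fit_df[!nas, , drop = FALSE])
        pred <- stats::predict(fit, newdata = others[nas, , drop = FALSE])
        pred[!is.finite(pred)] <- mean(df[[nm]][!nas])
        df[[nm]][nas] <- pred
      } else {
        pred_num <- others[, intersect(num_cols, colnames(others)), drop = FALSE]
        mu <- colMeans(pred_num)
        sdv <- vapply(pred_num, stats::sd, numeric(1))
        sdv[sdv == 0] <- 1
        z <- scale(as.matrix(pred_num), center = mu, scale = sdv)
        levs <- levels(factor(df[[nm]][!nas]))
        centroids <- matrix(0, length(levs), ncol(z))
        for (li in seq_along(levs)) {
          centroids[li, ] <- colMeans(z[!nas & df[[nm]] == levs[li], ,
                                        drop = FALSE])
        }
        zm <- z[nas, , drop = FALSE]
        d2 <- vapply(seq_len(nrow(centroids)), function(k) {
          rowSums(sweep(zm, 2, centroids[k, ])^2)
        }, numeric(nrow(zm)))
        d2 <- matrix(d2, nrow = nrow(zm))
        df[[nm]][nas] <- levs[apply(d2, 1, which.min)]
      }
    }
  }

  if (is_cohort) {
    x$features <- df
    x
  } else {
    df
  }
}

#' Tukey-fence winsorization with percentile caps
#'
#' Outliers are detected with the classical Tukey fences
#' `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`; values below the lower fence are
#' replaced by the column's 1st percentile and values above the upper
#' fence by its 99th percentile (quantiles by linear interpolation,
#' type 7). All other values — and missing entries — are untouched.
#' The `cap_at_fences` variant caps at the fences themselves instead of
#' the percentiles.
#'
#' @param column numeric vector with at least 4 finite values.
#' @param cap_at_fences cap at the Tukey fences rather than the
#'   1st/99th percentiles (default FALSE, the percentile convention).
#' @return List with `values` (the winsorized column), `caps`
#'   `(low, high)`, `fences` `(lower, upper)` and `n_winsorized`.
#' @export
tukey_winsorize <- function(column, cap_at_fences = FALSE) {
  finite <- is.finite(column)
  if (sum(finite) < 4) stop("need at least 4 finite values to winsorize")
  q <- stats::quantile(column[finite], c(0.25, 0.75, 0.01, 0.99),
                       names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  caps <- if (cap_at_fences) {
    c(low = unname(fences[1]), high = unname(fences[2]))
  } else {
    c(low = q[3], high = q[4])
  }
  out <- column
  low_out <- finite & column < fences[1]
  high_out <- finite & column > fences[2]
  out[low_out] <- caps[["low"]]
  out[high_out] <- caps[["high"]]
  list(values = out, caps = caps, fences = fences,
       n_winsorized = sum(low_out) + sum(high_out))
}

#' Min-max scaling to \[0, 1\]
#'
#' `(x - min) / (max - min)` with parameters fit on the supplied data or
#' reused from a previous fit (leakage guard: fit on the training split,
#' apply to test). A constant column maps to all zeros with a warning.
#'
#' @param column numeric vector.
#' @param params optional `(min, max)` from a previous fit.
#' @return List with `values` and `params`.
#' @export
min_max_scale <- function(column, params = NULL) {
  if (is.null(params)) {
    params <- c(min = min(column, na.rm = TRUE), max = max(column, na.rm = TRUE))
  }
  if (params[["max"]] <= params[["min"]]) {
    warning("constant column: scaled to 0")
    return(list(values = rep(0, length(column)), params = params))
  }
  list(values = (column - params[["min"]]) / (params[["max"]] - params[["min"]]),
       params = params)
}

#' Invert a min-max scaling
#'
#' @param values scaled values.
#' @param params the `(min, max)` parameters of the fit.
#' @return The original-scale values.
#' @export
inverse_min_max <- function(values, params) {
  values * (params[["max"]] - params[["min"]]) + params[["min"]]
}

#' One-hot encoding of a categorical column
#'
#' One indicator column per category, categories in lexicographic
#' order, no dropped level, so every row sums to 1. At transform time a
#' value outside the fitted level set is an error naming the offender.
#'
#' @param column factor or character vector.
#' @param levels optional fixed level set from a previous fit.
#' @param prefix column-name prefix (default the deparsed input name).
#' @return Numeric indicator matrix with `length(levels)` columns.
#' @export
one_hot_encode <- function(column, levels = NULL, prefix = "x") {
  vals <- as.character(column)
  if (is.null(levels)) {
    levels <- sort(unique(vals))
  } else {
    unseen <- setdiff(unique(vals), levels)
    if (length(unseen)) {
      stop("unseen categor", if (length(unseen) > 1) "ies: " else "y: ",
           paste(unseen, collapse = ", "))
    }
  }
  m <- vapply(levels, function(l) as.numeric(vals == l), numeric(length(vals)))
  m <- matrix(m, nrow = length(vals),
              dimnames = list(NULL, paste(prefix, levels, sep = "_")))
  m
}

#' Stratified train/test split
#'
#' Per-class training counts are set by largest-remainder apportionment
#' of `round(train_fraction * n)` across classes, so split proportions
#' differ from the cohort proportions by less than one row per class.
#' Rows are shuffled within class under the seed.
#'
#' @param label binary 0/1 vector, or a `cohort_table`.
#' @param train_fraction fraction of rows in the training split,
#'   default 0.7; must leave both splits nonempty.
#' @param seed integer seed, default 42.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(label, train_fraction = 0.7, seed = 42) {
  if (inherits(label, "cohort_table")) label <- label$label
  label <- as.integer(label)
  n <- length(label)
  classes <- sort(unique(label))
  if (length(classes) < 2) stop("both classes must be present to stratify")
  counts <- vapply(classes, function(c) sum(label == c), integer(1))
  if (any(counts < 2)) stop("every class needs at least 2 members")
  total_train <- round(train_fraction * n)
  if (total_train <= 0 || total_train >= n) {
    stop("train_fraction ", train_fraction, " leaves an empty split")
  }
  q <- train_fraction * counts
  base <- floor(q)
  rem <- total_train - sum(base)
  if (rem > 0) {
    extra <- order(-(q - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    drop <- order(q - base)[seq_len(-rem)]
    base[drop] <- base[drop] - 1
  }
  s <- rng_stream(seed)
  train <- integer(0)
  for (k in seq_along(classes)) {
    idx <- which(label == classes[k])
    idx <- stream_do(s, function() sample(idx))
    train <- c(train, idx[seq_len(base[k])])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Full preprocessing chain for a cohort
#'
#' Imputes missing entries (chained equations on the full table, as the
#' upstream protocol imputes once before partitioning), winsorizes every
#' continuous feature at the Tukey fences, splits rows stratified by
#' label, then fits min-max scaling on the training rows only and
#' applies it to both splits; categorical features are one-hot encoded
#' over their full level sets. Returns model-ready numeric matrices and
#' an audit report.
#'
#' @param cohort a `cohort_table`.
#' @param train_fraction training fraction, default 0.7.
#' @param seed split seed, default 42.
#' @param cycles imputation cycles, default 5.
#' @return List with `train` and `test` (each `list(X, y)` with X a
#'   numeric data frame), `split` (the index lists), and `report` (per
#'   column: n imputed, n winsorized, caps, scale parameters; split
#'   sizes).
#' @export
preprocess_cohort <- function(cohort, train_fraction = 0.7, seed = 42,
                              cycles = 5) {
  stopifnot(inherits(cohort, "cohort_table"))
  n_imputed <- colSums(cohort$missing_mask)
  imputed <- mice_impute(cohort, cycles = cycles)
  df <- imputed$features

  report_cols <- list()
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      w <- tukey_winsorize(df[[nm]])
      df[[nm]] <- w$values
      report_cols[[nm]] <- list(
        n_imputed = unname(n_imputed[nm]), n_winsorized = w$n_winsorized,
        caps = as.list(w$caps)
      )
    } else {
      report_cols[[nm]] <- list(n_imputed = unname(n_imputed[nm]),
                                n_winsorized = 0L, caps = NULL)
    }
  }

  split <- stratified_split(cohort$label, train_fraction, seed)

  build <- function(rows, scale_params) {
    out <- list()
    params <- list()
    for (nm in names(df)) {
      col <- df[[nm]][rows]
      if (is.numeric(df[[nm]])) {
        sc <- min_max_scale(col, params = scale_params[[nm]])
        out[[nm]] <- sc$values
        params[[nm]] <- sc$params
      } else {
        m <- one_hot_encode(col, levels = sort(levels(df[[nm]])), prefix = nm)
        for (j in seq_len(ncol(m))) out[[colnames(m)[j]]] <- m[, j]
      }
    }
    list(X = as.data.frame(out), params = params)
  }

  tr <- build(split$train, scale_params = list())
  te <- build(split$test, scale_params = tr$params)

  for (nm in names(tr$params)) {
    report_cols[[nm]]$scale <- as.list(tr$params[[nm]])
  }

  list(
    train = list(X = tr$X, y = cohort$label[split$train]),
    test = list(X = te$X, y = cohort$label[split$test]),
    split = split,
    report = list(columns = report_cols,
                  split_sizes = c(train = length(split$train),
                                  test = length(split$test)))
  )
}
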