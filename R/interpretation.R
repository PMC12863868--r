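#' @name shapley
#' @title Shapley attribution of model predictions
#'
#' @description
#' Feature contributions are computed against an interventional value
#' function: `f(S)` is the model score averaged over the background
#' rows with the features in `S` taken from the explained sample and
#' the remaining features from the background row. The exact enumerator
#' sums the classical weighted marginal contributions over all feature
#' subsets; the sampled estimator averages marginal contributions along
#' random feature orderings and is unbiased for the exact values.
#' Exact mode satisfies the efficiency axiom: the base value plus the
#' contributions reconstructs the model score of the sample.
NULL

composite_scores <- function(model_score, x, background, subset_list) {
  # one score call over the stacked composites; returns mean score per subset
  B <- as.matrix(background)
  m <- nrow(B)
  d <- ncol(B)
  big <- B[rep(seq_len(m), times = length(subset_list)), , drop = FALSE]
  for (s in seq_along(subset_list)) {
    cols <- subset_list[[s]]
    if (length(cols)) {
      rows <- (s - 1) * m + seq_len(m)
      big[rows, cols] <- matrix(x[cols], nrow = m, ncol = length(cols),
                                byrow = TRUE)
    }
  }
  sc <- model_score(as.data.frame(big))
  colMeans(matrix(sc, nrow = m))
}

subset_bits <- function(d) {
  # (2^d) x d logical matrix; row k+1 holds the bits of integer k
  k <- 0:(2^d - 1)
  vapply(seq_len(d), function(j) (k %/% 2^(j - 1)) %% 2 == 1,
         logical(length(k)))
}

all_subset_values <- function(model_score, x, background, chunk = 4096L) {
  d <- length(x)
  bits <- subset_bits(d)
  n_sub <- nrow(bits)
  f <- numeric(n_sub)
  start <- 1L
  while (start <= n_sub) {
    end <- min(start + chunk - 1L, n_sub)
    subsets <- lapply(start:end, function(k) which(bits[k, ]))
    f[start:end] <- composite_scores(model_score, x, background, subsets)
    start <- end + 1L
  }
  list(f = f, bits = bits)
}

#' Exact Shapley values by subset enumeration
#'
#' @param model_score function mapping a data frame of rows to numeric
#'   scores (e.g. `function(X) predict(model, X, type = "score")`).
#' @param x the explained sample: named numeric vector or one-row data
#'   frame matching the background columns.
#' @param background data frame or matrix of background rows (nonempty).
#' @param features optional character vector naming/ordering the
#'   features; defaults to the background columns.
#' @return Object of class `attribution`: `phi` (named contributions),
#'   `base` (value of the empty subset), `prediction` (value of the full
#'   subset, equal to `base + sum(phi)`).
#' @rdname shapley
#' @export
shapley_exact <- function(model_score, x, background, features = NULL) {
  background <- as.data.frame(background)
  if (nrow(background) < 1) stop("background must be nonempty")
  if (!is.null(features)) background <- background[, features, drop = FALSE]
  x <- unlist(as.data.frame(as.list(x))[, colnames(background), drop = FALSE])
  d <- length(x)
  if (d > 15) {
    stop("exact enumeration guarded at 15 features (got ", d,
         "); use shapley_sampled()")
  }
  fv <- all_subset_values(model_score, x, background)
  f <- fv$f
  bits <- fv$bits
  sizes <- rowSums(bits)
  w <- factorial(0:(d - 1)) * factorial(d - 1 - 0:(d - 1)) / factorial(d)
  phi <- numeric(d)
  for (i in seq_len(d)) {
    without <- which(!bits[, i])
    with_i <- without + 2^(i - 1)
    phi[i] <- sum(w[sizes[without] + 1] * (f[with_i] - f[without]))
  }
  names(phi) <- colnames(background)
  structure(
    list(phi = phi, base = f[1], prediction = f[length(f)], mode = "exact"),
    class = "attribution"
  )
}

#' Permutation-sampling Shapley estimator
#'
#' @param n_permutations number of random feature orderings (>= 1).
#' @param rng an [rng_stream()] or integer seed.
#' @rdname shapley
#' @export
shapley_sampled <- function(model_score, x, background, n_permutations = 2000,
                            rng = 1, features = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  stream <- if (inherits(rng, "rng_stream")) rng else rng_stream(rng)
  background <- as.data.frame(background)
  if (!is.null(features)) background <- background[, features, drop = FALSE]
  x <- unlist(as.data.frame(as.list(x))[, colnames(background), drop = FALSE])
  d <- length(x)
  B <- as.matrix(background)
  m <- nrow(B)

  f_empty <- mean(model_score(as.data.frame(B)))
  perms <- stream_do(stream, function() {
    t(vapply(seq_len(n_permutations), function(p) sample.int(d), integer(d)))
  })
  perms <- matrix(perms, nrow = n_permutations)

  big <- B[rep(seq_len(m), times = n_permutations * d), , drop = FALSE]
  for (p in seq_len(n_permutations)) {
    comp <- B
    for (k in seq_len(d)) {
      j <- perms[p, k]
      comp[, j] <- x[j]
      rows <- ((p - 1) * d + k - 1) * m + seq_len(m)
      big[rows, ] <- comp
    }
  }
  sc <- model_score(as.data.frame(big))
  block_means <- colMeans(matrix(sc, nrow = m))

  contrib <- numeric(d)
  for (p in seq_len(n_permutations)) {
    fs <- c(f_empty, block_means[(p - 1) * d + seq_len(d)])
    contrib[perms[p, ]] <- contrib[perms[p, ]] + diff(fs)
  }
  phi <- contrib / n_permutations
  names(phi) <- colnames(background)
  structure(
    list(phi = phi, base = f_empty, prediction = f_empty + sum(phi),
         mode = "sampled", n_permutations = n_permutations),
    class = "attribution"
  )
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("Shapley attribution (%s mode): base %.4f, prediction %.4f\n",
              x$mode, x$base, x$prediction))
  print(round(sort(x$phi, decreasing = TRUE), 4))
  invisible(x)
}

#' Pairwise Shapley interaction index
#'
#' The symmetric interaction of features `i` and `j`: the weighted sum
#' over subsets `S` excluding both of the second difference
#' `f(S + ij) - f(S + i) - f(S + j) + f(S)`, with weight
#' `|S|! (d - |S| - 2)! / (d - 1)!`. Zero for additively separable
#' models; for a pure product model of two active features it equals
#' the product term's full effect.
#'
#' @param model_score,x,background as in [shapley_exact()].
#' @param i,j distinct feature names or indices.
#' @return The interaction value (a single number).
#' @export
shapley_interaction <- function(model_score, x, background, i, j) {
  background <- as.data.frame(background)
  x <- unlist(as.data.frame(as.list(x))[, colnames(background), drop = FALSE])
  d <- length(x)
  if (d > 12) stop("exact interaction guarded at 12 features (got ", d, ")")
  if (is.character(i)) i <- match(i, colnames(background))
  if (is.character(j)) j <- match(j, colnames(background))
  if (is.na(i) || is.na(j)) stop("unknown feature name")
  if (i == j) stop("interaction requires two distinct features")
  fv <- all_subset_values(model_score, x, background)
  f <- fv$f
  bits <- fv$bits
  sizes <- rowSums(bits)
  base_idx <- which(!bits[, i] & !bits[, j])
  s <- sizes[base_idx]
  w <- factorial(s) * factorial(d - s - 2) / factorial(d - 1)
  fi <- f[base_idx + 2^(i - 1)]
  fj <- f[base_idx + 2^(j - 1)]
  fij <- f[base_idx + 2^(i - 1) + 2^(j - 1)]
  sum(w * (fij - fi - fj + f[base_idx]))
}

#' Attribute a set of samples and collect the contribution matrix
#'
#' Runs the sampled estimator on each row of `X_explain` (exact mode if
#' the dimension permits and `mode = "exact"`), returning the per-sample
#' contribution matrix for ranking.
#'
#' @param model_score scoring function as in [shapley_exact()].
#' @param X_explain data frame of samples to attribute.
#' @param background background rows.
#' @param mode `"sampled"` (default) or `"exact"`.
#' @param n_permutations permutations per sample in sampled mode.
#' @param seed integer seed.
#' @return List with `phi` (samples x features matrix) and `base`
#'   (per-sample base values).
#' @export
explain_samples <- function(model_score, X_explain, background,
                            mode = c("sampled", "exact"),
                            n_permutations = 2000, seed = 1) {
  mode <- match.arg(mode)
  X_explain <- as.data.frame(X_explain)
  stream <- rng_stream(seed)
  res <- lapply(seq_len(nrow(X_explain)), function(r) {
    if (mode == "exact") {
      shapley_exact(model_score, X_explain[r, , drop = FALSE], background)
    } else {
      shapley_sampled(model_score, X_explain[r, , drop = FALSE], background,
                      n_permutations = n_permutations, rng = stream)
    }
  })
  phi <- do.call(rbind, lapply(res, `[[`, "phi"))
  rownames(phi) <- NULL
  list(phi = phi, base = vapply(res, `[[`, numeric(1), "base"))
}

#' Rank features by mean absolute contribution
#'
#' Importance of a feature is the mean of `|phi|` over the attributed
#' samples; features are ordered descending, ties broken
#' lexicographically by name.
#'
#' @param phi a samples x features contribution matrix (or the list
#'   returned by [explain_samples()], or a single `attribution`).
#' @return Data frame with columns `feature` and `importance`, ordered.
#' @export
rank_importance <- function(phi) {
  if (inherits(phi, "attribution")) phi <- rbind(phi$phi)
  if (is.list(phi) && !is.data.frame(phi) && !is.matrix(phi)) phi <- phi$phi
  phi <- rbind(phi)
  if (nrow(phi) < 1) stop("need at least one attributed sample")
  imp <- colMeans(abs(phi))
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             row.names = NULL)
}
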