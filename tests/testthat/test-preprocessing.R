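test_that("chained-equations imputation preserves observed data and anchors", {
  df <- data.frame(a = c(1, 2, 3, 4, 5), b = c(7, 7, NA, 7, 7))
  out <- mice_impute(df)
  expect_equal(out$b, rep(7, 5))              # constant column refilled
  expect_identical(out$a, df$a)               # observed entries untouched

  clean <- data.frame(x = 1:5, y = 5:1)
  expect_identical(mice_impute(clean), clean) # no-op without missingness

  allna <- data.frame(x = 1:4, y = rep(NA_real_, 4))
  expect_error(mice_impute(allna), "entirely missing")
  half <- data.frame(x = 1:10, y = c(rep(NA_real_, 6), 1:4))
  expect_error(mice_impute(half), "50%")
})

test_that("regression imputation beats the mean under strong correlation", {
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 2000
    x1 <- rnorm(n)
    x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
    miss <- sample(n, 0.2 * n)
    dfm <- data.frame(x1 = x1, x2 = x2)
    dfm$x2[miss] <- NA
    imp <- mice_impute(dfm)
    rmse_chain <- sqrt(mean((imp$x2[miss] - x2[miss])^2))
    rmse_mean <- sqrt(mean((mean(dfm$x2, na.rm = TRUE) - x2[miss])^2))
    wins <- wins + (rmse_chain < rmse_mean)
  }
  expect_gte(wins, 19)
})

test_that("categorical holes are filled from the fitted level set", {
  set.seed(5)
  n <- 400
  grp <- factor(sample(c("lo", "hi"), n, replace = TRUE))
  x <- ifelse(grp == "hi", 3, -3) + rnorm(n)
  df <- data.frame(g = grp, x = x)
  miss <- sample(n, 40)
  df$g[miss] <- NA
  out <- mice_impute(df)
  expect_false(anyNA(out$g))
  # nearest-centroid conditional recovers the separable group structure
  expect_gte(mean(as.character(out$g[miss]) == as.character(grp[miss])), 0.9)
})

test_that("winsorization caps Tukey-fence outliers at the 1st/99th percentiles", {
  x <- c(1:9, 1000)
  w <- tukey_winsorize(x)
  q <- quantile(x, c(0.25, 0.75, 0.99), names = FALSE, type = 7)
  upper_fence <- q[2] + 1.5 * (q[2] - q[1])
  expect_gt(1000, upper_fence)
  expect_equal(w$values, c(1:9, q[3]))
  expect_equal(w$n_winsorized, 1)

  tame <- c(2, 4, 6, 8, 10)
  expect_equal(tukey_winsorize(tame)$values, tame)

  # idempotent on realistic columns; rank order of untouched entries kept
  set.seed(6)
  for (i in 1:10) {
    col <- rnorm(500, sd = runif(1, 0.5, 3))
    once <- tukey_winsorize(col)
    twice <- tukey_winsorize(once$values)
    expect_equal(twice$values, once$values)
    untouched <- col >= once$fences[1] & col <= once$fences[2]
    expect_identical(order(col[untouched]), order(once$values[untouched]))
  }
  expect_error(tukey_winsorize(c(1, 2, 3)), "4 finite")
  # fence-cap variant caps at the fences themselves
  wf <- tukey_winsorize(x, cap_at_fences = TRUE)
  expect_equal(wf$values[10], upper_fence)
})

test_that("min-max scaling hits [0,1], warns on constants, and inverts", {
  sc <- min_max_scale(c(0, 5, 10))
  expect_equal(sc$values, c(0, 0.5, 1))
  expect_warning(cz <- min_max_scale(c(7, 7, 7)), "constant")
  expect_equal(cz$values, c(0, 0, 0))
  set.seed(7)
  x <- rnorm(100, 50, 9)
  sc <- min_max_scale(x)
  expect_equal(inverse_min_max(sc$values, sc$params), x, tolerance = 1e-12)
  # stored parameters transform unseen data consistently
  new <- min_max_scale(c(55, 60), params = sc$params)
  expect_equal(new$values, (c(55, 60) - sc$params[["min"]]) /
                 (sc$params[["max"]] - sc$params[["min"]]))
})

test_that("one-hot encoding is complete, ordered, and rejects unseen levels", {
  m <- one_hot_encode(c("b", "a", "c"), prefix = "f")
  expect_equal(colnames(m), c("f_a", "f_b", "f_c"))
  expect_equal(m[1, ], c(f_a = 0, f_b = 1, f_c = 0))
  expect_true(all(rowSums(m) == 1))
  single <- one_hot_encode(rep("only", 4))
  expect_equal(ncol(single), 1)
  expect_true(all(single == 1))
  set.seed(8)
  r <- one_hot_encode(sample(letters[1:5], 200, replace = TRUE))
  expect_true(all(rowSums(r) == 1))
  expect_error(one_hot_encode(c("a", "z"), levels = c("a", "b")), "z")
})

test_that("stratified split apportions the printed cohort exactly", {
  label <- c(rep(0L, 1402), rep(1L, 450))
  sp <- stratified_split(label, 0.7, seed = 42)
  expect_equal(length(sp$train), 1296)
  expect_equal(length(sp$test), 556)
  expect_equal(sum(label[sp$train] == 0), 981)
  expect_equal(sum(label[sp$train] == 1), 315)
  # a partition of the rows
  expect_setequal(c(sp$train, sp$test), seq_along(label))
  expect_length(intersect(sp$train, sp$test), 0)
  # per-class proportions within one row of the cohort proportions
  expect_lt(abs(mean(label[sp$train]) - mean(label)), 1 / length(sp$train) * 2)
  expect_error(stratified_split(label, 1.0), "empty split")
  expect_error(stratified_split(rep(0L, 10), 0.7), "both classes")
})

test_that("the full chain is deterministic, complete, and leakage-guarded", {
  spec <- tiny_cohort_spec(seed = 14, n = 250)
  co <- generate_cohort(spec)
  p1 <- preprocess_cohort(co)
  p2 <- preprocess_cohort(co)
  expect_identical(p1$train$X, p2$train$X)
  expect_identical(p1$split, p2$split)
  expect_false(anyNA(p1$train$X))
  expect_false(anyNA(p1$test$X))
  # training columns scale to exactly [0,1]; test columns use train params
  num_cols <- setdiff(colnames(p1$train$X),
                      grep("dietary|smoking", colnames(p1$train$X), value = TRUE))
  for (nm in num_cols[1:5]) {
    expect_equal(range(p1$train$X[[nm]]), c(0, 1))
  }
  rpt <- p1$report
  expect_equal(unname(rpt$split_sizes["train"] + rpt$split_sizes["test"]), 250)
  expect_equal(sum(vapply(rpt$columns, `[[`, numeric(1), "n_imputed")),
               sum(co$missing_mask))
})
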