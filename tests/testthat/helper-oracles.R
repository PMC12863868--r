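# Independent oracles and shared fixtures for the test suite.

# All permutations of 1..n as an (n!) x n matrix (recursive construction).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

# Interventional value function computed with plain row loops, independent
# of the package's batched implementation.
oracle_value <- function(score_fn, x, bg, subset) {
  vals <- numeric(nrow(bg))
  for (r in seq_len(nrow(bg))) {
    row <- bg[r, , drop = FALSE]
    if (length(subset)) row[, subset] <- x[subset]
    vals[r] <- score_fn(row)
  }
  mean(vals)
}

# Brute-force Shapley values: average marginal contribution over every
# ordering of the features.
oracle_shapley <- function(score_fn, x, bg) {
  d <- length(x)
  perms <- all_permutations(d)
  phi <- numeric(d)
  for (p in seq_len(nrow(perms))) {
    prev <- oracle_value(score_fn, x, bg, integer(0))
    chosen <- integer(0)
    for (k in seq_len(d)) {
      chosen <- c(chosen, perms[p, k])
      cur <- oracle_value(score_fn, x, bg, chosen)
      phi[perms[p, k]] <- phi[perms[p, k]] + (cur - prev)
      prev <- cur
    }
  }
  phi / nrow(perms)
}

# A deterministic step fitness over the unit cube: coordinates snapped to
# the 3-level grid {0, 1/2, 1}; optimum at the snapped target cell.
grid_fitness <- function(target = c(1, 0.5, 0)) {
  function(v) -sum((round(v * 2) / 2 - target)^2)
}

grid_optimum <- function(target = c(1, 0.5, 0)) {
  g <- grid_fitness(target)
  grid <- as.matrix(expand.grid(c(0, 0.5, 1), c(0, 0.5, 1), c(0, 0.5, 1)))
  max(apply(grid, 1, g))
}

# Rastrigin-style multimodal fitness on [0,1]^2 (maximization).
rastrigin_fitness <- function(v) {
  z <- 10 * v - 5
  -(20 + sum(z^2 - 10 * cos(2 * pi * z)))
}

# Small linearly separable classification problem.
separable_data <- function(n = 100, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- data.frame(
    a = y * 10 + rnorm(n, 0, 0.1),
    b = rnorm(n)
  )
  list(X = X, y = y)
}

# Down-scaled cohort for fast pipeline tests.
tiny_cohort_spec <- function(seed = 1, n = 250, missing_rate = 0.032) {
  scaled_cohort_spec(n, seed = seed, missing_rate = missing_rate)
}

one_dim_space <- function() {
  hp_space(list(list(name = "x", kind = "continuous", lower = 0, upper = 1)))
}
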