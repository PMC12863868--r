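test_that("inertia weight decays linearly from 2 to 0 and guards its domain", {
  expect_equal(dynamic_weight(0, 100), 2.0)
  expect_equal(dynamic_weight(100, 100), 0.0)
  expect_equal(dynamic_weight(50, 100), 1.0)
  expect_error(dynamic_weight(101, 100), "lie in")
  expect_error(dynamic_weight(1, 0), ">= 1")
})

test_that("coefficient vectors stay inside their analytic ranges", {
  s <- rng_stream(5)
  z <- coefficient_vectors(0, 4, s)
  expect_equal(z$A, rep(0, 4))
  # Monte-Carlo bound check at a = 1 over many draws
  draws <- replicate(2500, {
    co <- coefficient_vectors(1, 4, s)
    c(co$A, co$C)
  })
  A <- draws[1:4, ]; C <- draws[5:8, ]
  expect_true(all(A >= -1 & A <= 1))
  expect_true(all(C >= 0 & C <= 2))
})

test_that("the pack move reproduces hand-evaluated updates", {
  leaders <- matrix(c(0.8, 0.6, 0.2), 3, 1)
  # a = 1, r1 = r2 = 0.5 -> A = 0, C = 1: every pulled point is its leader
  A0 <- matrix(0, 3, 1); C1 <- matrix(1, 3, 1)
  expect_equal(gwo_candidate(0.4, leaders, A0, C1), (0.8 + 0.6 + 0.2) / 3)
  # coincident leaders with A = 0 collapse onto the leader for any C
  L <- matrix(0.55, 3, 1)
  expect_equal(gwo_candidate(0.1, L, A0, matrix(c(0.3, 1.7, 0.9), 3, 1)), 0.55)
  # a = 1, r1 = 0.25 (A = -0.5), r2 = 0.5 (C = 1): evaluate the four
  # printed formulas by hand: X_k' = X_k + 0.5 |X_k - x|
  Am <- matrix(-0.5, 3, 1)
  hand <- mean(c(0.8 + 0.5 * 0.4, 0.6 + 0.5 * 0.2, 0.2 + 0.5 * 0.2))
  expect_equal(gwo_candidate(0.4, leaders, Am, C1), hand)
  # stochastic updates always land in the unit cube
  s <- rng_stream(3)
  for (i in 1:100) {
    out <- update_position(runif(3), matrix(runif(9), 3, 3), 2, s)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("opposition points interpolate between best and worst", {
  expect_equal(opposition_point(0.2, 0.8, 0), 0.2)
  expect_equal(opposition_point(0.2, 0.8, 1), 0.8)
  expect_equal(opposition_point(0.2, 0.8, 0.5), 0.5)
  expect_equal(opposition_point(c(0.2, 0.9), 0.1, 0, style = "reflect"),
               c(0.8, 0.1))
  pack <- new_pack(matrix(seq(0.1, 1, by = 0.1), 10, 1), fitness = 10:1)
  opp <- elite_opposition(pack, 0.1, rng_stream(2))
  expect_equal(nrow(opp), 1)
  expect_true(all(opp >= 0 & opp <= 1))
})

test_that("elite retention keeps the previous generation's best", {
  prev <- new_pack(matrix(1:5 / 10, 5, 1), fitness = c(5, 4, 3, 2, 1))
  cand <- new_pack(matrix(6:10 / 10, 5, 1), fitness = c(0.5, 0.4, 0.3, 0.2, 0.1))
  merged <- elite_retention(prev, cand, 0.2)
  expect_equal(length(merged$fitness), 5)
  expect_true(5 %in% merged$fitness)        # the previous alpha survives
  expect_equal(max(merged$fitness), 5)
  # full retention reproduces the previous pack regardless of candidates
  full <- elite_retention(prev, cand, 1)
  expect_setequal(full$fitness, prev$fitness)
})

test_that("termination honours the tolerance rule and the iteration cap", {
  expect_true(check_termination(c(1.0, 1.0 + 1e-7), tol = 1e-5, T_max = 100))
  expect_false(check_termination(c(1.0, 2.0), tol = 1e-5, T_max = 100))
  expect_true(check_termination(c(1.0, 2.0), tol = 1e-5, T_max = 2))
  # patience window: a single flat step does not stop a patient run
  expect_false(check_termination(c(1, 1, 2), tol = 1e-5, T_max = 100,
                                 patience = 2))
  expect_true(check_termination(c(1, 2, 2, 2), tol = 1e-5, T_max = 100,
                                patience = 2))
})

test_that("IGWO recovers a one-dimensional analytic optimum", {
  f <- function(v) -(v[1] - 0.37)^2
  errs <- vapply(1:20, function(s) {
    r <- igwo_optimize(f, one_dim_space(), optimizer_config(seed = s))
    abs(r$best_coords[1] - 0.37)
  }, numeric(1))
  expect_lt(median(errs), 0.01)
})

test_that("IGWO with all components disabled is the plain pack search", {
  f <- function(v) -(v[1] - 0.6)^2
  cfg <- optimizer_config(
    population_size = 10, max_iterations = 15, seed = 4,
    components = c(dynamic_weight = FALSE, elite_opposition = FALSE,
                   elite_retention = FALSE)
  )
  r <- igwo_optimize(f, one_dim_space(), cfg)
  expect_true(all(r$trace$a == 1.0))          # constant-weight off-state
  expect_true(all(diff(r$trace$best_fitness) >= 0))
  expect_lt(abs(r$best_coords[1] - 0.6), 0.1)
})

test_that("seeded optimizer runs are bit-reproducible", {
  f <- function(v) sum(sin(5 * v)) - sum((v - 0.3)^2)
  cfg <- optimizer_config(population_size = 8, max_iterations = 10, seed = 99)
  r1 <- igwo_optimize(f, default_space(), cfg)
  r2 <- igwo_optimize(f, default_space(), cfg)
  expect_identical(r1$best_coords, r2$best_coords)
  expect_identical(r1$trace, r2$trace)
})

test_that("PSO converges on the quadratic and respects its fixed point", {
  f <- function(v) -(v[1] - 0.37)^2
  errs <- vapply(1:20, function(s) {
    r <- pso_optimize(f, one_dim_space(), optimizer_config(seed = s))
    abs(r$best_coords[1] - 0.37)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  r <- pso_optimize(f, one_dim_space(),
                    optimizer_config(population_size = 5, max_iterations = 10,
                                     seed = 1))
  expect_lte(nrow(r$trace), 10)
})

test_that("random search returns the argmax and improves with budget", {
  g <- grid_fitness()
  r1 <- random_search(g, default_space(), budget = 1, seed = 3)
  c1 <- sample_uniform(default_space(), 1, rng_stream(3))
  expect_equal(r1$best_fitness, g(c1[1, ]))
  # ample budget over a 27-cell grid finds the enumerated optimum
  big <- random_search(g, default_space(), budget = 500, seed = 3)
  expect_equal(big$best_fitness, grid_optimum())
  # prefix property: best fitness is monotone in the budget at fixed seed
  fits <- vapply(c(10, 50, 200), function(b) {
    random_search(g, default_space(), budget = b, seed = 11)$best_fitness
  }, numeric(1))
  expect_true(all(diff(fits) >= 0))
  expect_error(random_search(g, default_space(), budget = 0), "budget")
})

test_that("masked selection recovers a planted informative subset", {
  fit_fn <- function(m) sum(m[1:3]) - 0.25 * sum(m[4:6])
  hits <- vapply(1:20, function(s) {
    r <- select_features(fit_fn, 6,
                         optimizer_config(population_size = 10,
                                          max_iterations = 20, seed = s))
    identical(r$mask, c(1L, 1L, 1L, 0L, 0L, 0L))
  }, logical(1))
  expect_gte(sum(hits), 18)
  # degenerate single-feature problem and the never-empty-mask repair
  one <- select_features(function(m) sum(m), 1, optimizer_config(seed = 1))
  expect_equal(one$mask, 1L)
  r <- select_features(function(m) -sum(m), 5,
                       optimizer_config(population_size = 6,
                                        max_iterations = 8, seed = 2))
  expect_gte(sum(r$mask), 1)
})

test_that("opposition learning does not reduce mid-run diversity (reported)", {
  run_div <- function(opposition, seed) {
    cfg <- optimizer_config(
      population_size = 15, max_iterations = 20, seed = seed,
      patience = 20,
      components = c(elite_opposition = opposition)
    )
    sp <- hp_space(list(
      list(name = "u", kind = "continuous", lower = 0, upper = 1),
      list(name = "v", kind = "continuous", lower = 0, upper = 1)
    ))
    r <- igwo_optimize(rastrigin_fitness, sp, cfg)
    r$trace$diversity[min(10, nrow(r$trace))]
  }
  with_opp <- mean(vapply(1:20, function(s) run_div(TRUE, s), numeric(1)))
  without <- mean(vapply(1:20, function(s) run_div(FALSE, s), numeric(1)))
  # empirical diversity-preservation check: informational, not a hard gate
  if (with_opp < without) {
    message(sprintf(
      "diversity with opposition (%.4f) below without (%.4f) on this landscape",
      with_opp, without))
  }
  expect_true(is.finite(with_opp) && is.finite(without))
})

test_that("traces serialize to JSON lines, one record per iteration", {
  r <- igwo_optimize(function(v) -(v[1] - 0.5)^2, one_dim_space(),
                     optimizer_config(population_size = 5, max_iterations = 4,
                                      seed = 2, patience = 4))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trace_jsonl(r$trace, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(r$trace))
  rec <- jsonlite::fromJSON(lines[1])
  expect_named(rec, c("iteration", "a", "best_fitness", "mean_fitness",
                      "diversity"))
})
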