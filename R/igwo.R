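#' Optimizer settings
#'
#' Configuration shared by the improved grey wolf optimizer and its
#' ablation variants. The three improvement components can be toggled
#' individually: the linearly decaying inertia weight (off substitutes
#' the constant a = 1, the schedule's mean, so the coefficient vectors
#' stay bounded), elite opposition-based learning, and elite retention.
#'
#' `dynamic_weight_factor` (0.9) and `balance_factor` (0.8) are recorded
#' knobs from the source protocol that map to no equation of the update
#' rules; they are stored but inert.
#'
#' @param population_size pack size N (>= 3), default 30.
#' @param max_iterations iteration cap T, default 100.
#' @param elite_opposition_fraction fraction of the pack treated as
#'   opposition elites, default 0.10.
#' @param elite_retention_fraction fraction of a generation guaranteed
#'   survival, default 0.20.
#' @param convergence_tol early-stop tolerance on the best-fitness series,
#'   default 1e-5.
#' @param patience number of consecutive sub-tolerance steps required
#'   before early stop, default 5.
#' @param seed master seed; split into named streams (init, updates,
#'   opposition, levy) so ablations do not shift other components' draws.
#' @param components named logical flags `dynamic_weight`,
#'   `elite_opposition`, `elite_retention` (all TRUE by default).
#' @param opposition_style `"interpolate"` draws opposites between the
#'   elite and the worst member (as the update rule states);
#'   `"reflect"` uses classical opposition 1 - x.
#' @param dynamic_weight_factor,balance_factor recorded, inert.
#' @return Object of class `optimizer_config`.
#' @export
optimizer_config <- function(population_size = 30, max_iterations = 100,
                             elite_opposition_fraction = 0.10,
                             elite_retention_fraction = 0.20,
                             convergence_tol = 1e-5, patience = 5,
                             seed = 1,
                             components = c(dynamic_weight = TRUE,
                                            elite_opposition = TRUE,
                                            elite_retention = TRUE),
                             opposition_style = c("interpolate", "reflect"),
                             dynamic_weight_factor = 0.9,
                             balance_factor = 0.8) {
  stopifnot(
    population_size >= 3, max_iterations >= 1, convergence_tol > 0,
    patience >= 1,
    elite_opposition_fraction > 0, elite_opposition_fraction <= 1,
    elite_retention_fraction > 0, elite_retention_fraction <= 1
  )
  flags <- c(dynamic_weight = TRUE, elite_opposition = TRUE,
             elite_retention = TRUE)
  flags[names(components)] <- components
  structure(
    list(
      population_size = as.integer(population_size),
      max_iterations = as.integer(max_iterations),
      elite_opposition_fraction = elite_opposition_fraction,
      elite_retention_fraction = elite_retention_fraction,
      convergence_tol = convergence_tol,
      patience = as.integer(patience),
      seed = as.integer(seed),
      components = flags,
      opposition_style = match.arg(opposition_style),
      dynamic_weight_factor = dynamic_weight_factor,
      balance_factor = balance_factor
    ),
    class = "optimizer_config"
  )
}

#' Linearly decaying inertia weight
#'
#' `a = 2 - 2 t / T`: starts at 2 (wide exploration, |A| can exceed 1)
#' and decays to 0 at the final iteration (pure exploitation).
#'
#' @param t current iteration, 0 <= t <= T.
#' @param T_max maximum iterations, >= 1.
#' @return The weight a in \[0, 2\].
#' @export
dynamic_weight <- function(t, T_max) {
  if (T_max < 1) stop("T_max must be >= 1")
  if (t < 0 || t > T_max) stop("iteration t must lie in [0, T_max]")
  2 - 2 * t / T_max
}

#' Draw GWO coefficient vectors
#'
#' `A = 2 a r1 - a` and `C = 2 r2` componentwise, with r1, r2 uniform on
#' \[0,1\], so A ranges over \[-a, a\] and C over \[0, 2\].
#'
#' @param a inertia weight in \[0, 2\].
#' @param d dimension.
#' @param stream an [rng_stream()].
#' @return List with components `A` and `C`, each length `d`.
#' @export
coefficient_vectors <- function(a, d, stream) {
  stopifnot(a >= 0, a <= 2, d >= 1)
  r <- stream_do(stream, function() runif(2 * d))
  list(A = 2 * a * r[seq_len(d)] - a, C = 2 * r[d + seq_len(d)])
}

#' Deterministic core of the pack-hierarchy move
#'
#' Given the three leaders and pre-drawn coefficient vectors, computes
#' `D_k = |C_k * X_k - x|`, `X_k' = X_k - A_k * D_k` for each leader and
#' returns the repaired average of the three pulled positions.
#'
#' @param x current position (length d).
#' @param leaders 3 x d matrix: rows are the alpha, beta, delta positions.
#' @param A,C 3 x d matrices of coefficient vectors, row k for leader k.
#' @return The new position, clamped into \[0,1\]^d.
#' @export
gwo_candidate <- function(x, leaders, A, C) {
  stopifnot(nrow(leaders) == 3, nrow(A) == 3, nrow(C) == 3)
  pulled <- matrix(0, 3, length(x))
  for (k in 1:3) {
    D <- abs(C[k, ] * leaders[k, ] - x)
    pulled[k, ] <- leaders[k, ] - A[k, ] * D
  }
  repair(colMeans(pulled))
}

#' One position update guided by the leader triple
#'
#' Draws independent coefficient vectors for each leader from the stream
#' and applies [gwo_candidate()].
#'
#' @param x current position.
#' @param leaders 3 x d matrix of repaired leader positions.
#' @param a inertia weight.
#' @param stream an [rng_stream()].
#' @return Updated, repaired position.
#' @export
update_position <- function(x, leaders, a, stream) {
  d <- length(x)
  A <- matrix(0, 3, d)
  C <- matrix(0, 3, d)
  for (k in 1:3) {
    co <- coefficient_vectors(a, d, stream)
    A[k, ] <- co$A
    C[k, ] <- co$C
  }
  gwo_candidate(x, leaders, A, C)
}

#' Wolf pack container
#'
#' @param positions N x d matrix of repaired candidate positions.
#' @param fitness numeric vector of length N (maximization).
#' @return Object of class `wolf_pack`.
#' @export
new_pack <- function(positions, fitness) {
  positions <- rbind(positions)
  stopifnot(nrow(positions) == length(fitness))
  structure(list(positions = positions, fitness = as.numeric(fitness)),
            class = "wolf_pack")
}

#' Indices of the leader triple (alpha, beta, delta)
#'
#' Top three members by fitness; ties broken by lower member index.
#'
#' @param pack a `wolf_pack`.
#' @return Integer vector of length 3.
#' @export
pack_leaders <- function(pack) {
  order(-pack$fitness, seq_along(pack$fitness))[1:3]
}

#' Opposition point between an elite and the worst member
#'
#' `x_new = x_best + f * (x_worst - x_best)`: at f = 0 the elite itself,
#' at f = 1 the worst member. The `"reflect"` style instead returns the
#' classical opposite `1 - x_best` (f is ignored).
#'
#' @param x_best elite position.
#' @param x_worst worst position.
#' @param f interpolation draw in \[0, 1\].
#' @param style `"interpolate"` (default) or `"reflect"`.
#' @return Repaired opposition point.
#' @export
opposition_point <- function(x_best, x_worst, f,
                             style = c("interpolate", "reflect")) {
  style <- match.arg(style)
  if (style == "reflect") return(repair(1 - x_best))
  repair(x_best + f * (x_worst - x_best))
}

#' Generate opposition candidates for the pack's elites
#'
#' For each of the top `ceiling(fraction * N)` members one opposition
#' point is generated with an independent f ~ U\[0,1\], anchored at the
#' current worst member.
#'
#' @param pack evaluated `wolf_pack`.
#' @param fraction elite fraction.
#' @param stream an [rng_stream()].
#' @param style see [opposition_point()].
#' @return Matrix of opposition candidates (possibly zero rows).
#' @export
elite_opposition <- function(pack, fraction, stream,
                             style = c("interpolate", "reflect")) {
  style <- match.arg(style)
  n <- length(pack$fitness)
  k <- ceiling(fraction * n)
  if (k < 1) {
    message("elite fraction rounds to zero members; no opposition points")
    return(matrix(numeric(0), 0, ncol(pack$positions)))
  }
  ord <- order(-pack$fitness, seq_len(n))
  elites <- pack$positions[ord[seq_len(k)], , drop = FALSE]
  worst <- pack$positions[ord[n], ]
  f <- stream_do(stream, function() runif(k))
  out <- matrix(0, k, ncol(pack$positions))
  for (i in seq_len(k)) {
    out[i, ] <- opposition_point(elites[i, ], worst, f[i], style)
  }
  out
}

#' Merge a generation with retained elites
#'
#' The top `ceiling(fraction * N)` members of the previous pack are
#' guaranteed slots in the next pack; the remaining slots are filled by
#' the best candidate members. Pack size is preserved.
#'
#' @param previous evaluated `wolf_pack` of size N.
#' @param candidates evaluated `wolf_pack` (the updated generation).
#' @param fraction retention fraction.
#' @return The merged `wolf_pack` of size N.
#' @export
elite_retention <- function(previous, candidates, fraction) {
  n <- length(previous$fitness)
  k <- min(n, ceiling(fraction * n))
  ord_prev <- order(-previous$fitness, seq_len(n))[seq_len(k)]
  n_fill <- n - k
  ord_cand <- order(-candidates$fitness, seq_along(candidates$fitness))
  fill <- ord_cand[seq_len(min(n_fill, length(ord_cand)))]
  new_pack(
    rbind(previous$positions[ord_prev, , drop = FALSE],
          candidates$positions[fill, , drop = FALSE]),
    c(previous$fitness[ord_prev], candidates$fitness[fill])
  )
}

#' Termination test
#'
#' Stops at the iteration cap, or when the last `patience` consecutive
#' changes of the best-fitness series all fall below the tolerance
#' (requires at least `patience + 1` recorded iterations).
#'
#' @param f_history numeric vector of per-iteration best fitness (or a
#'   trace data frame with a `best_fitness` column).
#' @param tol convergence tolerance.
#' @param T_max iteration cap.
#' @param patience consecutive sub-tolerance steps required (default 1).
#' @return TRUE if the run should stop.
#' @export
check_termination <- function(f_history, tol, T_max, patience = 1) {
  if (is.data.frame(f_history)) f_history <- f_history$best_fitness
  t <- length(f_history)
  if (t < 1) stop("empty fitness history")
  if (t >= T_max) return(TRUE)
  if (t >= patience + 1) {
    deltas <- abs(diff(f_history))
    if (all(utils::tail(deltas, patience) < tol)) return(TRUE)
  }
  FALSE
}

mean_pairwise_distance <- function(positions) {
  if (nrow(positions) < 2) return(0)
  mean(stats::dist(positions))
}

eval_fitness_all <- function(fitness_fn, positions, iteration) {
  vapply(seq_len(nrow(positions)), function(i) {
    val <- tryCatch(
      fitness_fn(positions[i, ]),
      error = function(e) {
        stop("fitness evaluation failed at iteration ", iteration,
             ", member ", i, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    as.numeric(val)
  }, numeric(1))
}

#' Improved grey wolf optimization
#'
#' Maximizes `fitness_fn` over the normalized unit cube of `space`.
#' Each iteration: compute the inertia weight, move every wolf toward
#' the leader triple, inject opposition points for the elite fraction
#' (each replaces the current worst member only if strictly better),
#' merge with retained elites, refresh the leaders, append a trace
#' record, and test termination. The best-so-far archive is maintained
#' independently of the population, so the reported optimum is monotone
#' in all component ablations.
#'
#' @param fitness_fn function mapping a coordinate vector in \[0,1\]^d to
#'   a scalar fitness (larger is better); must be deterministic given the
#'   run's seed policy.
#' @param space an `hp_space` defining d and the decoding.
#' @param config an [optimizer_config()].
#' @return List of class `igwo_result` with `best_config` (decoded),
#'   `best_fitness`, `best_coords`, `trace` (one row per iteration:
#'   iteration, a, best_fitness, mean_fitness, diversity), `n_evals`.
#' @export
igwo_optimize <- function(fitness_fn, space, config = optimizer_config()) {
  stopifnot(inherits(config, "optimizer_config"))
  N <- config$population_size
  T_max <- config$max_iterations
  streams <- make_streams(config$seed, c("init", "updates", "opposition", "levy"))

  positions <- sample_uniform(space, N, streams$init)
  fitness <- eval_fitness_all(fitness_fn, positions, 0L)
  n_evals <- N
  pack <- new_pack(positions, fitness)
  bi <- pack_leaders(pack)[1]
  best_coords <- pack$positions[bi, ]
  best_fitness <- pack$fitness[bi]

  trace <- vector("list", T_max)
  t_done <- 0L
  for (t in seq_len(T_max)) {
    a <- if (config$components[["dynamic_weight"]]) dynamic_weight(t, T_max) else 1.0
    lead <- pack$positions[pack_leaders(pack), , drop = FALSE]
    d <- ncol(pack$positions)
    cand <- t(matrix(vapply(
      seq_len(N),
      function(i) update_position(pack$positions[i, ], lead, a, streams$updates),
      numeric(d)
    ), nrow = d))
    cand_fit <- eval_fitness_all(fitness_fn, cand, t)
    n_evals <- n_evals + N
    cpack <- new_pack(cand, cand_fit)

    if (config$components[["elite_opposition"]]) {
      opp <- elite_opposition(cpack, config$elite_opposition_fraction,
                              streams$opposition, config$opposition_style)
      if (nrow(opp) > 0) {
        opp_fit <- eval_fitness_all(fitness_fn, opp, t)
        n_evals <- n_evals + nrow(opp)
        for (i in seq_len(nrow(opp))) {
          worst <- which.min(cpack$fitness)
          if (opp_fit[i] > cpack$fitness[worst]) {
            cpack$positions[worst, ] <- opp[i, ]
            cpack$fitness[worst] <- opp_fit[i]
          }
        }
      }
    }

    pack <- if (config$components[["elite_retention"]]) {
      elite_retention(pack, cpack, config$elite_retention_fraction)
    } else {
      cpack
    }

    gi <- pack_leaders(pack)[1]
    if (pack$fitness[gi] > best_fitness) {
      best_fitness <- pack$fitness[gi]
      best_coords <- pack$positions[gi, ]
    }

    trace[[t]] <- data.frame(
      iteration = t, a = a, best_fitness = best_fitness,
      mean_fitness = mean(pack$fitness),
      diversity = mean_pairwise_distance(pack$positions)
    )
    t_done <- t
    hist <- vapply(trace[seq_len(t)], `[[`, numeric(1), "best_fitness")
    if (check_termination(hist, config$convergence_tol, T_max, config$patience)) break
  }

  structure(
    list(
      best_config = decode(space, best_coords),
      best_fitness = best_fitness,
      best_coords = best_coords,
      trace = do.call(rbind, trace[seq_len(t_done)]),
      n_evals = n_evals,
      config = config
    ),
    class = "igwo_result"
  )
}

#' @export
print.igwo_result <- function(x, ...) {
  cat(sprintf("IGWO result: best fitness %.6f after %d iterations (%d evaluations)\n",
              x$best_fitness, nrow(x$trace), x$n_evals))
  invisible(x)
}

#' Global-best particle swarm baseline
#'
#' Canonical PSO with inertia weight 0.7 and acceleration coefficients
#' c1 = c2 = 1.5: `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`,
#' `x <- repair(x + v)`. Same contract, trace and termination rules as
#' [igwo_optimize()].
#'
#' @inheritParams igwo_optimize
#' @param inertia inertia weight, default 0.7.
#' @param c1,c2 acceleration coefficients, default 1.5.
#' @return List of class `igwo_result` (trace column `a` holds the
#'   constant inertia weight).
#' @export
pso_optimize <- function(fitness_fn, space, config = optimizer_config(),
                         inertia = 0.7, c1 = 1.5, c2 = 1.5) {
  N <- config$population_size
  T_max <- config$max_iterations
  d <- space_dim(space)
  streams <- make_streams(config$seed, c("init", "updates"))

  x <- sample_uniform(space, N, streams$init)
  v <- matrix(0, N, d)
  fit <- eval_fitness_all(fitness_fn, x, 0L)
  n_evals <- N
  pbest <- x
  pbest_fit <- fit
  gi <- order(-fit, seq_len(N))[1]
  gbest <- x[gi, ]
  gbest_fit <- fit[gi]

  trace <- vector("list", T_max)
  t_done <- 0L
  for (t in seq_len(T_max)) {
    r <- stream_do(streams$updates, function() {
      list(r1 = matrix(runif(N * d), N, d), r2 = matrix(runif(N * d), N, d))
    })
    v <- inertia * v + c1 * r$r1 * (pbest - x) + c2 * r$r2 * (sweep(-x, 2, gbest, "+"))
    x <- repair(x + v)
    fit <- eval_fitness_all(fitness_fn, x, t)
    n_evals <- n_evals + N
    improved <- fit > pbest_fit
    pbest[improved, ] <- x[improved, , drop = FALSE]
    pbest_fit[improved] <- fit[improved]
    gi <- order(-pbest_fit, seq_len(N))[1]
    if (pbest_fit[gi] > gbest_fit) {
      gbest_fit <- pbest_fit[gi]
      gbest <- pbest[gi, ]
    }
    trace[[t]] <- data.frame(
      iteration = t, a = inertia, best_fitness = gbest_fit,
      mean_fitness = mean(fit), diversity = mean_pairwise_distance(x)
    )
    t_done <- t
    hist <- vapply(trace[seq_len(t)], `[[`, numeric(1), "best_fitness")
    if (check_termination(hist, config$convergence_tol, T_max, config$patience)) break
  }

  structure(
    list(
      best_config = decode(space, gbest),
      best_fitness = gbest_fit,
      best_coords = gbest,
      trace = do.call(rbind, trace[seq_len(t_done)]),
      n_evals = n_evals,
      config = config
    ),
    class = "igwo_result"
  )
}

#' Uniform random-search baseline
#'
#' Evaluates `budget` uniform candidates and returns the argmax. Under a
#' fixed seed the candidate stream is a prefix of any larger budget's, so
#' the best fitness is non-decreasing in the budget.
#'
#' @param fitness_fn as in [igwo_optimize()].
#' @param space an `hp_space`.
#' @param budget number of evaluations (>= 1).
#' @param seed integer seed.
#' @return List with `best_config`, `best_fitness`, `best_coords`.
#' @export
random_search <- function(fitness_fn, space, budget, seed = 1) {
  if (budget < 1) stop("budget must be >= 1")
  s <- rng_stream(seed)
  cand <- sample_uniform(space, budget, s)
  fit <- eval_fitness_all(fitness_fn, cand, 0L)
  bi <- order(-fit, seq_len(budget))[1]
  list(
    best_config = decode(space, cand[bi, ]),
    best_fitness = fit[bi],
    best_coords = cand[bi, ]
  )
}

#' Mantegna Levy-flight steps
#'
#' Heavy-tailed step proposals with stability index `beta`:
#' `step = scale * u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`,
#' `v ~ N(0, 1)`.
#'
#' @param n number of steps.
#' @param stream an [rng_stream()].
#' @param beta stability index, default 1.5.
#' @param scale step scale relative to the unit cube, default 0.1.
#' @return Numeric vector of n steps.
#' @export
levy_step <- function(n, stream, beta = 1.5, scale = 0.1) {
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  stream_do(stream, function() {
    u <- stats::rnorm(n, 0, sigma_u)
    v <- stats::rnorm(n)
    scale * u / abs(v)^(1 / beta)
  })
}

#' Binary feature selection with the masked grey wolf search
#'
#' Wolves move in `[0,1]^p`; a position is thresholded at 0.5 into a
#' feature mask before fitness evaluation. Initialization adds Levy
#' flight perturbations to the uniform start; each wolf's move length is
#' rescaled by a Cauchy mutation whose scale decays as `1 - t/T`. A mask
#' that thresholds to all zeros is repaired by activating one uniformly
#' random feature.
#'
#' @param fitness_fn function mapping a 0/1 mask of length `n_features`
#'   to a scalar fitness (larger is better).
#' @param n_features number of candidate features (>= 1).
#' @param config an [optimizer_config()].
#' @return List with `mask` (the best 0/1 vector), `fitness`, and `trace`.
#' @export
select_features <- function(fitness_fn, n_features, config = optimizer_config()) {
  if (n_features < 1) stop("n_features must be >= 1")
  if (n_features == 1) {
    return(list(mask = 1L, fitness = fitness_fn(1L), trace = NULL))
  }
  N <- config$population_size
  T_max <- config$max_iterations
  streams <- make_streams(config$seed, c("init", "updates", "opposition", "levy"))

  to_mask <- function(x) {
    m <- as.integer(x > 0.5)
    if (all(m == 0)) {
      j <- stream_do(streams$levy, function() sample.int(n_features, 1))
      m[j] <- 1L
    }
    m
  }

  positions <- stream_do(streams$init, function() {
    matrix(runif(N * n_features), N, n_features)
  })
  positions <- repair(positions + matrix(levy_step(N * n_features, streams$levy),
                                         N, n_features))
  masks <- lapply(seq_len(N), function(i) to_mask(positions[i, ]))
  fitness <- vapply(masks, function(m) as.numeric(fitness_fn(m)), numeric(1))
  pack <- new_pack(positions, fitness)
  bi <- pack_leaders(pack)[1]
  best_mask <- masks[[bi]]
  best_fitness <- fitness[bi]

  trace <- vector("list", T_max)
  t_done <- 0L
  for (t in seq_len(T_max)) {
    a <- if (config$components[["dynamic_weight"]]) dynamic_weight(t, T_max) else 1.0
    lead <- pack$positions[pack_leaders(pack), , drop = FALSE]
    gamma_t <- 1 - t / T_max
    new_masks <- vector("list", N)
    cand <- matrix(0, N, n_features)
    for (i in seq_len(N)) {
      move <- update_position(pack$positions[i, ], lead, a, streams$updates)
      s <- stream_do(streams$updates, function() abs(1 + gamma_t * stats::rcauchy(1)))
      s <- min(s, 2)
      cand[i, ] <- repair(pack$positions[i, ] + s * (move - pack$positions[i, ]))
      new_masks[[i]] <- to_mask(cand[i, ])
    }
    cand_fit <- vapply(new_masks, function(m) as.numeric(fitness_fn(m)), numeric(1))
    cpack <- new_pack(cand, cand_fit)
    pack <- if (config$components[["elite_retention"]]) {
      elite_retention(pack, cpack, config$elite_retention_fraction)
    } else {
      cpack
    }
    gi <- pack_leaders(pack)[1]
    if (pack$fitness[gi] > best_fitness) {
      best_fitness <- pack$fitness[gi]
      best_mask <- to_mask(pack$positions[gi, ])
    }
    trace[[t]] <- data.frame(
      iteration = t, a = a, best_fitness = best_fitness,
      mean_fitness = mean(pack$fitness),
      diversity = mean_pairwise_distance(pack$positions)
    )
    t_done <- t
    hist <- vapply(trace[seq_len(t)], `[[`, numeric(1), "best_fitness")
    if (check_termination(hist, config$convergence_tol, T_max, config$patience)) break
  }

  list(mask = best_mask, fitness = best_fitness,
       trace = do.call(rbind, trace[seq_len(t_done)]))
}

#' Write an optimization trace as JSON lines
#'
#' One JSON object per completed iteration.
#'
#' @param trace the trace data frame of an `igwo_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_jsonl <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(trace))) {
    writeLines(jsonlite::toJSON(as.list(trace[i, ]), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
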