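#' Hyperparameter search space
#'
#' The optimizer moves candidates through the normalized unit cube
#' `[0,1]^d`; a space object records how each coordinate maps back to a
#' classifier setting. Integer dimensions decode by rounding an affine
#' map of the coordinate onto `[lower, upper]`; continuous dimensions use
#' the affine map directly. A bound can be open, in which case decoded
#' values are nudged inside by a small epsilon.
#'
#' @param dims a list of dimension descriptions, each a list with fields
#'   `name`, `kind` (`"integer"` or `"continuous"`), `lower`, `upper`,
#'   and optionally `open_lower` / `open_upper` (default closed).
#' @return An object of class `hp_space`.
#' @seealso [default_space()] for the random-forest tuning domain.
#' @export
hp_space <- function(dims) {
  stopifnot(is.list(dims), length(dims) >= 1)
  dims <- lapply(dims, function(d) {
    stopifnot(!is.null(d$name), !is.null(d$kind), !is.null(d$lower), !is.null(d$upper))
    if (!d$kind %in% c("integer", "continuous")) {
      stop("dimension kind must be 'integer' or 'continuous', got: ", d$kind)
    }
    if (!(d$lower < d$upper)) {
      stop("dimension '", d$name, "': lower bound must be strictly below upper bound")
    }
    d$open_lower <- isTRUE(d$open_lower)
    d$open_upper <- isTRUE(d$open_upper)
    d
  })
  structure(list(dims = dims), class = "hp_space")
}

#' @export
print.hp_space <- function(x, ...) {
  cat("Hyperparameter space (", length(x$dims), " dimensions)\n", sep = "")
  for (d in x$dims) {
    cat(sprintf(
      "  %-14s %-10s %s%g, %g%s\n", d$name, d$kind,
      if (d$open_lower) "(" else "[", d$lower, d$upper,
      if (d$open_upper) ")" else "]"
    ))
  }
  invisible(x)
}

#' Default random-forest tuning domain
#'
#' Three dimensions: ensemble size `n_trees` on the integers 50..200,
#' tree depth cap `max_depth` on 5..15, and the per-split feature
#' sampling fraction `p_features` on the half-open interval (0.3, 0.8].
#' The minimum leaf size is a fixed setting of the classifier (5), not a
#' searched dimension.
#'
#' @return An `hp_space` with the three dimensions above.
#' @export
default_space <- function() {
  hp_space(list(
    list(name = "n_trees", kind = "integer", lower = 50, upper = 200),
    list(name = "max_depth", kind = "integer", lower = 5, upper = 15),
    list(name = "p_features", kind = "continuous", lower = 0.3, upper = 0.8,
         open_lower = TRUE)
  ))
}

#' Read a search space from a YAML file
#'
#' The file holds a `dims` list; each entry has `name`, `kind`, `lower`,
#' `upper` and optional `open_lower`/`open_upper` flags.
#'
#' @param path path to a YAML file.
#' @return An `hp_space`.
#' @export
space_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$dims)) stop("YAML space file must contain a 'dims' list")
  hp_space(cfg$dims)
}

#' Number of dimensions of a space
#' @param space an `hp_space`.
#' @return Integer dimension count.
#' @export
space_dim <- function(space) {
  stopifnot(inherits(space, "hp_space"))
  length(space$dims)
}

#' Draw uniform candidates in the unit cube
#'
#' Each coordinate is drawn independently from U\[0,1\]; rows are
#' candidates, columns are named after the space's dimensions.
#'
#' @param space an `hp_space`.
#' @param n number of candidates (>= 1).
#' @param stream an [rng_stream()] supplying the draws.
#' @return An `n` x `d` numeric matrix of coordinates in \[0,1\].
#' @export
sample_uniform <- function(space, n, stream) {
  stopifnot(inherits(space, "hp_space"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a count >= 1")
  }
  d <- space_dim(space)
  # row-major fill: candidate i consumes draws (i-1)*d+1 .. i*d, so under a
  # fixed seed a smaller budget's candidates are a prefix of a larger one's
  m <- stream_do(stream, function() {
    matrix(runif(n * d), nrow = n, ncol = d, byrow = TRUE)
  })
  colnames(m) <- vapply(space$dims, `[[`, character(1), "name")
  m
}

#' Clamp a candidate into the unit cube
#'
#' Boundary repair by coordinate-wise clamping to \[0,1\]. Idempotent;
#' feasible candidates are returned unchanged.
#'
#' @param v numeric vector (or matrix of row candidates).
#' @return The repaired vector or matrix.
#' @export
repair <- function(v) {
  pmin(pmax(v, 0), 1)
}

#' Decode a unit-cube candidate into classifier settings
#'
#' Integer dimensions map to `round(lower + coord * (upper - lower))`;
#' continuous dimensions use the affine map without rounding. An open
#' lower (upper) bound is enforced by nudging a decoded value sitting on
#' it inward by 1e-9. When the space carries the default dimension names
#' the result is returned as an [rf_config()] (with the fixed leaf size);
#' otherwise a plain named list.
#'
#' @param space an `hp_space`.
#' @param v numeric coordinate vector, already repaired into \[0,1\].
#' @return An `rf_config` or named list of decoded values.
#' @export
decode <- function(space, v) {
  stopifnot(inherits(space, "hp_space"))
  v <- as.numeric(v)
  if (length(v) != space_dim(space)) {
    stop("candidate has ", length(v), " coordinates but space has ", space_dim(space))
  }
  if (any(v < 0 | v > 1)) {
    stop("candidate coordinates must lie in [0,1]; call repair() first")
  }
  eps <- 1e-9
  vals <- vector("list", length(v))
  nms <- character(length(v))
  for (k in seq_along(v)) {
    d <- space$dims[[k]]
    x <- d$lower + v[k] * (d$upper - d$lower)
    if (d$kind == "integer") x <- round(x)
    if (d$open_lower && x <= d$lower) x <- d$lower + eps
    if (d$open_upper && x >= d$upper) x <- d$upper - eps
    vals[[k]] <- x
    nms[k] <- d$name
  }
  names(vals) <- nms
  if (setequal(nms, c("n_trees", "max_depth", "p_features"))) {
    return(rf_config(
      n_trees = vals$n_trees, max_depth = vals$max_depth,
      p_features = vals$p_features
    ))
  }
  vals
}

#' Random-forest configuration
#'
#' The tuned settings of the forest: ensemble size, depth cap and the
#' fraction of features sampled at each split, plus the fixed minimum
#' leaf size.
#'
#' @param n_trees number of trees, in \[50, 200\].
#' @param max_depth maximum tree depth, in \[5, 15\].
#' @param p_features fraction of features drawn per split, in (0.3, 0.8].
#' @param min_samples_leaf minimum observations per leaf (fixed default 5).
#' @param check validate the tuned-domain bounds (default TRUE). Baseline
#'   configurations outside the tuned domain can switch this off.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees, max_depth, p_features, min_samples_leaf = 5,
                      check = TRUE) {
  n_trees <- as.integer(round(n_trees))
  max_depth <- as.integer(round(max_depth))
  if (check) {
    if (n_trees < 50 || n_trees > 200) stop("n_trees must lie in [50, 200]")
    if (max_depth < 5 || max_depth > 15) stop("max_depth must lie in [5, 15]")
    if (p_features <= 0.3 || p_features > 0.8) {
      stop("p_features must lie in (0.3, 0.8]")
    }
  }
  structure(
    list(
      n_trees = n_trees, max_depth = max_depth,
      p_features = as.numeric(p_features),
      min_samples_leaf = as.integer(min_samples_leaf)
    ),
    class = "rf_config"
  )
}

#' @export
print.rf_config <- function(x, ...) {
  cat(sprintf(
    "RF config: n_trees = %d, max_depth = %d, p_features = %.4f, min_samples_leaf = %d\n",
    x$n_trees, x$max_depth, x$p_features, x$min_samples_leaf
  ))
  invisible(x)
}
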