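#' Named, reproducible random-number streams
#'
#' A run of the optimizer draws random numbers for several logically
#' independent purposes (population initialization, position updates,
#' opposition sampling, ...). Each purpose gets its own stream so that
#' switching one component off does not shift the draws consumed by the
#' others. A stream is an environment carrying a saved `.Random.seed`
#' state; drawing from a stream swaps that state in, draws, and swaps the
#' caller's state back.
#'
#' @param seed integer seed for the stream.
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Evaluate a thunk under a stream's RNG state
#'
#' @param stream an [rng_stream()].
#' @param fn a zero-argument function using R's RNG.
#' @return The value of `fn()`; the stream's state is advanced.
#' @export
stream_do <- function(stream, fn) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}

#' Split a master seed into named independent streams
#'
#' Sub-seeds are drawn from the master seed, one per requested name, and
#' kept within the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param names character vector of stream names.
#' @return Named list of `rng_stream` objects.
#' @export
make_streams <- function(seed, names) {
  master <- rng_stream(seed)
  sub <- stream_do(master, function() sample.int(.Machine$integer.max, length(names)))
  out <- lapply(sub, rng_stream)
  names(out) <- names
  out
}
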