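#' Named, isolated random streams
#'
#' Every stochastic role in the pipeline (cropping, flipping, blurring,
#' within-class permutation, pool sampling, parameter initialisation, ...)
#' draws from its own named stream, derived deterministically from a base
#' seed and the stream name. Streams are isolated from each other and from
#' the global RNG, so disabling one role (e.g. the permutation at
#' \code{alpha = 0}) leaves every other draw untouched. This is what makes
#' the reduction of the permuted pipeline to the vanilla two-view pipeline
#' testable bit-for-bit.
#'
#' @param seed integer base seed.
#' @param name character stream name.
#' @return an environment holding the stream's RNG state.
#' @export
rng_stream <- function(seed, name = "default") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- derive_seed(seed, name)
  e <- new.env(parent = emptyenv())
  e$name <- name
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(s)
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Derive a child seed from a base seed and a stream name
#'
#' A small multiplicative string hash folded into the base seed; the result
#' is always a positive integer below 2^31 so it is a valid \code{set.seed}
#' argument.
#'
#' @param seed integer base seed.
#' @param name character stream name.
#' @return integer in [1, 2147480009].
#' @export
derive_seed <- function(seed, name) {
  m <- 2147480009 # prime below 2^31
  h <- 0
  for (ch in utf8ToInt(as.character(name))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(((abs(seed) %% m) * 48271 + h) %% m + 1)
}

with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Draw uniforms from a named stream
#' @param stream an \code{rng_stream}.
#' @param n number of draws.
#' @param min,max range.
#' @return numeric vector of length \code{n}.
#' @export
stream_runif <- function(stream, n, min = 0, max = 1) {
  with_stream(stream, stats::runif(n, min, max))
}

#' Draw normals from a named stream
#' @inheritParams stream_runif
#' @param mean,sd distribution parameters.
#' @export
stream_rnorm <- function(stream, n, mean = 0, sd = 1) {
  with_stream(stream, stats::rnorm(n, mean, sd))
}

#' Sample indices from a named stream
#' @inheritParams stream_runif
#' @param x vector (or upper bound) passed to \code{sample}.
#' @param size sample size.
#' @param replace sample with replacement?
#' @export
stream_sample <- function(stream, x, size = length(x), replace = FALSE) {
  with_stream(stream, sample(x, size, replace = replace))
}

stream_sample_int <- function(stream, n, size) {
  if (size == 0L) return(integer(0))
  with_stream(stream, sample.int(n, size))
}

#' Bundle of per-role streams for the view-generation pipeline
#'
#' @param seed base seed.
#' @return list with streams \code{crop}, \code{flip}, \code{blur},
#'   \code{perm}, \code{affine}.
#' @export
view_rng <- function(seed) {
  list(
    crop   = rng_stream(seed, "view/crop"),
    flip   = rng_stream(seed, "view/flip"),
    blur   = rng_stream(seed, "view/blur"),
    perm   = rng_stream(seed, "view/perm"),
    affine = rng_stream(seed, "view/affine")
  )
}
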