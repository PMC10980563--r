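# Internal utilities: deterministic RNG substreams and small helpers.
#
# The simulator needs many independent, individually reproducible random
# streams (one per flow-cell channel, one per read for signal noise) so that
# client actions on one channel never perturb draws on another. Base R has a
# single global RNG, so each stream owns a saved .Random.seed snapshot that is
# swapped in around every draw.

#' Create a deterministic random stream
#'
#' @param seed integer seed for this stream.
#' @return an object of class `rng_stream`.
#' @keywords internal
rng_stream <- function(seed) {
  seed <- as.integer(as.double(seed) %% 2147483647)
  old <- get0(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$state <- get(".Random.seed", envir = .GlobalEnv)
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = .GlobalEnv)
  } else {
    rm(".Random.seed", envir = .GlobalEnv)
  }
  class(st) <- "rng_stream"
  st
}

#' Derive a child stream seed from a master seed and an index
#'
#' Distinct (seed, index) pairs map to distinct 31-bit seeds via an LCG-style
#' mix; results stay below 2^31 so they are valid R integer seeds.
#' @keywords internal
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  x <- (as.double(master_seed) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + (as.double(index) %% m) * 16807) %% m
  x <- (x * 69621) %% m
  x
}

# Evaluate fn() with the stream's RNG state active, then save it back.
rng_do <- function(rs, fn) {
  old <- get0(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  assign(".Random.seed", rs$state, envir = .GlobalEnv)
  on.exit({
    rs$state <- get(".Random.seed", envir = .GlobalEnv)
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  fn()
}

rng_runif <- function(rs, n = 1L, min = 0, max = 1) {
  rng_do(rs, function() stats::runif(n, min, max))
}

rng_rnorm <- function(rs, n = 1L, mean = 0, sd = 1) {
  rng_do(rs, function() stats::rnorm(n, mean, sd))
}

rng_rgamma <- function(rs, n = 1L, shape, rate) {
  rng_do(rs, function() stats::rgamma(n, shape = shape, rate = rate))
}

rng_rexp <- function(rs, n = 1L, rate = 1) {
  rng_do(rs, function() stats::rexp(n, rate))
}

rng_rgeom <- function(rs, n = 1L, prob) {
  rng_do(rs, function() stats::rgeom(n, prob))
}

rng_sample_int <- function(rs, n, size = 1L, prob = NULL, replace = FALSE) {
  rng_do(rs, function() sample.int(n, size = size, prob = prob, replace = replace))
}

# Integer in [0, n), one variate.
rng_unif_int <- function(rs, n) {
  as.integer(floor(rng_runif(rs) * n)) %% as.integer(n)
}

#' Draw an RFC-4122-shaped version-4 UUID string from a stream
#' @keywords internal
rng_uuid <- function(rs) {
  b <- as.integer(floor(rng_runif(rs, 16L) * 256)) %% 256L
  b[7] <- bitwOr(bitwAnd(b[7], 15L), 64L)   # version 4
  b[9] <- bitwOr(bitwAnd(b[9], 63L), 128L)  # variant 10xx
  h <- format(as.hexmode(b), width = 2)
  paste0(
    paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
    paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
    paste(h[11:16], collapse = "")
  )
}

# Reverse complement of a plain character string over ACGT.
revcomp_chr <- function(s) {
  if (!nzchar(s)) return(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
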