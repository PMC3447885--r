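# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
# All synthetic-data generators funnel their randomness through this so that
# an identical seed yields byte-identical artifacts.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# sample() without the length-1 surprise
sample_int <- function(x, size) x[sample.int(length(x), size)]

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

# angle at vertex b of the triple a-b-c, degrees
angle_deg <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
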