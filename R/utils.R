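# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All exported stochastic functions funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stage/neuron seed from a root seed; keeps results reproducible from
# one user-supplied integer while decorrelating RNG streams. Stays < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 1000003 * as.double(index)) %%
               2147483647)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Run-length view of a logical vector: data.frame of maximal TRUE runs
# (1-based inclusive frame indices).
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
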