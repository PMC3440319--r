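# Internal helpers shared across modules.

# Evaluate `expr` with a locally seeded RNG, restoring the caller's RNG state.
# All randomized operations in the package route through this so a single seed
# argument makes them reproducible without clobbering the session RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage seed from a global seed so that toggling one pipeline
# stage does not perturb the random streams of the others.  Kept below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 7919 * h) %% 2147483647)
}

# Exact #{v >= t} for a sorted-ascending numeric vector and a vector of
# thresholds; ties count as exceedances.
count_ge_sorted <- function(v_sorted, thresholds) {
  length(v_sorted) - findInterval(thresholds, v_sorted, left.open = TRUE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Binary group membership from a two-level label vector; returns a logical
# vector marking the second ("case") level.
as_two_level <- function(labels, n) {
  f <- as.factor(labels)
  if (nlevels(f) != 2L) {
    abort(sprintf("labels must have exactly 2 levels, got %d", nlevels(f)))
  }
  if (length(f) != n) {
    abort(sprintf("labels length (%d) does not match number of samples (%d)", length(f), n))
  }
  f
}
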