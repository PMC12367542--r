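# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing stochastic functions funnel their `seed` argument through
# here so the global RNG stream is never disturbed.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a base seed and stream indices; keeps every
# sub-computation independently reproducible while staying under 2^31.
child_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed %% 2147483647L)
  for (i in idx) {
    x <- (x * 48271 + as.double(i)) %% 2147483647
  }
  as.integer(x)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s.", name, format(lower)))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s.", name, format(lower)))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s.", name, format(upper)))
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}
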