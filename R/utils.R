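# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes through this so that
# results are pure functions of their arguments (including the seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Scalar validation helpers ---------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %g is outside its valid range", name, x), call. = FALSE)
  }
  invisible(x)
}

check_binary_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", name), call. = FALSE)
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1, FALSE, TRUE))) {
    stop(sprintf("`%s` must be binary (0/1 or logical)", name), call. = FALSE)
  }
  invisible(mask)
}

as_binary <- function(mask) {
  m <- (mask != 0) * 1L
  dim(m) <- dim(mask)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
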