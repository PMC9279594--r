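# Internal helpers shared across modules.

# Stop with a consistent error class so callers/tests can distinguish
# user-input problems from programming errors.
abort_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("senesceq_input_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input(name, " must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    abort_input(name, " must be > ", lower)
  }
  if (!strict_lower && x < lower) {
    abort_input(name, " must be >= ", lower)
  }
  if (x > upper) abort_input(name, " must be <= ", upper)
  invisible(x)
}

assert_proportion <- function(x, name) {
  assert_scalar_number(x, name, lower = 0, upper = 1)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    abort_input(name, " must be a single integer")
  }
  if (x < lower) abort_input(name, " must be >= ", lower)
  invisible(as.integer(x))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators are deterministic without side effects.
with_seed <- function(seed, expr) {
  assert_count(seed, "seed")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
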