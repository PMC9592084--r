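# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_invalid("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_invalid("`%s` must be >= %g (got %g)", name, lower, x)
  if (strict_upper && x >= upper)
    stop_invalid("`%s` must be < %g (got %g)", name, upper, x)
  if (!strict_upper && x > upper)
    stop_invalid("`%s` must be <= %g (got %g)", name, upper, x)
  as.numeric(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_invalid("`%s` must be TRUE or FALSE", name)
  x
}

is_uniform_grid <- function(x, rel_tol = 1e-8) {
  d <- diff(x)
  if (any(d <= 0)) return(FALSE)
  max(abs(d - mean(d))) <= rel_tol * mean(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
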