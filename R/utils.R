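#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  if (integer && x != round(x))
    stopf("`%s` must be an integer, got %s", name, x)
  invisible(x)
}

# All randomness flows through explicit seeds; callers' RNG state is restored.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    assert_scalar_num(seed, "seed", integer = TRUE)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, k) {
  (as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629
}

is_stack3d <- function(x) is.array(x) && length(dim(x)) == 3L
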