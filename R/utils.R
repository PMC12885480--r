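# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stopf("invalid parameter: `%s` must be finite numeric", name)
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps voxelwise fits reproducible without perturbing the session stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a 32-bit-safe per-voxel seed from a base seed and a linear index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483647L)
}

# Lower median: for even n, the smaller of the two central order statistics.
# Deterministic tie-break used when fixing the time shift in two-step fitting.
median_lower <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[[ceiling(n / 2)]]
}
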