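# Internal helpers shared across modules.

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit. seed = NULL leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero at `digits` decimals (base round() is half-even).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a bounded child seed from a master seed and a stage offset.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647)
}

stopIfNot01 <- function(p, what = "p-values") {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop(what, " must lie in [0, 1]")
  invisible(p)
}

# Median of each row of a matrix (thin wrapper so the dependency is one place).
rowMeds <- function(x) matrixStats::rowMedians(x)
colMeds <- function(x) matrixStats::colMedians(x)
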