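# Internal numerical and RNG helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable.  Returns -Inf when a == b.
logdiffexp <- function(a, b) {
  if (b > a) stop("logdiffexp: requires a >= b")
  if (b == a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream: generators must be pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Fold an allele-2 frequency onto the minor-allele scale [0, 0.5].
fold_maf <- function(f) pmin(f, 1 - f)

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("%s must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
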