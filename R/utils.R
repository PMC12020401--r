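# Internal numerical helpers shared across modules.

#' @importFrom stats rnorm runif median quantile cov aggregate setNames
NULL

## Symmetric positive-definite matrix powers via eigendecomposition.
## Used for whitening (power = -1/2); eigenvalues are clamped at `floor`
## so that a barely-PD covariance never produces Inf.
.spd_power <- function(S, power, floor = 1e-12) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% (vals^power * t(e$vectors))
}

## Run `expr` with a local RNG state seeded at `seed`, restoring the
## caller's state afterwards. Keeps generators pure functions of their spec.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a stream-specific child seed from a parent seed; stays < 2^31.
.child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 7919) %% 2147483647
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
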