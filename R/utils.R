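# Internal numerical helpers.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards so simulation calls do not perturb
## the global stream.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% (.Machine$integer.max - 1L)))
  expr
}

## Stationary AR(1) with unit marginal variance, lag-1 coefficient phi.
## Returns an n x k matrix (one series per column); a 50-step burn-in from a
## zero state brings each series to (numerical) stationarity.
arUnitSeries <- function(n, k, phi) {
  stopifnot(abs(phi) < 1)
  burn <- 50L
  innov <- matrix(rnorm((n + burn) * k, sd = sqrt(1 - phi^2)), n + burn, k)
  if (phi == 0) return(innov[(burn + 1L):(burn + n), , drop = FALSE])
  x <- stats::filter(innov, phi, method = "recursive")
  matrix(as.numeric(x), n + burn, k)[(burn + 1L):(burn + n), , drop = FALSE]
}

## OLS residuals of each column of Y on a single regressor g (with
## intercept). Degenerate g (zero variance) falls back to mean-centering.
residualizeColumns <- function(Y, g) {
  Y <- as.matrix(Y)
  if (length(g) != nrow(Y))
    stop("regressor length does not match number of rows")
  if (stats::var(g) <= .Machine$double.eps * max(1, mean(g^2))) {
    return(sweep(Y, 2L, colMeans(Y)))
  }
  gc <- g - mean(g)
  beta <- crossprod(gc, sweep(Y, 2L, colMeans(Y))) / sum(gc^2)
  sweep(Y, 2L, colMeans(Y)) - outer(gc, drop(beta))
}

checkFiniteField <- function(value, field) {
  if (!all(is.finite(value)))
    stop("non-finite value in field '", field, "'", call. = FALSE)
  invisible(value)
}
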