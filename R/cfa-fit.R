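# Maximum-likelihood estimation of the confirmatory factor model, fit
# indices, score-test modification indices, and regression-method factor
# scores. The ML discrepancy is
#   F_ML = log|Sigma(theta)| - log|S| + tr(S Sigma(theta)^-1) - p,
# minimized over free loadings, residual (co)variances and factor
# correlations under unit-factor-variance identification.

## Implied covariance Sigma = Lambda Phi Lambda' + Theta.
impliedSigma <- function(lambda, phi, theta)
  lambda %*% phi %*% t(lambda) + theta

## ML discrepancy between sample covariance S and implied Sigma; Inf when
## Sigma is not positive definite.
mlDiscrepancy <- function(S, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  p <- nrow(S)
  ldSigma <- 2 * sum(log(diag(ch)))
  ldS <- determinant(S, logarithm = TRUE)$modulus
  siginv <- chol2inv(ch)
  as.numeric(ldSigma - ldS + sum(S * siginv) - p)
}

## Factor correlation matrix from 6 unconstrained parameters: rows of a
## lower-triangular factor are (r_1, ..., r_{i-1}, 1) normalized to unit
## length, giving a positive-definite correlation matrix for any input.
phiFromRaw <- function(raw, m) {
  L <- diag(m)
  idx <- 0L
  for (i in seq_len(m)[-1L]) {
    v <- c(raw[idx + seq_len(i - 1L)], 1)
    L[i, seq_len(i)] <- v / sqrt(sum(v^2))
    idx <- idx + i - 1L
  }
  tcrossprod(L)
}

## Inverse map for starting values: raw parameters reproducing (approximately
## or exactly) a given correlation matrix.
rawFromPhi <- function(phi) {
  L <- t(chol(phi))
  unlist(lapply(seq_len(nrow(phi))[-1L],
                function(i) L[i, seq_len(i - 1L)] / L[i, i]))
}

## Parameter packing: [lambda (p), log theta_diag (p), phi raw (m(m-1)/2),
## theta off-diagonals (k)].
unpackParams <- function(par, spec) {
  p <- length(spec@indicators)
  m <- length(spec@factors)
  k <- nrow(spec@residualCovariances)
  lambdaVec <- par[seq_len(p)]
  logTheta <- par[p + seq_len(p)]
  phiRaw <- par[2L * p + seq_len(m * (m - 1L) / 2L)]
  thOff <- if (k) par[2L * p + m * (m - 1L) / 2L + seq_len(k)] else numeric()
  lambda <- matrix(0, p, m, dimnames = list(spec@indicators, spec@factors))
  lambda[cbind(seq_len(p), match(spec@loadingPattern[spec@indicators],
                                 spec@factors))] <- lambdaVec
  theta <- diag(exp(logTheta), p)
  dimnames(theta) <- list(spec@indicators, spec@indicators)
  if (k) for (r in seq_len(k)) {
    i <- spec@residualCovariances[r, 1L]
    j <- spec@residualCovariances[r, 2L]
    theta[i, j] <- theta[j, i] <- thOff[r]
  }
  list(lambda = lambda, phi = phiFromRaw(phiRaw, m), theta = theta,
       phiRaw = phiRaw)
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the ML discrepancy between the sample covariance of the
#' indicators and the implied covariance `Lambda Phi Lambda' + Theta`,
#' under unit-variance factors with all loadings free. Fit statistics
#' follow the standard ML conventions: `chisq = (n - 1) * F_ML` (the
#' multiplier is configurable to `n`), `RMSEA =
#' sqrt(max(chisq - df, 0) / (df (n - 1)))`, CFI against the independence
#' baseline, and SRMR as the root mean squared standardized residual over
#' the `p(p+1)/2` unique covariance elements.
#'
#' Optimization is quasi-Newton with analytic gradients for loadings and
#' residual (co)variances (numeric for the factor-correlation
#' parameterization) from deterministic default starts; a second start and
#' a BFGS polish guard against local minima. Residual variances are kept
#' positive by a log parameterization with a small floor; solutions at the
#' floor are flagged as Heywood cases.
#'
#' @param spec a [FactorModelSpec-class].
#' @param data subjects x indicators data.frame or matrix (columns must
#'   include the spec's indicators; incomplete rows are dropped listwise).
#'   Alternatively supply `S` and `n` directly.
#' @param S optional sample covariance matrix (used when `data` is NULL).
#' @param n sample size (required with `S`).
#' @param chisqMultiplier `"n-1"` (default) or `"n"`.
#' @return a [FittedFactorModel-class].
#' @examples
#' spec <- cohortSpec(nSubjects = 300, seed = 7)
#' sim <- generatePhenotypes(spec)
#' sc <- generateTaskScores(spec, sim$truth)$scores
#' dat <- reverseCode(sc[-1], EF_TIMED_INDICATORS)
#' fit <- fitMl(efFactorModel(), dat)
#' fitIndices(fit)
#' @export
fitMl <- function(spec, data = NULL, S = NULL, n = NULL,
                  chisqMultiplier = c("n-1", "n")) {
  chisqMultiplier <- match.arg(chisqMultiplier)
  validObject(spec)
  p <- length(spec@indicators)
  m <- length(spec@factors)
  k <- nrow(spec@residualCovariances)
  if (!is.null(data)) {
    data <- as.data.frame(data, check.names = FALSE)
    missing <- setdiff(spec@indicators, colnames(data))
    if (length(missing))
      stop("data lacks indicator column(s): ", paste(missing, collapse = ", "))
    X <- as.matrix(data[spec@indicators])
    X <- X[stats::complete.cases(X), , drop = FALSE]
    n <- nrow(X)
    if (n <= p) stop("need more subjects than indicators")
    mu <- colMeans(X)
    S <- stats::cov(X)
  } else {
    if (is.null(S) || is.null(n)) stop("supply data, or S together with n")
    S <- as.matrix(S)
    if (is.null(rownames(S))) dimnames(S) <- list(spec@indicators,
                                                  spec@indicators)
    S <- S[spec@indicators, spec@indicators]
    mu <- setNames(rep(0, p), spec@indicators)
  }
  if (inherits(tryCatch(chol(S), error = identity), "error"))
    stop("sample covariance is not positive definite")
  df <- modelDf(spec)
  mult <- if (chisqMultiplier == "n-1") n - 1 else n

  sdj <- sqrt(diag(S))
  nphi <- m * (m - 1L) / 2L
  lower <- c(rep(-Inf, p), log(1e-6 * diag(S)), rep(-Inf, nphi + k))
  makeStart <- function(lamFrac, thFrac, rho) {
    phi0 <- matrix(rho, m, m); diag(phi0) <- 1
    c(lamFrac * sdj, log(thFrac * diag(S)), rawFromPhi(phi0), rep(0, k))
  }

  objective <- function(par) {
    est <- unpackParams(par, spec)
    mlDiscrepancy(S, impliedSigma(est$lambda, est$phi, est$theta))
  }
  gradient <- function(par) {
    est <- unpackParams(par, spec)
    sigma <- impliedSigma(est$lambda, est$phi, est$theta)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(par)))
    siginv <- chol2inv(ch)
    A <- siginv - siginv %*% S %*% siginv
    dimnames(A) <- dimnames(S)
    ALP <- A %*% est$lambda %*% est$phi
    fidx <- match(spec@loadingPattern[spec@indicators], spec@factors)
    gLambda <- 2 * ALP[cbind(seq_len(p), fidx)]
    gLogTheta <- diag(A) * diag(est$theta)
    gPhi <- vapply(seq_len(nphi), function(q) {
      h <- 1e-6
      rp <- est$phiRaw; rm <- est$phiRaw
      rp[q] <- rp[q] + h; rm[q] <- rm[q] - h
      (mlDiscrepancy(S, impliedSigma(est$lambda, phiFromRaw(rp, m),
                                     est$theta)) -
       mlDiscrepancy(S, impliedSigma(est$lambda, phiFromRaw(rm, m),
                                     est$theta))) / (2 * h)
    }, numeric(1))
    gOff <- if (k) vapply(seq_len(k), function(r) {
      2 * A[spec@residualCovariances[r, 1L], spec@residualCovariances[r, 2L]]
    }, numeric(1)) else numeric()
    c(gLambda, gLogTheta, gPhi, gOff)
  }

  starts <- list(makeStart(0.7, 0.5, 0.4), makeStart(0.9, 0.3, 0.2))
  fits <- lapply(starts, function(s0)
    nlminb(s0, objective, gradient, lower = lower,
           control = list(iter.max = 2000L, eval.max = 4000L)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  polish <- optim(best$par, objective, gradient, method = "L-BFGS-B",
                  lower = lower,
                  control = list(maxit = 500L, factr = 1e4))
  if (polish$value < best$objective)
    best <- list(par = polish$par, objective = polish$value)

  est <- unpackParams(best$par, spec)
  ## orient each factor so that its mean loading is positive (sign of a
  ## factor is not identified)
  for (j in seq_len(m)) {
    if (sum(est$lambda[, j]) < 0) {
      est$lambda[, j] <- -est$lambda[, j]
      est$phi[j, -j] <- -est$phi[j, -j]
      est$phi[-j, j] <- -est$phi[-j, j]
    }
  }
  sigma <- impliedSigma(est$lambda, est$phi, est$theta)
  fml <- mlDiscrepancy(S, sigma)
  g <- gradient(best$par)
  gradNorm <- sqrt(sum(g^2))
  converged <- is.finite(fml) && gradNorm < 1e-3
  if (!converged)
    warning("possible non-convergence: gradient norm = ",
            signif(gradNorm, 3))
  heywood <- any(diag(est$theta) <= 1.05e-6 * diag(S))
  if (heywood)
    warning("Heywood case: residual variance at lower bound")

  chisq <- mult * fml
  ## independence baseline: diagonal Sigma
  fBase <- mlDiscrepancy(S, diag(diag(S), p))
  baseChisq <- mult * fBase
  baseDf <- p * (p - 1) / 2
  cfi <- 1 - max(chisq - df, 0) / max(baseChisq - baseDf, chisq - df, 0)
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n - 1))) else 0
  Dinv <- diag(1 / sdj, p)
  res <- Dinv %*% (S - sigma) %*% Dinv
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))

  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  W <- if (!is.null(ch)) est$phi %*% t(est$lambda) %*% chol2inv(ch)
       else matrix(NA_real_, m, p)
  dimnames(W) <- list(spec@factors, spec@indicators)

  new("FittedFactorModel", spec = spec, lambda = est$lambda, phi = est$phi,
      theta = est$theta, mu = mu, sigma = sigma, S = S, n = as.numeric(n),
      fml = fml, chisq = chisq, df = as.numeric(df), cfi = cfi,
      rmsea = rmsea, srmr = srmr, baselineChisq = baseChisq,
      baselineDf = baseDf, converged = converged, gradNorm = gradNorm,
      heywood = heywood, scoreWeights = W)
}

#' Rank eligible residual covariances by modification index
#'
#' For every same-task, same-factor indicator pair not already freed,
#' computes a univariate score-test modification index — the expected
#' chi-square drop from freeing that residual covariance, from the gradient
#' and curvature of the ML discrepancy at the fitted solution:
#' `MI = (n - 1) g^2 / (2 h)`. Pairs are returned ranked; the absolute
#' standardized residual covariance is reported alongside. Refitting with
#' the chosen pairs is the caller's job (see [addResidualCovariances()]).
#'
#' @param fit a converged [FittedFactorModel-class].
#' @param k number of top pairs to return (`k = 0` gives an empty result).
#' @return data.frame with columns `indicator1`, `indicator2`, `mi`,
#'   `stdResidual`, ranked by decreasing `mi`; zero rows if no pair is
#'   eligible.
#' @export
suggestResidualCovariances <- function(fit, k = 4L) {
  spec <- fit@spec
  pairs <- eligibleResidualPairs(spec)
  if (nrow(pairs) == 0L || k == 0L)
    return(data.frame(indicator1 = character(), indicator2 = character(),
                      mi = numeric(), stdResidual = numeric()))
  S <- fit@S
  sigma0 <- fit@sigma
  siginv <- chol2inv(chol(sigma0))
  A <- siginv - siginv %*% S %*% siginv
  dimnames(A) <- dimnames(S)
  sdj <- sqrt(diag(S))
  h <- 1e-4 * mean(diag(S))
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    g <- 2 * A[i, j]
    perturb <- function(d) {
      sig <- sigma0
      sig[i, j] <- sig[i, j] + d
      sig[j, i] <- sig[j, i] + d
      mlDiscrepancy(S, sig)
    }
    f0 <- fit@fml
    hess <- (perturb(h) - 2 * f0 + perturb(-h)) / h^2
    mi <- if (is.finite(hess) && hess > 0)
      (fit@n - 1) * g^2 / (2 * hess) else 0
    data.frame(indicator1 = i, indicator2 = j, mi = mi,
               stdResidual = abs((S[i, j] - sigma0[i, j]) /
                                   (sdj[i] * sdj[j])))
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$mi), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Regression-method factor scores
#'
#' Linear projections of the (centered) indicators using the weight matrix
#' `W = Phi Lambda' Sigma^-1` from a fitted model:
#' `scores = (x - mu) W'`.
#'
#' @param fit a [FittedFactorModel-class].
#' @param data subjects x indicators table containing the spec's indicator
#'   columns (already oriented as at fitting time).
#' @return data.frame of factor scores, one column per factor; a
#'   `subject_id` column of `data` is carried through.
#' @export
factorScores <- function(fit, data) {
  if (!all(is.finite(fit@scoreWeights)))
    stop("implied covariance singular; factor scores unavailable")
  data <- as.data.frame(data, check.names = FALSE)
  X <- as.matrix(data[fit@spec@indicators])
  scores <- sweep(X, 2L, fit@mu[fit@spec@indicators]) %*% t(fit@scoreWeights)
  out <- as.data.frame(scores, check.names = FALSE)
  if ("subject_id" %in% colnames(data))
    out <- cbind(subject_id = data$subject_id, out)
  rownames(out) <- NULL
  out
}

#' Fit the executive-function CFA with residual-covariance modification
#'
#' Convenience wrapper reproducing the full measurement-model workflow:
#' orient timed scores, fit the baseline four-factor model, free the top
#' `modify` eligible residual covariances by modification index, refit, and
#' extract regression-method factor scores from the modified model.
#'
#' @param scores data.frame with `subject_id` and the 14 task columns (raw
#'   orientation; timed scores are reverse-coded internally).
#' @param modify number of residual covariances to free (default 4).
#' @return list with `baseline` and `modified` [FittedFactorModel-class]
#'   objects, the `modification` ranking table, and `factorScores`.
#' @export
fitEfModel <- function(scores, modify = 4L) {
  spec <- efFactorModel()
  oriented <- reverseCode(scores, intersect(spec@reverseCoded,
                                            colnames(scores)))
  baseline <- fitMl(spec, oriented)
  mods <- suggestResidualCovariances(baseline, k = modify)
  modified <- if (nrow(mods)) {
    spec2 <- addResidualCovariances(
      spec, as.matrix(mods[c("indicator1", "indicator2")]))
    fitMl(spec2, oriented)
  } else baseline
  list(baseline = baseline, modified = modified, modification = mods,
       factorScores = factorScores(modified, oriented))
}
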