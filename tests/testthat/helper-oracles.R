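# Independent oracles shared by the unit and acceptance suites. Each one
# recomputes a quantity by a route independent of the implementation.

## Brute-force BH step-up: reject the largest k with p_(k) <= k alpha / m.
bhRejectBruteForce <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * alpha / m)
  rej <- rep(FALSE, m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

## Independent parameter count: enumerate free parameters one by one.
countParamsByEnumeration <- function(spec) {
  params <- character()
  for (j in spec@indicators) {
    params <- c(params, paste0("lambda_", j), paste0("theta_", j))
  }
  if (length(spec@factors) >= 2) {
    fpairs <- utils::combn(spec@factors, 2)
    for (q in seq_len(ncol(fpairs)))
      params <- c(params, paste0("phi_", fpairs[1, q], "_", fpairs[2, q]))
  }
  rc <- spec@residualCovariances
  for (r in seq_len(nrow(rc)))
    params <- c(params, paste0("thetaoff_", rc[r, 1], "_", rc[r, 2]))
  p <- length(spec@indicators)
  p * (p + 1) / 2 - length(params)
}

## Brute-force ML fit of a 2-factor (3 + 3) model on a fixed covariance:
## different parameterization (tanh correlation, log uniquenesses) and a
## derivative-free optimizer, independent of the package engine.
oracleTwoFactorFit <- function(S, n) {
  p <- 6
  fml <- function(par) {
    lam <- par[1:6]; psi <- exp(par[7:12]); rho <- tanh(par[13])
    L <- matrix(0, 6, 2); L[1:3, 1] <- lam[1:3]; L[4:6, 2] <- lam[4:6]
    Phi <- matrix(c(1, rho, rho, 1), 2)
    Sig <- L %*% Phi %*% t(L) + diag(psi)
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) return(1e10)
    as.numeric(determinant(Sig)$modulus - determinant(S)$modulus +
                 sum(diag(S %*% solve(Sig))) - p)
  }
  st <- c(0.7 * sqrt(diag(S)), log(0.5 * diag(S)), atanh(0.3))
  o <- optim(st, fml, method = "Nelder-Mead",
             control = list(maxit = 20000, reltol = 1e-14))
  o <- optim(o$par, fml, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-14))
  F0 <- o$value
  chisq <- (n - 1) * F0
  df <- 6 * 7 / 2 - 13
  fb <- as.numeric(sum(log(diag(S))) - determinant(S)$modulus)
  bchisq <- (n - 1) * fb
  Dinv <- diag(1 / sqrt(diag(S)))
  est <- local({
    lam <- o$par[1:6]; psi <- exp(o$par[7:12]); rho <- tanh(o$par[13])
    L <- matrix(0, 6, 2); L[1:3, 1] <- lam[1:3]; L[4:6, 2] <- lam[4:6]
    L %*% matrix(c(1, rho, rho, 1), 2) %*% t(L) + diag(psi)
  })
  resid <- Dinv %*% (S - est) %*% Dinv
  list(fml = F0, chisq = chisq,
       rmsea = sqrt(max(chisq - df, 0) / (df * (n - 1))),
       cfi = 1 - max(chisq - df, 0) / max(bchisq - 15, chisq - df, 0),
       srmr = sqrt(mean(resid[lower.tri(resid, diag = TRUE)]^2)))
}

## Fixed-covariance fixture for the oracle comparison.
twoFactorFixture <- function(seed, n = 150) {
  set.seed(seed)
  f1 <- rnorm(n); f2 <- 0.5 * f1 + sqrt(0.75) * rnorm(n)
  X <- cbind(a = f1 + rnorm(n), b = 0.7 * f1 + rnorm(n),
             c = 1.3 * f1 + rnorm(n), d = f2 + rnorm(n),
             e = 0.9 * f2 + rnorm(n), f = 0.6 * f2 + rnorm(n))
  list(S = cov(X), n = n,
       spec = factorModelSpec(c(a = "f1", b = "f1", c = "f1",
                                d = "f2", e = "f2", f = "f2")))
}
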