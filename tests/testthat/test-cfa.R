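# Factor model: degrees of freedom, ML estimation against independent
# oracles, modification indices, factor scores, reverse coding.

test_that("model degrees of freedom match the printed-model conventions", {
  base <- efFactorModel()
  expect_identical(modelDf(base), 71L)
  mod4 <- efFactorModel(list(c("LF", "CF"), c("TMT-A", "TMT-MS"),
                             c("0-back", "1-back"), c("CWI-I", "CWI-S")))
  expect_identical(modelDf(mod4), 67L)
  # just-identified single factor, 3 indicators
  one <- factorModelSpec(c(a = "g", b = "g", c = "g"))
  expect_identical(modelDf(one), 0L)
  # enumeration oracle across specs
  for (spec in list(base, mod4, one,
                    efFactorModel(list(c("1-back", "2-back"))))) {
    expect_equal(modelDf(spec), countParamsByEnumeration(spec))
  }
  # over-parameterized: single factor, 2 indicators
  expect_error(modelDf(factorModelSpec(c(a = "g", b = "g"))),
               "over-parameterized")
})

test_that("residual covariances must pair same-task, same-factor indicators", {
  elig <- eligibleResidualPairs(efFactorModel())
  key <- apply(elig, 1, function(r) paste(sort(r), collapse = "|"))
  expect_setequal(key, c("CF|LF", "CS|LF", "CF|CS", "TMT-A|TMT-MS",
                         "CWI-I|CWI-S", "0-back|1-back", "0-back|2-back",
                         "1-back|2-back"))
  # TMT-B shares the task but not the factor with TMT-A
  expect_error(efFactorModel(list(c("TMT-A", "TMT-B"))), "same-task")
  # LF and CWI-I share neither
  expect_error(efFactorModel(list(c("LF", "CWI-I"))), "same-task")
})

test_that("reverse coding negates listed columns once and only once", {
  d <- data.frame("TMT-A" = c(30, 40), CST = c(10, 12), check.names = FALSE)
  r <- reverseCode(d, "TMT-A")
  expect_equal(r[["TMT-A"]], c(-30, -40))
  expect_equal(r$CST, c(10, 12))
  expect_identical(reverseCode(d, character())[["TMT-A"]], c(30, 40))
  expect_error(reverseCode(r, "TMT-A"), "already applied")
  expect_error(reverseCode(d, "nonesuch"), "unknown indicator")
})

test_that("a just-identified model reproduces the sample covariance exactly", {
  set.seed(5)
  f <- rnorm(400)
  X <- cbind(a = f + rnorm(400, 0, 0.6), b = 0.8 * f + rnorm(400, 0, 0.7),
             c = 1.2 * f + rnorm(400, 0, 0.5))
  fit <- fitMl(factorModelSpec(c(a = "g", b = "g", c = "g")), X)
  expect_lt(fit@fml, 1e-9)
  expect_lt(fit@chisq, 1e-6)
  expect_equal(fit@rmsea, 0)
  expect_equal(fit@cfi, 1)
  expect_lt(fit@srmr, 1e-5)
  expect_equal(fit@sigma, fit@S, tolerance = 1e-6)
})

test_that("the ML engine agrees with a brute-force oracle on fixed covariances", {
  spec2 <- factorModelSpec(c(a = "f1", b = "f1", c = "f1",
                             d = "f2", e = "f2", f = "f2"))
  for (sd0 in c(101, 202, 303)) {
    set.seed(sd0)
    n <- 150
    f1 <- rnorm(n); f2 <- 0.5 * f1 + sqrt(0.75) * rnorm(n)
    X <- cbind(a = f1 + rnorm(n), b = 0.7 * f1 + rnorm(n),
               c = 1.3 * f1 + rnorm(n), d = f2 + rnorm(n),
               e = 0.9 * f2 + rnorm(n), f = 0.6 * f2 + rnorm(n))
    S <- cov(X)
    fit <- fitMl(spec2, S = S, n = n)
    oracle <- oracleTwoFactorFit(S, n)
    expect_lt(abs(fit@fml - oracle$fml), 1e-6)
    expect_lt(abs(fit@chisq - oracle$chisq), 1e-4)
    expect_lt(abs(fit@rmsea - oracle$rmsea), 1e-4)
    expect_lt(abs(fit@cfi - oracle$cfi), 1e-4)
  }
})

test_that("single-factor estimates agree with factanal", {
  set.seed(77)
  n <- 800
  f <- rnorm(n)
  lam <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  X <- sapply(lam, function(l) l * f + rnorm(n, 0, sqrt(1 - l^2)))
  colnames(X) <- paste0("v", 1:5)
  R <- cor(X)
  fit <- fitMl(factorModelSpec(setNames(rep("g", 5), colnames(X))),
               S = R, n = n)
  fa <- factanal(covmat = R, factors = 1, n.obs = n)
  expect_equal(unname(fit@lambda[, 1]), unname(as.numeric(fa$loadings)),
               tolerance = 2e-3)
  expect_equal(unname(diag(fit@theta)), unname(fa$uniquenesses),
               tolerance = 2e-3)
})

test_that("loadings are recovered from a large simulated cohort", {
  spec <- cohortSpec(nSubjects = 5000, seed = 11)
  ph <- generatePhenotypes(spec)
  sc <- generateTaskScores(spec, ph$truth)
  dat <- reverseCode(sc$scores[-1], EF_TIMED_INDICATORS)
  fit <- fitMl(efFactorModel(), dat)
  expect_true(fit@converged)
  # standardized loadings against the generative values
  stdl <- fit@lambda[cbind(seq_len(14),
                           match(EF_LOADING_PATTERN[EF_INDICATORS],
                                 EF_FACTORS))] / sqrt(diag(fit@S))
  truth <- vapply(EF_INDICATORS, function(j) {
    spec@factorLoadings[[j]] * sd(sc$trueFactors[[EF_LOADING_PATTERN[[j]]]]) *
      spec@indicatorScale[[j]] / sd(dat[[j]])
  }, numeric(1))
  expect_lt(max(abs(stdl - truth)), 0.05)
  expect_lt(fit@chisq / fit@df, 1.6)       # data generated from the model
})

test_that("modification indices recover a planted residual covariance", {
  spec <- tinySpec(nSubjects = 500, seed = 23)
  rep1 <- simReplicate(spec)
  sc <- rep1$scores$scores
  set.seed(99)
  z <- rnorm(nrow(sc), 0, 0.5)
  sc$LF <- sc$LF + z * 12.8                 # shared residual on the
  sc$CF <- sc$CF + z * 9.6                  # same-task fluency pair
  fitP <- fitMl(efFactorModel(), reverseCode(sc[-1], EF_TIMED_INDICATORS))
  mods <- suggestResidualCovariances(fitP, k = 4)
  expect_setequal(unlist(mods[1, c("indicator1", "indicator2")]),
                  c("LF", "CF"))
  expect_gt(mods$mi[1], 5 * mods$mi[2])
  # null data: all modification indices stay small
  fit0 <- fitMl(efFactorModel(),
                reverseCode(rep1$scores$scores[-1], EF_TIMED_INDICATORS))
  mods0 <- suggestResidualCovariances(fit0, k = 8)
  expect_lt(max(mods0$mi), 12)
  expect_identical(nrow(suggestResidualCovariances(fit0, k = 0)), 0L)
  # freeing a covariance can only decrease the discrepancy (nested models)
  fitP2 <- fitMl(addResidualCovariances(efFactorModel(),
                                        matrix(c("LF", "CF"), 1)),
                 reverseCode(sc[-1], EF_TIMED_INDICATORS))
  expect_lt(fitP2@fml, fitP@fml)
})

test_that("factor scores match their closed-form and empirical oracles", {
  # single indicator, lambda = 1, theta ~ 0: score is the centered indicator
  spec1 <- factorModelSpec(c(x = "g"))
  fit1 <- new("FittedFactorModel", spec = spec1,
              lambda = matrix(1, 1, 1, dimnames = list("x", "g")),
              phi = matrix(1, 1, 1), theta = matrix(0, 1, 1),
              mu = c(x = 3), sigma = matrix(1, 1, 1,
                                            dimnames = list("x", "x")),
              S = matrix(1, 1, 1), n = 10, fml = 0, chisq = 0, df = 0,
              cfi = 1, rmsea = 0, srmr = 0, baselineChisq = 0,
              baselineDf = 0, converged = TRUE, gradNorm = 0,
              heywood = FALSE,
              scoreWeights = matrix(1, 1, 1, dimnames = list("g", "x")))
  sc1 <- factorScores(fit1, data.frame(x = c(2, 3, 5)))
  expect_equal(sc1$g, c(-1, 0, 2))
  # zero loadings give identically zero scores
  fit0 <- fit1
  fit0@lambda[] <- 0
  fit0@scoreWeights[] <- 0
  expect_equal(factorScores(fit0, data.frame(x = c(2, 3, 5)))$g, c(0, 0, 0))
  # empirical oracle: W rows equal the population regression of factors on
  # indicators, estimated by simulating from the fitted parameters
  set.seed(41)
  spec2 <- factorModelSpec(c(a = "f1", b = "f1", d = "f2", e = "f2"))
  n <- 500
  f1 <- rnorm(n); f2 <- 0.4 * f1 + sqrt(1 - 0.16) * rnorm(n)
  X <- cbind(a = f1 + rnorm(n, 0, 0.5), b = 0.8 * f1 + rnorm(n, 0, 0.5),
             d = f2 + rnorm(n, 0, 0.5), e = 0.7 * f2 + rnorm(n, 0, 0.5))
  fit2 <- fitMl(spec2, X)
  nSim <- 2e5
  fs1 <- rnorm(nSim)
  fs2 <- fit2@phi[1, 2] * fs1 + sqrt(1 - fit2@phi[1, 2]^2) * rnorm(nSim)
  E <- matrix(rnorm(nSim * 4), nSim, 4) %*% diag(sqrt(diag(fit2@theta)))
  Xs <- cbind(fs1, fs2) %*% t(fit2@lambda) + E
  for (k in 1:2) {
    bru <- coef(lm(cbind(fs1, fs2)[, k] ~ Xs))[-1]
    expect_equal(unname(bru), unname(fit2@scoreWeights[k, ]),
                 tolerance = 0.05)
  }
})

test_that("factor scores track the true factors in the default cohort", {
  spec <- cohortSpec(seed = 12)
  ph <- generatePhenotypes(spec)
  sc <- generateTaskScores(spec, ph$truth)
  em <- fitEfModel(sc$scores, modify = 4L)
  expect_identical(modelDf(em$baseline), 71L)
  expect_identical(modelDf(em$modified), 67L)
  for (k in EF_FACTORS)
    expect_gt(cor(em$factorScores[[k]], sc$trueFactors[[k]]), 0.8)
})

test_that("fitMl validates its inputs", {
  spec <- factorModelSpec(c(a = "g", b = "g", c = "g"))
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "x")))
  expect_error(fitMl(spec, X), "lacks indicator")
  Xs <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(fitMl(spec, Xs), "more subjects")
  Sbad <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"),
                                          c("a", "b", "c")))
  expect_error(fitMl(spec, S = Sbad, n = 100), "positive definite")
  expect_error(fitMl(spec), "supply data")
})
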