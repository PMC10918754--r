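# Moderated regressions, FDR, simple slopes, age polynomials.

test_that("BH adjustment equals the brute-force step-up rule", {
  p0 <- c(0.01, 0.02, 0.04, 0.5)
  q0 <- fdrAdjust(p0)
  expect_identical(sum(q0 < 0.05), 2L)
  expect_equal(fdrAdjust(0.03), 0.03)                  # single test: q = p
  expect_equal(fdrAdjust(rep(0.2, 5)), rep(0.2, 5))    # ties stay tied
  expect_identical(fdrAdjust(numeric()), numeric())
  expect_error(fdrAdjust(c(0.1, 1.2)), "0, 1")
  set.seed(6)
  for (i in 1:25) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    q <- fdrAdjust(p)
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
    for (alpha in c(0.01, 0.05, 0.1, 0.25))
      expect_identical(q <= alpha, bhRejectBruteForce(p, alpha))
  }
})

## One generative-pathway dataset shared across regression tests.
lsSpec <- cohortSpec(nSubjects = 400, seed = 61)
lsRep <- simReplicate(lsSpec)
lsVres <- residualizeMotion(lsRep$variability, lsRep$phenotypes$mean_fd)
lsScores <- lsRep$scores$trueFactors

test_that("standardized coefficients equal the fully z-scored refit", {
  fit <- fitModeration("cognitive_flexibility", "DMN", lsScores, lsVres,
                       lsRep$phenotypes, interaction = FALSE)
  d <- fit$data
  z <- function(x) (x - mean(x)) / sd(x)
  zfit <- lm(z(d$.y) ~ z(d$.delta) + z(d$sexFemale) + z(d$handLeft) +
               z(d$education_years))
  co <- fit$coefficients
  for (tm in c(".delta", "sexFemale", "handLeft", "education_years")) {
    ztm <- paste0("z(d$", sub("^\\.", ".", tm), ")")
    expect_equal(co$beta[co$term == tm], unname(coef(zfit)[ztm]),
                 tolerance = 1e-10)
  }
  expect_true(is.na(co$beta[co$term == "(Intercept)"]))
})

test_that("the interaction coefficient is invariant to the centering constant", {
  fit <- fitModeration("processing_speed", "CEN", lsScores, lsVres,
                       lsRep$phenotypes, interaction = TRUE)
  d <- fit$data
  bInt <- fit$coefficients$b[fit$coefficients$term == ".delta:ageC"]
  for (c0 in c(0, 20, 45.5)) {
    ac <- d$age - c0
    ref <- lm(d$.y ~ d$.delta * ac + d$sexFemale + d$handLeft +
                d$education_years)
    expect_equal(unname(coef(ref)["d$.delta:ac"]), bInt, tolerance = 1e-10)
  }
})

test_that("simple slopes obey the linear identity and the re-centering oracle", {
  fit <- fitModeration("inhibitory_control", "DMN", lsScores, lsVres,
                       lsRep$phenotypes, interaction = TRUE)
  co <- fit$coefficients
  bD <- co$b[co$term == ".delta"]
  bI <- co$b[co$term == ".delta:ageC"]
  ss <- simpleSlopes(fit, ages = c(fit$ageMean, fit$ageMean + 20, 13.17))
  expect_equal(ss$slope[1], bD)
  expect_equal(ss$se[1], co$se[co$term == ".delta"])
  expect_equal(ss$slope[2], bD + 20 * bI)
  # re-centering oracle: refit with age centered at the probe age
  d <- fit$data
  for (r in 2:3) {
    ac <- d$age - ss$age[r]
    ref <- summary(lm(d$.y ~ d$.delta * ac + d$sexFemale + d$handLeft +
                        d$education_years))$coefficients
    expect_equal(ss$slope[r], unname(ref["d$.delta", "Estimate"]),
                 tolerance = 1e-10)
    expect_equal(ss$se[r], unname(ref["d$.delta", "Std. Error"]),
                 tolerance = 1e-10)
    expect_equal(ss$p[r], unname(ref["d$.delta", "Pr(>|t|)"]),
                 tolerance = 1e-10)
  }
  expect_error(simpleSlopes(fitModeration("inhibitory_control", "DMN",
                                          lsScores, lsVres,
                                          lsRep$phenotypes)),
               "interaction")
})

test_that("moderation fitting validates its inputs", {
  expect_error(fitModeration("cognitive_flexibility", "DMN",
                             lsScores[1:10, ], lsVres, lsRep$phenotypes),
               "20 complete cases")
  vbad <- lsVres
  vbad$DMN <- 1
  expect_error(fitModeration("cognitive_flexibility", "DMN", lsScores,
                             vbad, lsRep$phenotypes), "zero variance")
})

test_that("the model family has the Table-2 structure", {
  fam <- runModelFamily(lsScores, lsVres, lsRep$phenotypes)
  expect_identical(nrow(fam$focal), 48L)               # 4 x 6 x 2
  expect_setequal(unique(fam$focal$predictor),
                  c("whole_brain", BRAIN_NETWORKS))
  # FDR is applied within each (outcome, type) family of 6
  for (oc in unique(fam$focal$outcome)) for (ty in c("main", "interaction")) {
    rows <- fam$focal[fam$focal$outcome == oc & fam$focal$type == ty, ]
    expect_identical(nrow(rows), 6L)
    expect_equal(rows$q, fdrAdjust(rows$p))
  }
  # non-focal terms carry no q
  expect_true(all(is.na(fam$table$q[!fam$table$focal])))
  # planted limbic main effect: negative in all four outcomes
  ln <- fam$focal[fam$focal$type == "main" & fam$focal$predictor == "LN", ]
  expect_true(all(ln$b < 0))
  # simple slopes computed for surviving interactions, at 4 cohort ages
  if (nrow(fam$simpleSlopes))
    expect_true(all(table(fam$simpleSlopes$outcome,
                          fam$simpleSlopes$predictor) %in% c(0L, 4L)))
})

test_that("a planted interaction is recovered without bias", {
  gInt <- matrix(0, 4, 5, dimnames = list(EF_FACTORS, BRAIN_NETWORKS))
  gInt["cognitive_flexibility", "DMN"] <- 0.1
  est <- replicate(60, NA_real_)
  for (r in seq_len(60)) {
    # age curve zeroed: the linear moderation model is then correctly
    # specified, so the estimator must be unbiased for gamma
    sp <- cohortSpec(nSubjects = 400, seed = 3000 + r,
                     gammaMain = matrix(0, 4, 5), gammaInteraction = gInt,
                     factorAgeCurve = matrix(0, 4, 3,
                       dimnames = list(EF_FACTORS,
                                       c("intercept", "linear",
                                         "quadratic"))))
    rp <- simReplicate(sp)
    fit <- fitModeration("cognitive_flexibility", "DMN",
                         rp$scores$trueFactors,
                         residualizeMotion(rp$variability,
                                           rp$phenotypes$mean_fd),
                         rp$phenotypes, interaction = TRUE)
    est[r] <- fit$coefficients$b[fit$coefficients$term == ".delta:ageC"]
  }
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.1), 2 * mcse + 1e-3)
  expect_gt(mean(est), 0)
})

test_that("age polynomials recover curvature, peak, and exact linear fits", {
  # concave quadratic peaking at 45 (the generator's default curve)
  spNoG <- cohortSpec(seed = 71, gammaMain = matrix(0, 4, 5),
                      gammaInteraction = matrix(0, 4, 5))
  rp <- simReplicate(spNoG)
  curves <- agePolynomial(rp$scores$trueFactors, rp$phenotypes, degree = 2)
  expect_identical(nrow(curves), 8L)                   # 4 outcomes x 2 terms
  for (k in EF_FACTORS) {
    pk <- curves$peak_age[curves$outcome == k][1]
    expect_lt(abs(pk - 45), 2)
  }
  # degree 1 on exactly linear noiseless data: R^2 = 1
  lin <- data.frame(subject_id = rp$phenotypes$subject_id,
                    yy = 2 + 0.3 * rp$phenotypes$age)
  c1 <- suppressWarnings(agePolynomial(lin, rp$phenotypes, degree = 1,
                                       outcomes = "yy"))
  expect_equal(c1$r_squared, 1)
  expect_equal(c1$b_raw, 0.3)
  expect_error(agePolynomial(lin, rp$phenotypes, degree = 0), "degree")
  # linear truth: the quadratic term is null-calibrated
  set.seed(17)
  tstats <- replicate(100, {
    age <- runif(200, 6, 85)
    d <- data.frame(subject_id = sprintf("s%03d", 1:200),
                    yy = 0.1 * age + rnorm(200))
    ph <- data.frame(subject_id = d$subject_id, age = age)
    cc <- agePolynomial(d, ph, degree = 2, outcomes = "yy")
    cc$t_orthogonal[cc$degree == 2]
  })
  expect_gte(mean(abs(tstats) < 2), 0.9)
})
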