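# Life-span models: main-effect and age-moderated regressions of factor
# scores on network variability, FDR correction, simple slopes at cohort
# ages, and polynomial age curves.

## Default ages (years) at which conditional slopes are probed: the mean
## ages of the adolescence, early-, middle- and older-adulthood cohorts.
COHORT_AGES <- c(adolescence = 13.17, early_adulthood = 27.01,
                 middle_adulthood = 50.09, older_adulthood = 69.42)

#' Fit one variability-to-executive-function regression
#'
#' OLS regression of a factor score on one variability predictor with the
#' standard covariate trio (sex, handedness, years of education), and
#' optionally mean-centered age plus the predictor-by-age interaction.
#' Age is mean-centered to limit collinearity with the product term.
#' Standardized coefficients are `b * sd(x) / sd(y)` for non-interaction
#' terms; the interaction beta is the product-term coefficient from a refit
#' in which outcome, predictor, and age are z-scored before the product is
#' formed.
#'
#' @param outcome name of the factor-score column in `scores`.
#' @param predictor name of the variability column in `variability`
#'   (a network or `whole_brain`).
#' @param scores data.frame with `subject_id` and factor-score columns.
#' @param variability data.frame with `subject_id` and variability columns
#'   (typically adjusted, motion-residualized summaries).
#' @param phenotypes data.frame with `subject_id`, `age`, `sex`,
#'   `handedness`, `education_years`.
#' @param interaction logical; include age and the predictor-by-age term.
#' @return list of class `moderationFit`: `coefficients` data.frame (term,
#'   b, se, t, p, beta), `vcov`, `residualDf`, `ageMean`, `model` id
#'   fields, and the underlying `lm` fit.
#' @export
fitModeration <- function(outcome, predictor, scores, variability,
                          phenotypes, interaction = FALSE) {
  dat <- merge(merge(scores[c("subject_id", outcome)],
                     variability[c("subject_id", predictor)],
                     by = "subject_id"),
               phenotypes[c("subject_id", "age", "sex", "handedness",
                            "education_years")], by = "subject_id")
  names(dat)[names(dat) == outcome] <- ".y"
  names(dat)[names(dat) == predictor] <- ".delta"
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 20L) stop("fewer than 20 complete cases")
  if (stats::sd(dat$.delta) == 0) stop("predictor has zero variance")
  dat$sexFemale <- as.numeric(dat$sex == "female")
  dat$handLeft <- as.numeric(dat$handedness == "left")
  ageMean <- mean(dat$age)
  dat$ageC <- dat$age - ageMean
  form <- if (interaction)
    .y ~ .delta + ageC + .delta:ageC + sexFemale + handLeft + education_years
  else .y ~ .delta + sexFemale + handLeft + education_years
  X <- stats::model.matrix(form, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  fit <- stats::lm(form, data = dat)
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  sdY <- stats::sd(dat$.y)
  beta <- vapply(terms, function(tm) {
    if (tm == "(Intercept)") return(NA_real_)
    if (tm == ".delta:ageC") {
      zdat <- dat
      zdat$.y <- scale(dat$.y)[, 1L]
      zdat$.delta <- scale(dat$.delta)[, 1L]
      zdat$ageC <- scale(dat$ageC)[, 1L]
      zfit <- stats::lm(form, data = zdat)
      return(unname(coef(zfit)[".delta:ageC"]))
    }
    unname(sm[tm, "Estimate"] * stats::sd(dat[[tm]]) / sdY)
  }, numeric(1))
  coefs <- data.frame(term = terms, b = sm[, "Estimate"],
                      se = sm[, "Std. Error"], t = sm[, "t value"],
                      p = sm[, "Pr(>|t|)"], beta = beta,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, vcov = stats::vcov(fit),
                 residualDf = fit$df.residual, ageMean = ageMean,
                 outcome = outcome, predictor = predictor,
                 interaction = interaction, lm = fit, data = dat),
            class = "moderationFit")
}

#' Benjamini-Hochberg FDR adjustment within a family
#'
#' Step-up false-discovery-rate adjusted p-values (q-values), capped at 1
#' and monotone after sorting; `q >= p` elementwise.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return q-values aligned with `p` (empty input gives empty output).
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.04, 0.5))   # two values below 0.05
#' @export
fdrAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Conditional (simple) slopes of variability at chosen ages
#'
#' For an interaction model, the conditional effect of the variability
#' predictor at age `a` (years) is `b_delta + (a - ageMean) * b_int`, with
#' delta-method variance
#' `Var(b_delta) + a_c^2 Var(b_int) + 2 a_c Cov(b_delta, b_int)` and a
#' t-test on the model's residual degrees of freedom. At the centering age
#' the conditional slope equals the model's main variability coefficient.
#'
#' @param fit a `moderationFit` from [fitModeration()] with
#'   `interaction = TRUE`.
#' @param ages numeric ages (years); defaults to the four cohort means
#'   13.17, 27.01, 50.09, 69.42.
#' @return data.frame with `age`, `slope`, `se`, `t`, `p`.
#' @export
simpleSlopes <- function(fit, ages = COHORT_AGES) {
  if (!inherits(fit, "moderationFit") || !isTRUE(fit$interaction))
    stop("simpleSlopes requires an interaction moderationFit")
  V <- fit$vcov
  if (!all(c(".delta", ".delta:ageC") %in% rownames(V)))
    stop("coefficient covariance lacks interaction terms")
  bD <- fit$coefficients$b[fit$coefficients$term == ".delta"]
  bI <- fit$coefficients$b[fit$coefficients$term == ".delta:ageC"]
  ac <- ages - fit$ageMean
  slope <- bD + ac * bI
  se <- sqrt(V[".delta", ".delta"] + ac^2 * V[".delta:ageC", ".delta:ageC"] +
               2 * ac * V[".delta", ".delta:ageC"])
  tval <- slope / se
  data.frame(age = unname(ages), slope = slope, se = se, t = tval,
             p = 2 * stats::pt(-abs(tval), fit$residualDf),
             row.names = NULL)
}

#' Polynomial age curves of the factor scores
#'
#' Fits each factor score on orthogonal polynomials of age and reports the
#' fit, the raw-basis coefficients, and (for degree 2) the age at peak
#' performance `-b1 / (2 b2)`.
#'
#' @param scores data.frame with `subject_id` and factor-score columns.
#' @param phenotypes data.frame with `subject_id` and `age`.
#' @param degree polynomial degree (`>= 1`, `< n`).
#' @param outcomes factor columns to fit; defaults to all non-id columns.
#' @return data.frame with one row per (outcome, basis degree) coefficient
#'   plus per-outcome `r.squared` and `peak_age` attributes in columns.
#' @export
agePolynomial <- function(scores, phenotypes, degree = 2L,
                          outcomes = setdiff(names(scores), "subject_id")) {
  stopifnot(degree >= 1L)
  dat <- merge(scores, phenotypes[c("subject_id", "age")], by = "subject_id")
  if (degree >= nrow(dat)) stop("degree must be smaller than sample size")
  rows <- lapply(outcomes, function(y) {
    d <- dat[stats::complete.cases(dat[c(y, "age")]), , drop = FALSE]
    ofit <- stats::lm(d[[y]] ~ poly(d$age, degree))
    rfit <- stats::lm(d[[y]] ~ poly(d$age, degree, raw = TRUE))
    b <- coef(rfit)
    peak <- if (degree == 2L && b[3L] < 0) -b[2L] / (2 * b[3L]) else NA_real_
    sm <- summary(ofit)$coefficients
    data.frame(outcome = y, degree = seq_len(degree),
               b_raw = unname(b[-1L]),
               t_orthogonal = unname(sm[-1L, "t value"]),
               p_orthogonal = unname(sm[-1L, "Pr(>|t|)"]),
               r_squared = summary(ofit)$r.squared, peak_age = unname(peak),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full model family
#'
#' Fits every (outcome, predictor) regression — 4 executive-function
#' factors by 6 variability predictors (whole brain + 5 networks), each
#' without ("main") and with ("interaction") the predictor-by-age term —
#' 48 models in all, each predictor in its own model to avoid the severe
#' inter-predictor collinearity of joint inclusion. FDR correction is
#' applied to the focal term within each (outcome, effect-type) family of
#' 6 predictors. Simple slopes at the four cohort ages are computed for
#' every interaction surviving `q < 0.05`.
#'
#' @inheritParams fitModeration
#' @param predictors variability columns to use (default: `whole_brain`
#'   and the five networks present).
#' @param slopeAges ages for [simpleSlopes()].
#' @return list with `table` (long data.frame of all terms of all models,
#'   with `q` on focal terms), `focal` (one row per model: the variability
#'   main effect or interaction term), and `simpleSlopes`.
#' @export
runModelFamily <- function(scores, variability, phenotypes,
                           predictors = intersect(
                             c("whole_brain", BRAIN_NETWORKS),
                             names(variability)),
                           slopeAges = COHORT_AGES) {
  outcomes <- intersect(EF_FACTORS, names(scores))
  grid <- expand.grid(outcome = outcomes, predictor = predictors,
                      type = c("main", "interaction"),
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    fit <- fitModeration(g$outcome, g$predictor, scores, variability,
                         phenotypes, interaction = g$type == "interaction")
    fits[[i]] <- fit
    tab <- fit$coefficients
    tab$outcome <- g$outcome; tab$predictor <- g$predictor
    tab$type <- g$type
    tab$focal <- tab$term == if (g$type == "main") ".delta" else ".delta:ageC"
    rows[[i]] <- tab
  }
  long <- do.call(rbind, rows)
  long$q <- NA_real_
  for (oc in outcomes) for (ty in c("main", "interaction")) {
    sel <- long$focal & long$outcome == oc & long$type == ty
    long$q[sel] <- fdrAdjust(long$p[sel])
  }
  focal <- long[long$focal, , drop = FALSE]
  rownames(focal) <- rownames(long) <- NULL
  slopes <- list()
  sig <- which(focal$type == "interaction" & !is.na(focal$q) &
                 focal$q < 0.05)
  for (j in sig) {
    idx <- which(grid$outcome == focal$outcome[j] &
                   grid$predictor == focal$predictor[j] &
                   grid$type == "interaction")
    ss <- simpleSlopes(fits[[idx]], slopeAges)
    ss$outcome <- focal$outcome[j]; ss$predictor <- focal$predictor[j]
    slopes[[length(slopes) + 1L]] <- ss
  }
  list(table = long, focal = focal,
       simpleSlopes = if (length(slopes)) do.call(rbind, slopes)
                      else data.frame())
}
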