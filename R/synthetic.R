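# Synthetic life-span cohort with known ground truth: ROI time series whose
# rMSSD structure, phenotypes, and four-factor task scores emulate a large
# resting-state study of executive functions across ages 6-85.

#' Build a synthetic cohort specification
#'
#' Constructs a [CohortSpec-class] holding every generative parameter of the
#' synthetic study. Defaults emulate the target study conditions: 724
#' subjects aged 6-85; 246 ROIs in five networks (CEN, DMN, SN, LN, DA)
#' plus unassigned regions; 423 timepoints at TR = 1.4 s (a 10-min scan
#' minus 5 discarded volumes); a shared global signal component whose
#' per-subject amplitude varies and increases with head motion; age-trended
#' per-network rMSSD targets with independent between-subject deviations
#' (centered across the brain, so the network-specific structure is
#' orthogonal to the global level); a U-shaped age-to-motion curve; and 14
#' task scores generated from four correlated executive-function factors
#' with a quadratic age curve, a negative limbic main effect and
#' age-moderated DMN (positive) and CEN (negative) variability effects.
#'
#' @param nSubjects number of subjects.
#' @param ageRange length-2 numeric, minimum and maximum age in years; ages
#'   are drawn uniformly.
#' @param networkSizes named integer vector (CEN, DMN, SN, LN, DA,
#'   unassigned) of ROI counts; must sum to `nRois`.
#' @param nRois total ROI count.
#' @param nTimepoints scan length in volumes.
#' @param tr repetition time, seconds.
#' @param globalWeight amplitude of the shared global component, expressed
#'   on the rMSSD scale relative to the size-weighted mean network baseline
#'   (0 = no shared component).
#' @param globalAmpSd between-subject SD of the multiplicative global
#'   amplitude.
#' @param arCoefficient lag-1 autocorrelation of all latent AR(1) processes,
#'   in (-1, 1).
#' @param networkDeltaBaseline named per-network rMSSD target at the
#'   mid-age, signal units.
#' @param networkDeltaAgeSlope named per-network change in target rMSSD per
#'   year of age. The default unassigned slope balances the size-weighted
#'   mean slope to zero so whole-brain adjusted variability carries no age
#'   trend.
#' @param networkDeltaSubjectSd between-subject SD of each network's rMSSD
#'   target around its age trend.
#' @param motionModel named numeric `c(base, quad, center, noise_sd)`:
#'   mean framewise displacement is
#'   `base + quad * (age - center)^2 + N(0, noise_sd)`, floored at 0.03 mm.
#' @param motionDeltaCoef effect of (mean FD - 0.25) on the subject's global
#'   amplitude — motion inflates global, not network-specific, variability.
#' @param factorLoadings named per-indicator loading on its factor (latent
#'   scale).
#' @param indicatorNoiseSd named per-indicator residual SD (latent scale).
#' @param indicatorMean,indicatorScale named location/scale applied when
#'   emitting observed scores, chosen to resemble published descriptive
#'   statistics of the task battery.
#' @param factorAgeCurve 4 x 3 matrix (rows = factors; columns = intercept,
#'   linear, quadratic coefficients in centered age). The default concave
#'   curve peaks at age 45.
#' @param factorResidSd per-factor residual SD.
#' @param factorResidCor common correlation of factor residuals.
#' @param gammaMain,gammaInteraction 4 x 5 matrices (factors x networks
#'   CEN, DMN, SN, LN, DA): main effect of the network's adjusted rMSSD on
#'   the factor, and its interaction with centered age (per delta-unit,
#'   per delta-unit-year).
#' @param timedIndicators indicators recorded as completion time / reaction
#'   time, emitted with reversed sign (lower = better).
#' @param seed integer master seed; every stochastic stage derives from it.
#' @return a validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(nSubjects = 10, nTimepoints = 50)
#' spec
#' @export
cohortSpec <- function(
  nSubjects = 724,
  ageRange = c(6, 85),
  networkSizes = c(CEN = 40, DMN = 50, SN = 30, LN = 30, DA = 30,
                   unassigned = 66),
  nRois = sum(networkSizes),
  nTimepoints = 423,
  tr = 1.4,
  globalWeight = 1.0,
  globalAmpSd = 0.4,
  arCoefficient = 0.3,
  networkDeltaBaseline = c(CEN = 1.0, DMN = 1.05, SN = 0.95, LN = 0.9,
                           DA = 1.0, unassigned = 1.0),
  networkDeltaAgeSlope = NULL,
  networkDeltaSubjectSd = 0.1,
  motionModel = c(base = 0.20, quad = 1e-4, center = 40, noise_sd = 0.06),
  motionDeltaCoef = 1.0,
  factorLoadings = setNames(rep(0.8, 14), EF_INDICATORS),
  indicatorNoiseSd = setNames(rep(0.6, 14), EF_INDICATORS),
  indicatorMean = c("CST" = 18.5, "LF" = 37.1, "CF" = 39.9, "TMT-B" = 83.2,
                    "CS" = 13.3, "CWI-I" = 57.8, "CWI-S" = 64.0,
                    "TMT-A" = 32.3, "TMT-MS" = 32.3, "RT" = 2.3,
                    "0-back" = 467, "1-back" = 506, "2-back" = 542,
                    "CPT" = 480),
  indicatorScale = c("CST" = 5.4, "LF" = 12.8, "CF" = 9.6, "TMT-B" = 40.5,
                     "CS" = 3.2, "CWI-I" = 19.9, "CWI-S" = 18.6,
                     "TMT-A" = 15.2, "TMT-MS" = 15.1, "RT" = 1.1,
                     "0-back" = 81, "1-back" = 151, "2-back" = 171,
                     "CPT" = 120),
  factorAgeCurve = matrix(rep(c(0, -8e-4, -8e-4), each = 4), 4, 3,
                          dimnames = list(EF_FACTORS,
                                          c("intercept", "linear",
                                            "quadratic"))),
  factorResidSd = setNames(rep(0.8, 4), EF_FACTORS),
  factorResidCor = 0.6,
  gammaMain = matrix(rep(c(0, 0, 0, -1.5, 0), each = 4), 4, 5,
                     dimnames = list(EF_FACTORS, BRAIN_NETWORKS)),
  gammaInteraction = matrix(rep(c(-0.08, 0.08, 0, 0, 0), each = 4), 4, 5,
                            dimnames = list(EF_FACTORS, BRAIN_NETWORKS)),
  timedIndicators = EF_TIMED_INDICATORS,
  seed = 1L) {

  ## accept list-valued fields (e.g. parsed from a YAML config)
  toNum <- function(x) if (is.list(x)) unlist(x) else x
  networkSizes <- toNum(networkSizes); ageRange <- toNum(ageRange)
  networkDeltaBaseline <- toNum(networkDeltaBaseline)
  networkDeltaAgeSlope <- toNum(networkDeltaAgeSlope)
  motionModel <- toNum(motionModel)
  factorLoadings <- toNum(factorLoadings)
  indicatorNoiseSd <- toNum(indicatorNoiseSd)
  indicatorMean <- toNum(indicatorMean); indicatorScale <- toNum(indicatorScale)
  factorResidSd <- toNum(factorResidSd)
  networkDeltaSubjectSd <- toNum(networkDeltaSubjectSd)
  if (is.data.frame(gammaMain)) gammaMain <- as.matrix(gammaMain)
  if (is.data.frame(gammaInteraction))
    gammaInteraction <- as.matrix(gammaInteraction)
  if (is.data.frame(factorAgeCurve)) factorAgeCurve <- as.matrix(factorAgeCurve)

  if (is.null(networkDeltaAgeSlope)) {
    networkDeltaAgeSlope <- c(CEN = -0.004, DMN = -0.004, SN = 0.004,
                              LN = 0.002, DA = -0.002, unassigned = NA)
    named <- networkDeltaAgeSlope[names(networkSizes) != "unassigned"]
    sizes <- networkSizes[names(named)]
    networkDeltaAgeSlope["unassigned"] <-
      -sum(sizes * named) / networkSizes["unassigned"]
  }
  fr <- if (length(factorResidSd) == 1L)
    setNames(rep(factorResidSd, 4), EF_FACTORS) else factorResidSd
  tau <- if (length(networkDeltaSubjectSd) == 1L)
    setNames(rep(networkDeltaSubjectSd, length(networkSizes)),
             names(networkSizes)) else networkDeltaSubjectSd
  new("CohortSpec", nSubjects = nSubjects, ageRange = as.numeric(ageRange),
      nRois = nRois, networkSizes = networkSizes,
      nTimepoints = nTimepoints, tr = tr, globalWeight = globalWeight,
      globalAmpSd = globalAmpSd, arCoefficient = arCoefficient,
      networkDeltaBaseline = networkDeltaBaseline,
      networkDeltaAgeSlope = networkDeltaAgeSlope,
      networkDeltaSubjectSd = tau, motionModel = motionModel,
      motionDeltaCoef = motionDeltaCoef, factorLoadings = factorLoadings,
      indicatorNoiseSd = indicatorNoiseSd, indicatorMean = indicatorMean,
      indicatorScale = indicatorScale, factorAgeCurve = factorAgeCurve,
      factorResidSd = fr, factorResidCor = factorResidCor,
      gammaMain = gammaMain, gammaInteraction = gammaInteraction,
      timedIndicators = timedIndicators, seed = as.numeric(seed))
}

midAge <- function(spec) mean(spec@ageRange)

#' ROI-to-network assignment implied by a cohort spec
#'
#' ROIs are labeled `ROI001 ...` and assigned to networks in contiguous
#' blocks following `networkSizes`.
#'
#' @param spec a [CohortSpec-class].
#' @return named character vector, ROI label -> network.
#' @export
networkMapFromSpec <- function(spec) {
  labels <- sprintf("ROI%03d", seq_len(spec@nRois))
  setNames(rep(names(spec@networkSizes), times = spec@networkSizes), labels)
}

## Deterministic per-subject seed derived from the master seed.
subjectSeed <- function(seed, i, stage = 0L) {
  (abs(seed) * 100003 + i * 7919 + stage * 337) %% 2147483546 + 1
}

## Age-trended network delta targets (no subject deviation), one per network
## group, at a given age.
networkDeltaAtAge <- function(spec, age) {
  pmax(spec@networkDeltaBaseline +
         spec@networkDeltaAgeSlope * (age - midAge(spec)), 0)
}

#' Generate one subject's synthetic ROI time series
#'
#' Each ROI's signal is `x_i(t) = gAmp * G(t) + s_i * eps_i(t)` where `G`
#' and the `eps_i` are independent stationary AR(1) processes with unit
#' marginal variance and lag-1 coefficient `arCoefficient`. The
#' idiosyncratic scale `s_i` is chosen so the ROI's network-specific
#' (adjustable) expected rMSSD equals the network's age-dependent target
#' `d`: since `E[(x_t - x_{t-1})^2] = 2 sigma^2 (1 - phi)` for such a
#' process, `s_i = d / sqrt(2 (1 - phi))` (which reduces to `d / sqrt(2)`
#' for white noise). The shared component amplitude is
#' `globalWeight * globalAmp * meanBaseline` on the rMSSD scale, so with
#' `globalWeight = 0` the raw rMSSD of each ROI matches its target exactly
#' in expectation, and with a shared component present the
#' whole-brain-adjusted rMSSD does.
#'
#' @param spec a [CohortSpec-class].
#' @param age subject age in years (within `ageRange`).
#' @param subjectSeed integer seed; the call is deterministic given it.
#' @param globalAmp subject's global amplitude multiplier (default 1).
#' @param networkDelta optional named per-network rMSSD targets overriding
#'   the age-trend targets (used to inject subject-level deviations).
#' @param subjectId label for the returned series.
#' @return a [RoiTimeSeries-class] (`nRois` x `nTimepoints`).
#' @export
generateSubjectTimeseries <- function(spec, age, subjectSeed,
                                      globalAmp = 1, networkDelta = NULL,
                                      subjectId = "sim") {
  validObject(spec)
  checkFiniteField(age, "age")
  if (age < spec@ageRange[1] || age > spec@ageRange[2])
    stop("age outside ageRange")
  if (is.null(networkDelta)) networkDelta <- networkDeltaAtAge(spec, age)
  map <- networkMapFromSpec(spec)
  targets <- networkDelta[map]
  phi <- spec@arCoefficient
  diffScale <- sqrt(2 * (1 - phi))
  s <- targets / diffScale
  meanBaseline <- sum(spec@networkSizes * spec@networkDeltaBaseline) /
    spec@nRois
  gAmp <- spec@globalWeight * globalAmp * meanBaseline / diffScale
  n <- spec@nTimepoints
  withSeed(subjectSeed, {
    G <- arUnitSeries(n, 1L, phi)[, 1L]
    E <- arUnitSeries(n, spec@nRois, phi)
    x <- t(E) * s + matrix(gAmp * G, spec@nRois, n, byrow = TRUE)
    rownames(x) <- names(map)
    RoiTimeSeries(subjectId, x, tr = spec@tr)
  })
}

#' Generate synthetic phenotypes and ground truth
#'
#' Draws ages uniformly over the age range; sex (57% female) and handedness
#' (10% left-handed) with the study's approximate marginals; years of
#' education increasing with age into adulthood; mean framewise
#' displacement from the U-shaped motion model; a per-subject global
#' variability amplitude `1 + motionDeltaCoef * (FD - 0.25) + noise`; and
#' per-network rMSSD target deviations, centered across the brain by ROI
#' count so the size-weighted whole-brain deviation is exactly zero.
#'
#' @param spec a [CohortSpec-class].
#' @return list with `phenotypes` (data.frame: subject_id, age, sex,
#'   handedness, education_years, mean_fd) and `truth` (data.frame with the
#'   per-subject global amplitude and true per-network adjusted-rMSSD
#'   targets `delta_<network>`).
#' @export
generatePhenotypes <- function(spec) {
  validObject(spec)
  n <- spec@nSubjects
  withSeed(spec@seed, {
    age <- runif(n, spec@ageRange[1], spec@ageRange[2])
    sex <- ifelse(rbinom(n, 1L, 0.57) == 1L, "female", "male")
    hand <- ifelse(rbinom(n, 1L, 0.10) == 1L, "left", "right")
    edu <- pmin(pmax(age - 5, 0), 12) +
      ifelse(age >= 18, pmax(rnorm(n, 2, 2.5), 0), 0)
    mm <- spec@motionModel
    fd <- mm[["base"]] + mm[["quad"]] * (age - mm[["center"]])^2 +
      rnorm(n, 0, mm[["noise_sd"]])
    fd <- pmax(fd, 0.03)
    amp <- pmax(1 + spec@motionDeltaCoef * (fd - 0.25) +
                  rnorm(n, 0, spec@globalAmpSd), 0.2)
    groups <- names(spec@networkSizes)
    dev <- matrix(rnorm(n * length(groups), 0,
                        rep(spec@networkDeltaSubjectSd[groups], each = n)),
                  n, length(groups), dimnames = list(NULL, groups))
    w <- spec@networkSizes[groups] / spec@nRois
    dev <- dev - drop(dev %*% w)
    trend <- t(vapply(age, function(a) networkDeltaAtAge(spec, a),
                      numeric(length(groups))))
    delta <- pmax(trend + dev, 0.05)
    colnames(delta) <- paste0("delta_", groups)
    id <- sprintf("sub%04d", seq_len(n))
    phen <- data.frame(subject_id = id, age = age, sex = sex,
                       handedness = hand, education_years = round(edu, 1),
                       mean_fd = fd, stringsAsFactors = FALSE)
    truth <- data.frame(subject_id = id, age = age, global_amp = amp,
                        delta, check.names = FALSE,
                        stringsAsFactors = FALSE)
    list(phenotypes = phen, truth = truth)
  })
}

#' Generate the 14 executive-function task scores
#'
#' Latent factor scores follow
#' `f_k = quadratic(age_c) + sum_net [gammaMain * delta_net +
#' gammaInteraction * delta_net * age_c] + u_k` with residuals `u`
#' correlated across the four factors; each indicator is
#' `lambda_j * f_(k(j)) + e_j`, then located/scaled to its published-style
#' mean and SD. Timed indicators are emitted with reversed sign (larger =
#' slower = worse) before relocation.
#'
#' @param spec a [CohortSpec-class].
#' @param truth ground-truth data.frame from [generatePhenotypes()].
#' @param networkDelta optional per-subject matrix/data.frame of the five
#'   network adjusted-rMSSD values (columns CEN, DMN, SN, LN, DA) to drive
#'   the scores; defaults to the generative targets in `truth`, keeping
#'   ground truth exact. Passing re-estimated values gives the end-to-end
#'   mode.
#' @return list with `scores` (data.frame: subject_id + the 14 task
#'   columns) and `trueFactors` (data.frame: subject_id + the four factor
#'   columns).
#' @export
generateTaskScores <- function(spec, truth, networkDelta = NULL) {
  validObject(spec)
  if (!all(spec@timedIndicators %in% EF_INDICATORS))
    stop("unknown indicator label in timedIndicators")
  n <- nrow(truth)
  if (is.null(networkDelta)) {
    networkDelta <- as.matrix(truth[paste0("delta_", BRAIN_NETWORKS)])
    colnames(networkDelta) <- BRAIN_NETWORKS
  }
  networkDelta <- as.matrix(networkDelta)[, BRAIN_NETWORKS, drop = FALSE]
  ageC <- truth$age - midAge(spec)
  curve <- spec@factorAgeCurve
  withSeed(spec@seed + 211L, {
    R <- matrix(spec@factorResidCor, 4, 4); diag(R) <- 1
    u <- matrix(rnorm(n * 4), n, 4) %*% chol(R)
    u <- sweep(u, 2L, spec@factorResidSd[EF_FACTORS], `*`)
    f <- sapply(seq_len(4L), function(k) {
      curve[k, "intercept"] + curve[k, "linear"] * ageC +
        curve[k, "quadratic"] * ageC^2 +
        drop(networkDelta %*% spec@gammaMain[k, ]) +
        ageC * drop(networkDelta %*% spec@gammaInteraction[k, ]) +
        u[, k]
    })
    colnames(f) <- EF_FACTORS
    scores <- sapply(EF_INDICATORS, function(j) {
      lat <- spec@factorLoadings[[j]] * f[, EF_LOADING_PATTERN[[j]]] +
        rnorm(n, 0, spec@indicatorNoiseSd[[j]])
      if (j %in% spec@timedIndicators) lat <- -lat
      spec@indicatorMean[[j]] + spec@indicatorScale[[j]] * lat
    })
    colnames(scores) <- EF_INDICATORS
    list(scores = data.frame(subject_id = truth$subject_id, scores,
                             check.names = FALSE, stringsAsFactors = FALSE),
         trueFactors = data.frame(subject_id = truth$subject_id, f,
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE))
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs [generatePhenotypes()] and [generateTaskScores()], optionally
#' generates every subject's ROI time series, and returns (or writes) the
#' complete study: phenotype table with task scores, ground truth, network
#' map, and time series.
#'
#' @param spec a [CohortSpec-class].
#' @param timeseries logical; also generate ROI time series (memory-heavy
#'   for full-size cohorts — the per-subject generator or
#'   [simulateVariability()] streams them instead).
#' @param dir optional output directory; when given, writes one
#'   `<subject_id>.csv` ROI x time matrix per subject (if `timeseries`),
#'   plus `phenotypes.csv`, `ground_truth.csv`, `network_map.tsv` and the
#'   spec echoed to `cohort_config.yaml`.
#' @return invisibly, a list with `phenotypes`, `truth`, `networkMap`, and
#'   (if requested) `timeseries` (list of [RoiTimeSeries-class]).
#' @export
simulateCohort <- function(spec, timeseries = TRUE, dir = NULL) {
  validObject(spec)
  ph <- generatePhenotypes(spec)
  ts <- generateTaskScores(spec, ph$truth)
  phen <- cbind(ph$phenotypes, ts$scores[-1L])
  truth <- cbind(ph$truth, ts$trueFactors[-1L])
  map <- networkMapFromSpec(spec)
  out <- list(phenotypes = phen, truth = truth, networkMap = map)
  if (timeseries) {
    out$timeseries <- lapply(seq_len(spec@nSubjects), function(i) {
      generateSubjectTimeseries(
        spec, ph$truth$age[i], subjectSeed(spec@seed, i),
        globalAmp = ph$truth$global_amp[i],
        networkDelta = setNames(
          as.numeric(ph$truth[i, paste0("delta_", names(spec@networkSizes))]),
          names(spec@networkSizes)),
        subjectId = phen$subject_id[i])
    })
  }
  if (!is.null(dir)) writeCohort(out, spec, dir)
  invisible(out)
}

#' Stream a synthetic cohort into variability tables
#'
#' Generates each subject's time series, computes raw and adjusted
#' variability profiles, and discards the series — the memory-safe path for
#' full-size cohorts.
#'
#' @param spec a [CohortSpec-class].
#' @inheritParams rmssd
#' @return list with `raw` and `adjusted` tables (see [variabilityTable()]),
#'   `phenotypes`, `truth`, `networkMap`.
#' @export
simulateVariability <- function(spec, denominator = c("n-1", "n-2")) {
  denominator <- match.arg(denominator)
  ph <- generatePhenotypes(spec)
  map <- networkMapFromSpec(spec)
  groups <- names(spec@networkSizes)
  profs <- lapply(seq_len(spec@nSubjects), function(i) {
    ts <- generateSubjectTimeseries(
      spec, ph$truth$age[i], subjectSeed(spec@seed, i),
      globalAmp = ph$truth$global_amp[i],
      networkDelta = setNames(
        as.numeric(ph$truth[i, paste0("delta_", groups)]), groups),
      subjectId = ph$phenotypes$subject_id[i])
    list(raw = variabilityProfile(ts, map, adjust = FALSE,
                                  denominator = denominator),
         adj = variabilityProfile(ts, map, adjust = TRUE,
                                  denominator = denominator))
  })
  list(raw = variabilityTable(lapply(profs, `[[`, "raw")),
       adjusted = variabilityTable(lapply(profs, `[[`, "adj")),
       phenotypes = ph$phenotypes, truth = ph$truth, networkMap = map)
}

#' Emulate measured variability from generative targets
#'
#' Returns the adjusted network and whole-brain variability table a
#' full time-series analysis would produce, without generating series:
#' each group's generative rMSSD target plus its analytic estimation
#' noise. For a near-white difference series averaged over `n_k` ROIs and
#' `T` timepoints the relative standard error of the group-mean rMSSD is
#' approximately `sqrt(1 / (2 (T - 1) n_k))`, which matches the empirical
#' estimation noise of the full pipeline at the default scan length.
#' Whole-brain variability is the ROI-count-weighted mean of the noisy
#' group values (aggregation conservation).
#'
#' @param spec a [CohortSpec-class].
#' @param truth ground-truth data.frame from [generatePhenotypes()].
#' @param seedOffset offset added to the spec seed for the noise draw.
#' @return data.frame with `subject_id`, the five network columns, and
#'   `whole_brain` — the drop-in analogue of the adjusted table from
#'   [simulateVariability()].
#' @export
measuredVariabilityFromTruth <- function(spec, truth, seedOffset = 407L) {
  groups <- names(spec@networkSizes)
  n <- nrow(truth)
  TT <- spec@nTimepoints
  withSeed(spec@seed + seedOffset, {
    hat <- sapply(groups, function(k) {
      t_k <- truth[[paste0("delta_", k)]]
      rel <- sqrt(1 / (2 * (TT - 1) * spec@networkSizes[[k]]))
      t_k * (1 + rnorm(n, 0, rel))
    })
    colnames(hat) <- groups
    wb <- drop(hat %*% (spec@networkSizes[groups] / spec@nRois))
    data.frame(subject_id = truth$subject_id,
               hat[, BRAIN_NETWORKS, drop = FALSE], whole_brain = wb,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
}
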