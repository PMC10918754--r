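#' One subject's parcellated BOLD time series
#'
#' Container for a single subject's region-of-interest (ROI) by time signal
#' matrix, as produced by atlas-based extraction from preprocessed
#' resting-state fMRI. Rows are ROIs (named), columns are timepoints sampled
#' every `tr` seconds.
#'
#' @slot subjectId single character label.
#' @slot signal numeric matrix, ROIs x timepoints; rownames are the ROI
#'   labels and must be unique.
#' @slot tr repetition time in seconds.
#'
#' @exportClass RoiTimeSeries
setClass("RoiTimeSeries",
  representation(subjectId = "character", signal = "matrix", tr = "numeric"))

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be length 1")
  if (ncol(object@signal) < 2L) msg <- c(msg, "at least 2 timepoints required")
  if (!all(is.finite(object@signal))) msg <- c(msg, "signal must be finite")
  rl <- rownames(object@signal)
  if (is.null(rl) || anyDuplicated(rl))
    msg <- c(msg, "signal must have unique ROI rownames")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    msg <- c(msg, "tr must be a positive scalar (seconds)")
  if (length(msg)) msg else TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param subjectId subject label.
#' @param signal numeric ROI x time matrix with ROI rownames (a `roiLabels`
#'   argument may supply them instead).
#' @param tr repetition time, seconds.
#' @param roiLabels optional ROI labels if `signal` has no rownames.
#' @return A [RoiTimeSeries-class] object.
#' @examples
#' ts <- RoiTimeSeries("s1", matrix(rnorm(20), 2, 10,
#'   dimnames = list(c("roiA", "roiB"), NULL)), tr = 1.4)
#' rmssd(ts)
#' @export
RoiTimeSeries <- function(subjectId, signal, tr = 1.4, roiLabels = NULL) {
  signal <- as.matrix(signal)
  if (!is.null(roiLabels)) rownames(signal) <- roiLabels
  new("RoiTimeSeries", subjectId = as.character(subjectId),
      signal = signal, tr = as.numeric(tr))
}

setMethod("show", "RoiTimeSeries", function(object) {
  cat("RoiTimeSeries '", object@subjectId, "': ",
      nrow(object@signal), " ROIs x ", ncol(object@signal),
      " timepoints (TR = ", object@tr, " s)\n", sep = "")
})

#' Synthetic life-span cohort specification
#'
#' Generative parameters for a synthetic resting-state study: cohort size
#' and age range, parcellation and network sizes, scan length, the shared
#' global signal component, per-network rMSSD targets and their age trends,
#' a U-shaped age-to-head-motion model, and the four-factor measurement
#' model that produces 14 task scores. See [cohortSpec()] for field
#' semantics and defaults.
#'
#' @exportClass CohortSpec
setClass("CohortSpec", representation(
  nSubjects = "numeric", ageRange = "numeric", nRois = "numeric",
  networkSizes = "numeric", nTimepoints = "numeric", tr = "numeric",
  globalWeight = "numeric", globalAmpSd = "numeric",
  arCoefficient = "numeric",
  networkDeltaBaseline = "numeric", networkDeltaAgeSlope = "numeric",
  networkDeltaSubjectSd = "numeric",
  motionModel = "numeric", motionDeltaCoef = "numeric",
  factorLoadings = "numeric", indicatorNoiseSd = "numeric",
  indicatorMean = "numeric", indicatorScale = "numeric",
  factorAgeCurve = "matrix", factorResidSd = "numeric",
  factorResidCor = "numeric",
  gammaMain = "matrix", gammaInteraction = "matrix",
  timedIndicators = "character", seed = "numeric"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  num <- c(nSubjects = object@nSubjects, nRois = object@nRois,
           nTimepoints = object@nTimepoints, tr = object@tr,
           globalWeight = object@globalWeight,
           globalAmpSd = object@globalAmpSd,
           arCoefficient = object@arCoefficient,
           motionDeltaCoef = object@motionDeltaCoef, seed = object@seed)
  for (f in names(num)) if (!is.finite(num[[f]]))
    msg <- c(msg, paste0("non-finite value in field '", f, "'"))
  if (!all(is.finite(object@ageRange)) || length(object@ageRange) != 2L ||
      object@ageRange[1] >= object@ageRange[2])
    msg <- c(msg, "ageRange must be finite with min < max")
  if (object@nSubjects < 2) msg <- c(msg, "nSubjects must be >= 2")
  if (abs(object@arCoefficient) >= 1)
    msg <- c(msg, "|arCoefficient| must be < 1")
  if (!isTRUE(all.equal(sum(object@networkSizes), object@nRois)))
    msg <- c(msg, "networkSizes must sum to nRois")
  if (!setequal(names(object@networkSizes), NETWORK_LEVELS))
    msg <- c(msg, "networkSizes must name CEN, DMN, SN, LN, DA, unassigned")
  sds <- c(object@globalAmpSd, object@networkDeltaSubjectSd,
           object@indicatorNoiseSd, object@factorResidSd,
           object@motionModel["noise_sd"])
  if (!all(is.finite(sds)) || any(sds < 0))
    msg <- c(msg, "all SD fields must be finite and >= 0")
  if (!identical(sort(names(object@factorLoadings)), sort(EF_INDICATORS)))
    msg <- c(msg, "factorLoadings must cover the 14 indicators")
  if (!all(object@timedIndicators %in% EF_INDICATORS))
    msg <- c(msg, "unknown indicator label in timedIndicators")
  if (!identical(dim(object@gammaMain), c(4L, 5L)) ||
      !identical(dim(object@gammaInteraction), c(4L, 5L)))
    msg <- c(msg, "gammaMain and gammaInteraction must be 4 factors x 5 networks")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec: ", object@nSubjects, " subjects, ages ",
      object@ageRange[1], "-", object@ageRange[2], ", ",
      object@nRois, " ROIs / ", length(object@networkSizes) - 1L,
      " networks, ", object@nTimepoints, " timepoints @ TR ",
      object@tr, " s (seed ", object@seed, ")\n", sep = "")
})

#' Per-subject signal variability profile
#'
#' Per-ROI rMSSD (`deltaRoi`), per-network mean rMSSD (`deltaNetwork`) and
#' whole-brain mean rMSSD for one subject, in one of three variants:
#' `"raw"`, `"adjusted"` (after whole-brain successive-difference
#' regression), or `"motion_residualized"`.
#'
#' @exportClass VariabilityProfile
setClass("VariabilityProfile", representation(
  subjectId = "character", deltaRoi = "numeric", deltaNetwork = "numeric",
  deltaWholeBrain = "numeric", variant = "character"))

setValidity("VariabilityProfile", function(object) {
  msg <- character()
  if (!object@variant %in% c("raw", "adjusted", "motion_residualized"))
    msg <- c(msg, "variant must be raw, adjusted or motion_residualized")
  if (object@variant %in% c("raw", "adjusted")) {
    if (any(object@deltaRoi < 0)) msg <- c(msg, "delta must be >= 0")
    if (length(object@deltaRoi) &&
        !isTRUE(all.equal(object@deltaWholeBrain,
                          mean(object@deltaRoi), tolerance = 1e-8)))
      msg <- c(msg, "deltaWholeBrain must equal the mean of deltaRoi")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "VariabilityProfile", function(object) {
  cat("VariabilityProfile '", object@subjectId, "' (", object@variant,
      "): whole-brain delta = ", signif(object@deltaWholeBrain, 4),
      "; networks: ", paste(names(object@deltaNetwork),
        signif(object@deltaNetwork, 3), sep = "=", collapse = ", "),
      "\n", sep = "")
})

#' Confirmatory factor model specification
#'
#' A loading pattern mapping each observed indicator to one latent factor,
#' an optional set of free residual covariances, and the set of
#' reverse-coded (timed) indicators. Identification is by unit factor
#' variances with all loadings free.
#'
#' @exportClass FactorModelSpec
setClass("FactorModelSpec", representation(
  indicators = "character", loadingPattern = "character",
  factors = "character", residualCovariances = "matrix",
  reverseCoded = "character", taskMap = "character"))

setValidity("FactorModelSpec", function(object) {
  msg <- character()
  if (anyDuplicated(object@indicators)) msg <- c(msg, "duplicate indicators")
  if (!identical(sort(names(object@loadingPattern)), sort(object@indicators)))
    msg <- c(msg, "loadingPattern must cover exactly the indicators")
  if (!all(object@loadingPattern %in% object@factors))
    msg <- c(msg, "loadingPattern values must be declared factors")
  rc <- object@residualCovariances
  if (ncol(rc) != 2L) msg <- c(msg, "residualCovariances must have 2 columns")
  if (nrow(rc)) {
    if (!all(rc %in% object@indicators))
      msg <- c(msg, "residual covariance names unknown")
    sameFactor <- object@loadingPattern[rc[, 1L]] ==
      object@loadingPattern[rc[, 2L]]
    sameTask <- object@taskMap[rc[, 1L]] == object@taskMap[rc[, 2L]]
    if (!all(sameFactor & sameTask))
      msg <- c(msg,
        "residual covariances must pair same-task, same-factor indicators")
  }
  if (!all(object@reverseCoded %in% object@indicators))
    msg <- c(msg, "unknown indicator label in reverseCoded")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FactorModelSpec", function(object) {
  cat("FactorModelSpec: ", length(object@indicators), " indicators, ",
      length(object@factors), " correlated factors, ",
      nrow(object@residualCovariances), " residual covariance(s); df = ",
      modelDf(object), "\n", sep = "")
})

#' Fitted confirmatory factor model
#'
#' Maximum-likelihood estimates of a [FactorModelSpec-class]: loading matrix
#' `lambda` (p x m), factor correlation matrix `phi`, residual covariance
#' `theta`, indicator means `mu`, implied covariance `sigma`, the sample
#' covariance `S` and size `n`, the ML discrepancy `fml` with chi-square,
#' degrees of freedom and fit indices (CFI, RMSEA, SRMR), and the
#' regression-method factor-score weight matrix `scoreWeights` (m x p).
#'
#' @exportClass FittedFactorModel
setClass("FittedFactorModel", representation(
  spec = "FactorModelSpec", lambda = "matrix", phi = "matrix",
  theta = "matrix", mu = "numeric", sigma = "matrix", S = "matrix",
  n = "numeric", fml = "numeric", chisq = "numeric", df = "numeric",
  cfi = "numeric", rmsea = "numeric", srmr = "numeric",
  baselineChisq = "numeric", baselineDf = "numeric",
  converged = "logical", gradNorm = "numeric", heywood = "logical",
  scoreWeights = "matrix"))

setMethod("show", "FittedFactorModel", function(object) {
  cat("FittedFactorModel: ", nrow(object@lambda), " indicators, ",
      ncol(object@lambda), " factors, n = ", object@n, "\n",
      "  chi-square(", object@df, ") = ", round(object@chisq, 2),
      ", CFI = ", round(object@cfi, 3),
      ", RMSEA = ", round(object@rmsea, 3),
      ", SRMR = ", round(object@srmr, 3), "\n",
      "  converged: ", object@converged,
      if (object@heywood) " [Heywood case flagged]" else "", "\n", sep = "")
})
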