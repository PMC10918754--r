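# Shared fixtures: small cohort specs and hand-built time series.

## Compact spec: 30 ROIs, short scans — fast end-to-end runs.
tinySpec <- function(nSubjects = 24, nTimepoints = 80, seed = 42, ...) {
  cohortSpec(nSubjects = nSubjects,
             networkSizes = c(CEN = 6, DMN = 6, SN = 5, LN = 5, DA = 4,
                              unassigned = 4),
             nTimepoints = nTimepoints, seed = seed, ...)
}

## Uniform delta targets / zero slopes helper for calibration fixtures.
flatTargets <- function(value, groups = NETWORK_LEVELS) {
  setNames(rep(value, length(groups)), groups)
}

## A RoiTimeSeries built from an explicit matrix.
makeSeries <- function(m, id = "s1", tr = 1.4) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("r%02d", seq_len(nrow(m)))
  RoiTimeSeries(id, m, tr = tr)
}

## Generative-pathway replicate: phenotypes, measured variability, scores.
simReplicate <- function(spec) {
  ph <- generatePhenotypes(spec)
  list(phenotypes = ph$phenotypes, truth = ph$truth,
       variability = measuredVariabilityFromTruth(spec, ph$truth),
       scores = generateTaskScores(spec, ph$truth))
}
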