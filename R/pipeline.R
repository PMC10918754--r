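# File interchange and the end-to-end pipeline driver:
# simulate -> variability -> cfa -> regress -> report.

#' Write a simulated cohort to disk
#'
#' Writes `phenotypes.csv`, `ground_truth.csv`, `network_map.tsv`, the
#' generative spec echoed to `cohort_config.yaml`, and (when present) one
#' `<subject_id>.csv` per subject under `timeseries/` — timepoints in rows,
#' one column per ROI with a header row of ROI labels.
#'
#' @param cohort list from [simulateCohort()].
#' @param spec the generating [CohortSpec-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
            row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  write.table(data.frame(roi_label = names(cohort$networkMap),
                         network = unname(cohort$networkMap)),
              file.path(dir, "network_map.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  yaml::write_yaml(specAsList(spec), file.path(dir, "cohort_config.yaml"))
  if (!is.null(cohort$timeseries)) {
    tsd <- file.path(dir, "timeseries")
    dir.create(tsd, showWarnings = FALSE)
    for (ts in cohort$timeseries) {
      m <- t(signalMatrix(ts))
      write.csv(m, file.path(tsd, paste0(subjectId(ts), ".csv")),
                row.names = FALSE)
    }
  }
  invisible(dir)
}

## Echo a CohortSpec as a plain list (YAML-ready).
specAsList <- function(spec) {
  nm <- slotNames(spec)
  out <- lapply(nm, function(s) {
    v <- slot(spec, s)
    if (is.matrix(v)) as.data.frame(v) else as.list(v)
  })
  names(out) <- nm
  out
}

#' Read a directory of ROI time-series matrices
#'
#' Reads every `*.csv`/`*.tsv` file (timepoints x ROIs, header row of ROI
#' labels; the subject id is the file name) into [RoiTimeSeries-class]
#' objects. A consistent ROI label set and order is enforced across
#' subjects. Subjects with non-finite values or fewer than 10 timepoints
#' are skipped with a logged reason, echoing quality-control exclusion.
#'
#' @param path directory of delimited matrices.
#' @param tr repetition time (seconds) to attach to each series.
#' @return named list of [RoiTimeSeries-class]; excluded subjects are
#'   reported via `message()` and recorded in the `"excluded"` attribute.
#' @export
readTimeseriesDir <- function(path, tr = 1.4) {
  files <- list.files(path, pattern = "\\.(csv|tsv)$", full.names = TRUE)
  if (!length(files)) stop("no time-series files found in ", path)
  ref <- NULL
  out <- list()
  excluded <- character()
  for (f in sort(files)) {
    sep <- if (grepl("\\.tsv$", f)) "\t" else ","
    m <- as.matrix(read.csv(f, sep = sep, check.names = FALSE))
    id <- sub("\\.(csv|tsv)$", "", basename(f))
    if (is.null(ref)) ref <- colnames(m)
    if (!identical(colnames(m), ref))
      stop("ROI header mismatch in file ", basename(f))
    if (!all(is.finite(m))) {
      message("excluding ", id, ": non-finite values")
      excluded <- c(excluded, id)
      next
    }
    if (nrow(m) < 10L) {
      message("excluding ", id, ": fewer than 10 timepoints")
      excluded <- c(excluded, id)
      next
    }
    out[[id]] <- RoiTimeSeries(id, t(m), tr = tr)
  }
  attr(out, "excluded") <- excluded
  out
}

#' Read and screen a phenotype table
#'
#' Requires columns `subject_id`, `age`, `sex`, `handedness`,
#' `education_years`, `mean_fd` and the 14 task labels. Subjects whose
#' mean framewise displacement is 0.5 mm or more are excluded (strict
#' `< 0.5` inclusion), with a log line per exclusion.
#'
#' @param path CSV path.
#' @param fdLimit exclusion threshold for mean FD (mm).
#' @return screened data.frame; excluded subject ids in the `"excluded"`
#'   attribute.
#' @export
readPhenotypes <- function(path, fdLimit = 0.5) {
  dat <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c(PHENOTYPE_COLUMNS, EF_INDICATORS)
  missing <- setdiff(required, names(dat))
  if (length(missing))
    stop("phenotype table lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(dat$subject_id))
    stop("duplicate subject_id in phenotype table")
  drop <- dat$mean_fd >= fdLimit
  for (id in dat$subject_id[drop])
    message("excluding ", id, ": mean FD >= ", fdLimit, " mm")
  out <- dat[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- dat$subject_id[drop]
  out
}

#' Read a ROI-to-network map
#'
#' @param path two-column TSV (`roi_label`, `network`).
#' @return named character vector, ROI label -> network.
#' @export
readNetworkMap <- function(path) {
  dat <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("roi_label", "network") %in% names(dat)))
    stop("network map needs columns roi_label and network")
  setNames(dat$network, dat$roi_label)
}

#' Default pipeline configuration
#'
#' @param outDir output directory for all artifacts.
#' @param seed master seed propagated to every stochastic stage.
#' @param simulate NULL to read inputs from `timeseriesDir`/`phenotypes`,
#'   or a named list of [cohortSpec()] overrides to simulate the study.
#' @param timeseriesDir,phenotypesFile,networkMapFile input paths (ignored
#'   when simulating).
#' @param adjust apply the whole-brain difference adjustment.
#' @param denominator rMSSD denominator convention.
#' @param modify number of residual covariances to free in the CFA.
#' @param polyDegree degree of the age curves.
#' @param slopeAges ages for simple slopes.
#' @param tr repetition time for read time series.
#' @return config list for [runPipeline()].
#' @export
pipelineConfig <- function(outDir, seed = 1L, simulate = list(),
                           timeseriesDir = NULL, phenotypesFile = NULL,
                           networkMapFile = NULL, adjust = TRUE,
                           denominator = "n-1", modify = 4L,
                           polyDegree = 2L, slopeAges = COHORT_AGES,
                           tr = 1.4) {
  list(outDir = outDir, seed = seed, simulate = simulate,
       timeseriesDir = timeseriesDir, phenotypesFile = phenotypesFile,
       networkMapFile = networkMapFile, adjust = adjust,
       denominator = denominator, modify = modify, polyDegree = polyDegree,
       slopeAges = slopeAges, tr = tr)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or ingest) -> variability (raw, adjusted,
#' motion-residualized, network correlation matrices) -> measurement model
#' (reverse coding, baseline and modified CFA, factor scores) -> life-span
#' regressions (48-model family, FDR, simple slopes, age curves), writing
#' every intermediate artifact to `config$outDir`. Fully reproducible from
#' the config and seed. Any stage failure halts with the stage name.
#'
#' @param config list from [pipelineConfig()] or a YAML file path with the
#'   same fields.
#' @return invisibly, a list with all in-memory results (`variability`,
#'   `cfa`, `regression`, `ageCurves`, `phenotypes`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    spec <- stage("simulate",
                  do.call(cohortSpec, c(config$simulate,
                                        list(seed = config$seed))))
    sim <- stage("simulate",
                 simulateVariability(spec,
                                     denominator = config$denominator))
    scores <- stage("simulate", generateTaskScores(spec, sim$truth)$scores)
    phen <- cbind(sim$phenotypes, scores[-1L])
    rawTab <- sim$raw; adjTab <- sim$adjusted
    write.csv(sim$truth, file.path(config$outDir, "ground_truth.csv"),
              row.names = FALSE)
  } else {
    tsList <- stage("ingest", readTimeseriesDir(config$timeseriesDir,
                                                tr = config$tr))
    map <- stage("ingest", readNetworkMap(config$networkMapFile))
    phen <- stage("ingest", readPhenotypes(config$phenotypesFile))
    tsList <- tsList[intersect(names(tsList), phen$subject_id)]
    phen <- phen[phen$subject_id %in% names(tsList), , drop = FALSE]
    rawTab <- stage("variability", variabilityTable(
      lapply(tsList, variabilityProfile, networkMap = map, adjust = FALSE,
             denominator = config$denominator)))
    adjTab <- stage("variability", variabilityTable(
      lapply(tsList, variabilityProfile, networkMap = map, adjust = TRUE,
             denominator = config$denominator)))
    scores <- phen[c("subject_id", EF_INDICATORS)]
  }
  phen <- phen[match(rawTab$subject_id, phen$subject_id), , drop = FALSE]

  useTab <- if (isTRUE(config$adjust)) adjTab else rawTab
  residTab <- stage("variability",
                    residualizeMotion(useTab, phen$mean_fd))
  corRaw <- stage("variability", networkCorrelationMatrix(rawTab))
  corAdj <- stage("variability", networkCorrelationMatrix(adjTab))
  write.csv(rawTab, file.path(config$outDir, "variability_raw.csv"),
            row.names = FALSE)
  write.csv(adjTab, file.path(config$outDir, "variability_adjusted.csv"),
            row.names = FALSE)
  write.csv(residTab,
            file.path(config$outDir, "variability_residualized.csv"),
            row.names = FALSE)
  write.csv(cbind(network = rownames(corRaw), as.data.frame(corRaw)),
            file.path(config$outDir, "network_correlations_raw.csv"),
            row.names = FALSE)
  write.csv(cbind(network = rownames(corAdj), as.data.frame(corAdj)),
            file.path(config$outDir, "network_correlations_adjusted.csv"),
            row.names = FALSE)

  cfa <- stage("cfa", fitEfModel(scores, modify = config$modify))
  write.csv(cfa$factorScores,
            file.path(config$outDir, "factor_scores.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(baseline = as.list(fitIndices(cfa$baseline)),
         modified = as.list(fitIndices(cfa$modified)),
         modification = cfa$modification,
         loadings = as.data.frame(factorLoadings(cfa$modified)),
         factor_correlations = as.data.frame(factorCor(cfa$modified))),
    file.path(config$outDir, "cfa_fit.json"), auto_unbox = TRUE,
    digits = NA)

  reg <- stage("regress", runModelFamily(cfa$factorScores, residTab, phen,
                                         slopeAges = config$slopeAges))
  write.csv(reg$table, file.path(config$outDir, "table2_long.csv"),
            row.names = FALSE)
  write.csv(reg$simpleSlopes,
            file.path(config$outDir, "simple_slopes.csv"),
            row.names = FALSE)
  curves <- stage("regress", agePolynomial(cfa$factorScores, phen,
                                           degree = config$polyDegree))
  write.csv(curves, file.path(config$outDir, "age_curves.csv"),
            row.names = FALSE)
  invisible(list(variability = list(raw = rawTab, adjusted = adjTab,
                                    residualized = residTab,
                                    corRaw = corRaw, corAdjusted = corAdj),
                 cfa = cfa, regression = reg, ageCurves = curves,
                 phenotypes = phen))
}
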