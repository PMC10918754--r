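# Signal variability: rMSSD, whole-brain successive-difference adjustment,
# network aggregation, motion residualization, network correlation matrices.

#' Root mean squared successive differences (rMSSD)
#'
#' Moment-to-moment variability of a time series:
#' \deqn{\delta = \sqrt{\sum_{t=2}^{n} (x_{t-1} - x_t)^2 / (n - 1)}}
#' where \eqn{n} is the number of timepoints. Unlike the standard deviation,
#' rMSSD is sensitive to temporal ordering and robust to slow trends, and is
#' less inflated by autocorrelation. The conventional denominator is
#' \eqn{n - 1} (the number of successive differences); `denominator = "n-2"`
#' is available as an alternative convention.
#'
#' For a [RoiTimeSeries-class] the statistic is computed per ROI.
#'
#' @param x numeric vector (one series) or a [RoiTimeSeries-class].
#' @param denominator `"n-1"` (default) or `"n-2"`.
#' @return nonnegative scalar, or a named per-ROI vector for a
#'   [RoiTimeSeries-class].
#' @details rMSSD is invariant to adding a constant and scales with `|a|`
#'   under multiplication by `a`. For an i.i.d. series with variance
#'   \eqn{\sigma^2}, \eqn{E[(x_t - x_{t-1})^2] = 2\sigma^2}, so
#'   \eqn{\delta \to \sqrt{2}\sigma}; for a stationary AR(1) with lag-1
#'   coefficient \eqn{\phi}, \eqn{\delta \to \sqrt{2\sigma^2(1-\phi)}}.
#' @examples
#' rmssd(c(0, 2, 0, 2))   # sqrt(12/3) = 2
#' @export
rmssd <- function(x, denominator = c("n-1", "n-2")) {
  denominator <- match.arg(denominator)
  if (is(x, "RoiTimeSeries")) {
    m <- signalMatrix(x)
    return(apply(m, 1L, rmssd, denominator = denominator))
  }
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("rmssd requires at least 2 timepoints")
  if (!all(is.finite(x))) stop("rmssd requires finite input")
  den <- if (denominator == "n-1") n - 1L else n - 2L
  if (den < 1L) stop("series too short for denominator convention")
  d <- x[-n] - x[-1L]
  sqrt(sum(d^2) / den)
}

#' Successive-difference matrix of a subject's ROI signals
#'
#' @param ts a [RoiTimeSeries-class].
#' @return ROI x (time - 1) matrix of differences \eqn{x_{t-1} - x_t}.
#' @keywords internal
successiveDifferences <- function(ts) {
  m <- signalMatrix(ts)
  m[, -ncol(m), drop = FALSE] - m[, -1L, drop = FALSE]
}

#' Whole-brain adjustment of successive differences
#'
#' Implements the global-variability adjustment: for each ROI the
#' successive-difference series \eqn{d_i(t) = x_i(t-1) - x_i(t)} is
#' residualized by ordinary least squares (with intercept) on the
#' whole-brain mean difference series \eqn{g(t)}, the average of
#' \eqn{d_i(t)} over all ROIs at each timepoint. The residual difference
#' series have exactly zero sample covariance with \eqn{g}, so variability
#' computed from them is orthogonalized from global signal variability,
#' analogous to global signal regression but on the difference series.
#'
#' If \eqn{g} is constant across time (a degenerate regressor), each ROI's
#' difference series is mean-centered instead.
#'
#' @param ts a [RoiTimeSeries-class] with at least 3 timepoints.
#' @return ROI x (time - 1) matrix of adjusted (residual) differences.
#' @seealso [adjustedRmssd()]
#' @export
adjustGlobalDifferences <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeries"))
  if (ncol(signalMatrix(ts)) < 3L)
    stop("adjustment requires at least 3 timepoints")
  d <- successiveDifferences(ts)
  g <- colMeans(d)
  t(residualizeColumns(t(d), g))
}

#' rMSSD after whole-brain difference adjustment
#'
#' Applies the rMSSD form (sum of squared differences over the raw-series
#' denominator, square root) to the residual difference series from
#' [adjustGlobalDifferences()], yielding per-ROI variability net of the
#' global component. The denominator convention matches the raw statistic
#' (number of original timepoints minus 1 by default), so adjusted and raw
#' values are directly comparable.
#'
#' @inheritParams adjustGlobalDifferences
#' @inheritParams rmssd
#' @return named per-ROI vector of adjusted delta values (all `>= 0`).
#' @export
adjustedRmssd <- function(ts, denominator = c("n-1", "n-2")) {
  denominator <- match.arg(denominator)
  n <- ncol(signalMatrix(ts))
  den <- if (denominator == "n-1") n - 1L else n - 2L
  r <- adjustGlobalDifferences(ts)
  sqrt(rowSums(r^2) / den)
}

#' Aggregate ROI variability to networks and whole brain
#'
#' Per-network unweighted mean of member-ROI delta values, plus the
#' whole-brain mean over all ROIs (including any not assigned to one of the
#' five networks).
#'
#' @param delta named per-ROI numeric vector.
#' @param networkMap named character vector, ROI label -> network label.
#'   Every ROI in `delta` must have an entry.
#' @return list with `network` (named means, empty networks dropped with a
#'   warning) and `wholeBrain` (scalar).
#' @examples
#' aggregateDelta(c(a = 1, b = 3, c = 5),
#'                c(a = "CEN", b = "CEN", c = "DMN"))
#' @export
aggregateDelta <- function(delta, networkMap) {
  if (!all(names(delta) %in% names(networkMap)))
    stop("network map does not cover all ROIs: ",
         paste(setdiff(names(delta), names(networkMap)), collapse = ", "))
  net <- networkMap[names(delta)]
  present <- intersect(NETWORK_LEVELS, unique(net))
  levels <- setdiff(present, "unassigned")
  empty <- setdiff(setdiff(unique(networkMap), "unassigned"), net)
  if (length(empty))
    warning("network(s) with no member ROIs dropped: ",
            paste(empty, collapse = ", "))
  means <- vapply(levels, function(k) mean(delta[net == k]), numeric(1))
  list(network = means, wholeBrain = mean(delta))
}

#' Compute a subject's variability profile
#'
#' Computes per-ROI rMSSD (raw, or whole-brain-adjusted), aggregates to the
#' five networks and the whole brain, and returns a
#' [VariabilityProfile-class].
#'
#' @param ts a [RoiTimeSeries-class].
#' @param networkMap named character vector, ROI label -> network.
#' @param adjust logical; apply the whole-brain difference adjustment.
#' @inheritParams rmssd
#' @return a [VariabilityProfile-class] (variant `"adjusted"` or `"raw"`).
#' @export
variabilityProfile <- function(ts, networkMap, adjust = TRUE,
                               denominator = c("n-1", "n-2")) {
  denominator <- match.arg(denominator)
  delta <- if (adjust) adjustedRmssd(ts, denominator)
           else rmssd(ts, denominator)
  agg <- aggregateDelta(delta, networkMap)
  new("VariabilityProfile", subjectId = subjectId(ts), deltaRoi = delta,
      deltaNetwork = agg$network, deltaWholeBrain = agg$wholeBrain,
      variant = if (adjust) "adjusted" else "raw")
}

#' Tabulate network and whole-brain variability across subjects
#'
#' @param profiles list of [VariabilityProfile-class] objects (one variant).
#' @return data.frame with `subject_id`, one column per network, and
#'   `whole_brain`.
#' @export
variabilityTable <- function(profiles) {
  stopifnot(length(profiles) > 0L)
  nets <- names(profiles[[1L]]@deltaNetwork)
  rows <- lapply(profiles, function(p) {
    stopifnot(identical(names(p@deltaNetwork), nets))
    c(p@deltaNetwork, whole_brain = p@deltaWholeBrain)
  })
  out <- data.frame(subject_id = vapply(profiles, subjectId, character(1)),
                    do.call(rbind, rows), check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Residualize variability summaries on head motion
#'
#' For each variability column, returns the OLS residuals (with intercept)
#' of delta on per-subject mean framewise displacement, computed across
#' subjects. Residuals have exactly zero sample correlation with motion and
#' may be negative. Zero-variance motion falls back to mean-centering.
#'
#' @param deltaTable data.frame from [variabilityTable()] (a `subject_id`
#'   column plus numeric summary columns).
#' @param motion numeric per-subject mean framewise displacement, aligned
#'   with the rows of `deltaTable`.
#' @return data.frame of the same shape, variability columns replaced by
#'   motion residuals.
#' @export
residualizeMotion <- function(deltaTable, motion) {
  stopifnot(nrow(deltaTable) >= 3L, length(motion) == nrow(deltaTable))
  if (!all(is.finite(motion))) stop("motion values must be finite")
  numCols <- setdiff(names(deltaTable), "subject_id")
  resid <- residualizeColumns(as.matrix(deltaTable[numCols]), motion)
  for (j in seq_along(numCols))
    deltaTable[[numCols[j]]] <- unname(resid[, j])
  deltaTable
}

#' Between-subject correlations of network variability
#'
#' Pearson correlation matrix, across subjects, of the five network
#' variability summaries plus whole-brain variability — the before/after
#' contrast used to demonstrate that the whole-brain adjustment
#' orthogonalizes network-specific from global variability.
#'
#' @param deltaTable data.frame from [variabilityTable()] (one variant).
#' @return symmetric correlation matrix with unit diagonal; columns with
#'   zero variance produce `NA` entries and a warning (never silent zeros).
#' @export
networkCorrelationMatrix <- function(deltaTable) {
  stopifnot(nrow(deltaTable) >= 3L)
  m <- as.matrix(deltaTable[setdiff(names(deltaTable), "subject_id")])
  zv <- apply(m, 2L, stats::sd) == 0
  if (any(zv))
    warning("zero-variance column(s): ", paste(colnames(m)[zv],
            collapse = ", "), "; correlations undefined (NA)")
  suppressWarnings(stats::cor(m))
}
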