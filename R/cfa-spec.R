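# Factor model specification: the correlated four-factor executive-function
# measurement model, degrees of freedom, residual-covariance eligibility,
# and orientation (reverse coding) of timed scores.

#' Construct a factor model specification
#'
#' General constructor for a confirmatory factor model with one loading per
#' indicator, unit-variance factors (all loadings free), free factor
#' covariances, and an optional set of free residual covariances.
#'
#' @param loadingPattern named character vector, indicator -> factor label.
#'   Indicator order is taken from its names.
#' @param residualCovariances NULL, or a 2-column character matrix (or list
#'   of length-2 vectors) of indicator pairs whose residual covariance is
#'   freed. Pairs must share both the source task and the factor.
#' @param reverseCoded indicators whose observed scores must be negated
#'   before fitting (timed scores, lower = better).
#' @param taskMap named character vector, indicator -> source task,
#'   constraining residual-covariance eligibility.
#' @return a validated [FactorModelSpec-class].
#' @seealso [efFactorModel()] for the default executive-function model.
#' @export
factorModelSpec <- function(loadingPattern, residualCovariances = NULL,
                            reverseCoded = character(),
                            taskMap = setNames(names(loadingPattern),
                                               names(loadingPattern))) {
  rc <- if (is.null(residualCovariances))
    matrix(character(), 0L, 2L)
  else if (is.list(residualCovariances))
    do.call(rbind, residualCovariances)
  else as.matrix(residualCovariances)
  new("FactorModelSpec", indicators = names(loadingPattern),
      loadingPattern = loadingPattern,
      factors = unique(unname(loadingPattern)),
      residualCovariances = rc, reverseCoded = reverseCoded,
      taskMap = taskMap)
}

#' The correlated four-factor executive-function model
#'
#' The default measurement model over the 14 task scores: cognitive
#' flexibility (CST, LF, CF, TMT-B, CS), inhibitory control (CWI-I, CWI-S),
#' processing speed (TMT-A, TMT-MS, RT), and working memory (0-back,
#' 1-back, 2-back, CPT). Factors are identified by unit variances with all
#' loadings free — the convention under which the baseline model has 71
#' degrees of freedom. Timed scores are marked reverse-coded so that every
#' factor is oriented as ability.
#'
#' @param residualCovariances optional residual-covariance pairs passed to
#'   [factorModelSpec()]; pairs must share task and factor (e.g. LF-CF).
#' @return a [FactorModelSpec-class].
#' @examples
#' modelDf(efFactorModel())                               # 71
#' modelDf(efFactorModel(list(c("LF", "CF"), c("0-back", "1-back"),
#'                            c("1-back", "2-back"), c("CWI-I", "CWI-S"))))
#' @export
efFactorModel <- function(residualCovariances = NULL) {
  factorModelSpec(EF_LOADING_PATTERN, residualCovariances,
                  reverseCoded = EF_TIMED_INDICATORS, taskMap = EF_TASK_MAP)
}

#' @rdname modelDf
#' @export
setMethod("modelDf", "FactorModelSpec", function(object) {
  p <- length(object@indicators)
  m <- length(object@factors)
  q <- p + p + m * (m - 1) / 2 + nrow(object@residualCovariances)
  df <- p * (p + 1) / 2 - q
  if (df < 0) stop("over-parameterized model: df = ", df)
  as.integer(df)
})

#' Residual-covariance pairs eligible for freeing
#'
#' Indicator pairs drawn from the same cognitive task and loading on the
#' same latent factor, excluding pairs already freed in the spec.
#'
#' @param spec a [FactorModelSpec-class].
#' @return 2-column character matrix of eligible pairs (possibly 0 rows).
#' @export
eligibleResidualPairs <- function(spec) {
  ind <- spec@indicators
  pairs <- t(utils::combn(ind, 2L))
  keep <- spec@loadingPattern[pairs[, 1L]] ==
    spec@loadingPattern[pairs[, 2L]] &
    spec@taskMap[pairs[, 1L]] == spec@taskMap[pairs[, 2L]]
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(spec@residualCovariances)) {
    key <- function(m) apply(m, 1L, function(r) paste(sort(r), collapse = "|"))
    pairs <- pairs[!key(pairs) %in% key(spec@residualCovariances), ,
                   drop = FALSE]
  }
  pairs
}

#' Add residual covariances to a model specification
#'
#' @param spec a [FactorModelSpec-class].
#' @param pairs 2-column character matrix or list of indicator pairs.
#' @return a new [FactorModelSpec-class] with the pairs freed.
#' @export
addResidualCovariances <- function(spec, pairs) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  factorModelSpec(spec@loadingPattern,
                  rbind(spec@residualCovariances, pairs),
                  reverseCoded = spec@reverseCoded, taskMap = spec@taskMap)
}

#' Orient timed scores so that larger means better
#'
#' Negates the listed columns (completion times / reaction times) so every
#' indicator is scored in the ability direction before model fitting. The
#' returned table carries a marker attribute; applying the function twice
#' is blocked with an error rather than silently undoing the orientation.
#'
#' @param data data.frame or matrix of task scores.
#' @param reverseCoded column labels to negate.
#' @return `data` with listed columns negated and attribute
#'   `reverseCoded` set.
#' @examples
#' reverseCode(data.frame(`TMT-A` = c(30, 40), check.names = FALSE),
#'             "TMT-A")
#' @export
reverseCode <- function(data, reverseCoded) {
  if (isTRUE(attr(data, "reverseCoded")))
    stop("reverseCode already applied to this table")
  unknown <- setdiff(reverseCoded, colnames(data))
  if (length(unknown))
    stop("unknown indicator label(s): ", paste(unknown, collapse = ", "))
  for (j in reverseCoded) data[, j] <- -data[, j]
  attr(data, "reverseCoded") <- TRUE
  data
}
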