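#' @name boldvar-accessors
#' @title Accessors for boldvar S4 classes
#' @description Small accessor generics for the core containers.
#' @param object an object of the documented class.
NULL

#' @rdname boldvar-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname boldvar-accessors
#' @export
setMethod("subjectId", "RoiTimeSeries", function(object) object@subjectId)

#' @rdname boldvar-accessors
#' @export
setMethod("subjectId", "VariabilityProfile", function(object) object@subjectId)

#' @rdname boldvar-accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @rdname boldvar-accessors
#' @export
setMethod("signalMatrix", "RoiTimeSeries", function(object) object@signal)

#' @rdname boldvar-accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))

#' @rdname boldvar-accessors
#' @export
setMethod("roiLabels", "RoiTimeSeries",
          function(object) rownames(object@signal))

#' @rdname boldvar-accessors
#' @export
setGeneric("repetitionTime", function(object) standardGeneric("repetitionTime"))

#' @rdname boldvar-accessors
#' @export
setMethod("repetitionTime", "RoiTimeSeries", function(object) object@tr)

#' @rdname boldvar-accessors
#' @export
setGeneric("deltaRoi", function(object) standardGeneric("deltaRoi"))

#' @rdname boldvar-accessors
#' @export
setMethod("deltaRoi", "VariabilityProfile", function(object) object@deltaRoi)

#' @rdname boldvar-accessors
#' @export
setGeneric("deltaNetwork", function(object) standardGeneric("deltaNetwork"))

#' @rdname boldvar-accessors
#' @export
setMethod("deltaNetwork", "VariabilityProfile",
          function(object) object@deltaNetwork)

#' @rdname boldvar-accessors
#' @export
setGeneric("deltaWholeBrain", function(object) standardGeneric("deltaWholeBrain"))

#' @rdname boldvar-accessors
#' @export
setMethod("deltaWholeBrain", "VariabilityProfile",
          function(object) object@deltaWholeBrain)

#' @rdname boldvar-accessors
#' @export
setGeneric("variant", function(object) standardGeneric("variant"))

#' @rdname boldvar-accessors
#' @export
setMethod("variant", "VariabilityProfile", function(object) object@variant)

#' Model degrees of freedom
#'
#' Degrees of freedom of a covariance-structure model: unique covariance
#' moments \eqn{p(p+1)/2} minus free parameters. Under unit-factor-variance
#' identification the free parameters are all \eqn{p} loadings, \eqn{p}
#' residual variances, \eqn{m(m-1)/2} factor covariances, and one parameter
#' per freed residual covariance.
#'
#' @param object a [FactorModelSpec-class] or [FittedFactorModel-class].
#' @return integer degrees of freedom.
#' @examples
#' modelDf(efFactorModel())            # 71 for the four-factor model
#' @export
setGeneric("modelDf", function(object) standardGeneric("modelDf"))

#' @rdname modelDf
#' @export
setMethod("modelDf", "FittedFactorModel",
          function(object) as.integer(object@df))

#' @rdname boldvar-accessors
#' @export
setGeneric("factorLoadings", function(object) standardGeneric("factorLoadings"))

#' @rdname boldvar-accessors
#' @export
setMethod("factorLoadings", "FittedFactorModel", function(object) object@lambda)

#' @rdname boldvar-accessors
#' @export
setGeneric("factorCor", function(object) standardGeneric("factorCor"))

#' @rdname boldvar-accessors
#' @export
setMethod("factorCor", "FittedFactorModel", function(object) object@phi)

#' Fit indices of a fitted factor model
#'
#' @param object a [FittedFactorModel-class].
#' @return named numeric vector with `fml`, `chisq`, `df`, `pvalue`, `cfi`,
#'   `rmsea`, `srmr`.
#' @export
setGeneric("fitIndices", function(object) standardGeneric("fitIndices"))

#' @rdname fitIndices
#' @export
setMethod("fitIndices", "FittedFactorModel", function(object) {
  c(fml = object@fml, chisq = object@chisq, df = object@df,
    pvalue = stats::pchisq(object@chisq, object@df, lower.tail = FALSE),
    cfi = object@cfi, rmsea = object@rmsea, srmr = object@srmr)
})
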