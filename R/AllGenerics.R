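#' Accessors for crmEvol S4 classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an S4 object from this package.
#' @return The corresponding component: see individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("regimes", function(object) standardGeneric("regimes"))
#' @rdname accessors
#' @export
setGeneric("shiftTips", function(object) standardGeneric("shiftTips"))
#' @rdname accessors
#' @export
setGeneric("rootRegime", function(object) standardGeneric("rootRegime"))
#' @rdname accessors
#' @export
setGeneric("motifProfile", function(object) standardGeneric("motifProfile"))
#' @rdname accessors
#' @export
setGeneric("informationContent",
           function(object) standardGeneric("informationContent"))
#' @rdname accessors
#' @export
setGeneric("scoreValues", function(object) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setGeneric("clusterScore", function(object) standardGeneric("clusterScore"))
#' @rdname accessors
#' @export
setGeneric("clusterInterval",
           function(object) standardGeneric("clusterInterval"))
#' @rdname accessors
#' @export
setGeneric("motifHits", function(object) standardGeneric("motifHits"))
#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setGeneric("isUntestable", function(object) standardGeneric("isUntestable"))
#' @rdname accessors
#' @export
setGeneric("deltaDistributions",
           function(object) standardGeneric("deltaDistributions"))
#' @rdname accessors
#' @export
setGeneric("overlapFraction",
           function(object) standardGeneric("overlapFraction"))
#' @rdname accessors
#' @export
setGeneric("observedDelta", function(object) standardGeneric("observedDelta"))
#' @rdname accessors
#' @export
setGeneric("panelSequences", function(object) standardGeneric("panelSequences"))
#' @rdname accessors
#' @export
setGeneric("panelTruth", function(object) standardGeneric("panelTruth"))

#' @rdname accessors
#' @export
setMethod("modelId", "RegimePainting", function(object) object@model)
#' @rdname accessors
#' @export
setMethod("modelId", "ModelFit", function(object) object@model)
#' @rdname accessors
#' @export
setMethod("regimes", "RegimePainting", function(object) {
  stats::setNames(object@regimes, paintingBranchIds(object))
})
#' @rdname accessors
#' @export
setMethod("shiftTips", "RegimePainting", function(object) object@shiftTips)
#' @rdname accessors
#' @export
setMethod("rootRegime", "RegimePainting", function(object) object@rootRegime)
#' @rdname accessors
#' @export
setMethod("motifProfile", "PWMatrix", function(object) object@profile)
#' @rdname accessors
#' @export
setMethod("informationContent", "PWMatrix", function(object) object@ic)
#' @rdname accessors
#' @export
setMethod("scoreValues", "ScoreMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("clusterScore", "ClusterScore", function(object) object@score)
#' @rdname accessors
#' @export
setMethod("clusterInterval", "ClusterScore", function(object) object@interval)
#' @rdname accessors
#' @export
setMethod("motifHits", "ClusterScore", function(object) object@hits)
#' @rdname accessors
#' @export
setMethod("fitParams", "ModelFit", function(object) object@params)
#' @rdname accessors
#' @export
setMethod("isUntestable", "ModelFit", function(object) object@untestable)
#' @rdname accessors
#' @export
setMethod("deltaDistributions", "BootstrapResult", function(object) {
  list(null = object@deltaNull, alt = object@deltaAlt)
})
#' @rdname accessors
#' @export
setMethod("overlapFraction", "BootstrapResult",
          function(object) object@overlap)
#' @rdname accessors
#' @export
setMethod("observedDelta", "BootstrapResult",
          function(object) object@observedDelta)
#' @rdname accessors
#' @export
setMethod("panelSequences", "SyntheticPanel",
          function(object) object@sequences)
#' @rdname accessors
#' @export
setMethod("panelTruth", "SyntheticPanel", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("logLik", "ModelFit", function(object, ...) object@logLik)

#' @rdname accessors
#' @param ... ignored.
#' @param k unused (signature compatibility with \code{stats::AIC}).
#' @export
setMethod("AIC", "ModelFit", function(object, ..., k = 2) object@AIC)
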