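#' @import methods
NULL

#' @export
setGeneric("rateMatrix", function(object, ...) standardGeneric("rateMatrix"))

#' @export
setGeneric("transitionMatrix", function(object, t, ...)
    standardGeneric("transitionMatrix"))

#' @export
setGeneric("stationaryDistribution", function(object, ...)
    standardGeneric("stationaryDistribution"))

#' @export
setGeneric("nParams", function(object) standardGeneric("nParams"))

#' @export
setGeneric("stateSpace", function(object) standardGeneric("stateSpace"))

#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))

#' @export
setGeneric("rates", function(object) standardGeneric("rates"))

#' @export
setGeneric("speciesTree", function(object) standardGeneric("speciesTree"))

#' @export
setGeneric("geneCounts", function(object) standardGeneric("geneCounts"))

#' @export
setGeneric("phyleticStates", function(object, ...)
    standardGeneric("phyleticStates"))

#' @export
setGeneric("domainLabels", function(object) standardGeneric("domainLabels"))

#' @export
setGeneric("priorProbs", function(object) standardGeneric("priorProbs"))

#' @export
setGeneric("aicScore", function(object, ...) standardGeneric("aicScore"))

#' @export
setGeneric("rootPosterior", function(object, ...)
    standardGeneric("rootPosterior"))

#' @export
setGeneric("presenceProbability", function(object)
    standardGeneric("presenceProbability"))

#' @export
setGeneric("lossGainRatio", function(object) standardGeneric("lossGainRatio"))
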