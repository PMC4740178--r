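#' @rdname BetaSet-accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname BetaSet-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname BetaSet-accessors
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname BetaSet-accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname BetaSet-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname DvmcResults-accessors
#' @export
setGeneric("dvmcTable", function(x) standardGeneric("dvmcTable"))

#' @rdname DvmcResults-accessors
#' @export
setGeneric("excludedProbes", function(x) standardGeneric("excludedProbes"))

#' @rdname DeviationSet-accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname DeviationSet-accessors
#' @export
setGeneric("pMatrix", function(x) standardGeneric("pMatrix"))

#' @rdname DeviationSet-accessors
#' @export
setGeneric("hitMatrix", function(x) standardGeneric("hitMatrix"))

#' @rdname DeviationSet-accessors
#' @export
setGeneric("pThreshold", function(x) standardGeneric("pThreshold"))

#' @rdname DeviationSet-accessors
#' @export
setGeneric("refStats", function(x) standardGeneric("refStats"))

#' @rdname ReferenceProfiles-accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname ReferenceProfiles-accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname CellFractions-accessors
#' @export
setGeneric("fractionWeights", function(x) standardGeneric("fractionWeights"))

#' @rdname CellFractions-accessors
#' @export
setGeneric("fitResiduals", function(x) standardGeneric("fitResiduals"))
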