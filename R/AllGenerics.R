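#' @rdname GridStack-accessors
#' @param x a [GridStack-class] or map object
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname GridStack-accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname GridStack-accessors
#' @param name layer name
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

#' @rdname GridStack-accessors
#' @export
setGeneric("layerKind", function(x) standardGeneric("layerKind"))

#' @rdname GridStack-accessors
#' @export
setGeneric("layerPriority", function(x) standardGeneric("layerPriority"))

#' @rdname GridStack-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname GridStack-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname GridStack-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname SpeciesMap-accessors
#' @param x a [SpeciesMap-class]
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname PresenceAbsence-accessors
#' @param x a [PresenceAbsence-class]
#' @export
setGeneric("paMatrix", function(x) standardGeneric("paMatrix"))

#' @rdname PresenceAbsence-accessors
#' @export
setGeneric("siteCoords", function(x) standardGeneric("siteCoords"))

#' @rdname PresenceAbsence-accessors
#' @export
setGeneric("tetradIds", function(x) standardGeneric("tetradIds"))

#' @rdname PresenceAbsence-accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname PresenceAbsence-accessors
#' @param species species name
#' @export
setGeneric("speciesData", function(x, species) standardGeneric("speciesData"))

#' @rdname SyntheticTruth-accessors
#' @param x a [SyntheticTruth-class]
#' @export
setGeneric("occupancyTruth", function(x) standardGeneric("occupancyTruth"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("abundanceTruth", function(x) standardGeneric("abundanceTruth"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("presenceTruth", function(x) standardGeneric("presenceTruth"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("coverLayers", function(x) standardGeneric("coverLayers"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("woodlandFraction", function(x) standardGeneric("woodlandFraction"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("linearFraction", function(x) standardGeneric("linearFraction"))

#' Predict occupancy scores from a fitted SDM or ensemble
#'
#' @param object a [FittedSDM-class] or [EnsembleSDM-class]
#' @param newdata data.frame of covariates
#' @return numeric scores in `[0, 1]`
#' @export
setGeneric("predictSDM", function(object, newdata) standardGeneric("predictSDM"))
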