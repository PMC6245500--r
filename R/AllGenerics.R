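#' @rdname MetabolicModel-class
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("lowerBounds", function(x) standardGeneric("lowerBounds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("upperBounds", function(x) standardGeneric("upperBounds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("gprRules", function(x) standardGeneric("gprRules"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("subsystems", function(x) standardGeneric("subsystems"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("biomassReaction", function(x) standardGeneric("biomassReaction"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("maintenanceReaction", function(x) standardGeneric("maintenanceReaction"))

#' @rdname CohortExpression-class
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname CohortExpression-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname CohortExpression-class
#' @export
setGeneric("probeGenes", function(x) standardGeneric("probeGenes"))

#' @rdname CohortExpression-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname CohortExpression-class
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @rdname CohortExpression-class
#' @export
setGeneric("sexes", function(x) standardGeneric("sexes"))

#' @rdname FluxProfileMatrix-class
#' @export
setGeneric("fluxMatrix", function(x) standardGeneric("fluxMatrix"))

#' @rdname FluxProfileMatrix-class
#' @export
setGeneric("pathwayFluxMatrix", function(x) standardGeneric("pathwayFluxMatrix"))

#' @rdname AgePrediction-class
#' @export
setGeneric("predictorValues", function(x) standardGeneric("predictorValues"))

#' @rdname AgePrediction-class
#' @export
setGeneric("scaledAges", function(x) standardGeneric("scaledAges"))

#' @rdname ElasticNetFit-class
#' @export
setGeneric("selectedPredictors", function(x) standardGeneric("selectedPredictors"))

#' @rdname ElasticNetFit-class
#' @export
setGeneric("effectSizes", function(x) standardGeneric("effectSizes"))
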