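#' @rdname MetabolicModel-class
#' @param x,object a \code{MetabolicModel}.
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("biomassReaction", function(x) standardGeneric("biomassReaction"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("objectiveCoefficients",
           function(x) standardGeneric("objectiveCoefficients"))

#' Flux balance analysis
#'
#' Solve the FBA linear program max/min c'v subject to S v = 0 and
#' lb <= v <= ub.
#'
#' @param model a \code{\link{MetabolicModel}}.
#' @param ... passed to methods.
#' @return A \code{\link{FluxDistribution}}.
#' @export
setGeneric("fba", function(model, ...) standardGeneric("fba"))

#' Flux variability analysis
#'
#' @param model a \code{\link{MetabolicModel}}.
#' @param ... passed to methods.
#' @return A \code{\link{FluxRange}}.
#' @export
setGeneric("fluxVariability",
           function(model, ...) standardGeneric("fluxVariability"))

#' Random-objective vertex sampling of the flux solution space
#'
#' @param model a \code{\link{MetabolicModel}}.
#' @param ... passed to methods.
#' @return A \code{\link{FluxSample}}.
#' @export
setGeneric("sampleFluxes", function(model, ...) standardGeneric("sampleFluxes"))

#' @rdname FluxSample-class
#' @param x a \code{FluxSample}.
#' @export
setGeneric("fluxMatrix", function(x) standardGeneric("fluxMatrix"))

#' @rdname FluxDistribution-class
#' @param x a \code{FluxDistribution}.
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))
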