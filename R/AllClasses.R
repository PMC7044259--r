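#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t colSums rowSums
NULL

#' MetabolicModel: a stoichiometric metabolic model
#'
#' Container for a constraint-based (genome-scale or toy) metabolic model:
#' metabolites with elemental formulas, reactions with flux bounds, the
#' stoichiometric matrix, the biomass reaction and the optimization objective.
#' Fluxes are in mmol/gDW/h throughout (biomass flux in 1/h); mass fractions
#' are g/gDW.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{formula} (Hill notation, \code{NA} when
#'   unknown) and \code{charge}.
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lowerBound}, \code{upperBound} and \code{subsystem}.
#' @slot S sparse stoichiometric matrix (rows = metabolites, columns =
#'   reactions; negative coefficients are consumed).
#' @slot biomassId id of the biomass (growth) reaction.
#' @slot objective named numeric vector of objective weights per reaction id.
#'
#' @examples
#' m <- buildToyGEM()
#' m
#' head(metabolites(m))
#' @export
setClass("MetabolicModel",
  representation(
    metabolites = "data.frame",
    reactions = "data.frame",
    S = "Matrix",
    biomassId = "character",
    objective = "numeric"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  need <- c("id", "name", "compartment", "formula", "charge")
  if (!all(need %in% names(met)))
    msg <- c(msg, "metabolites must have columns id, name, compartment, formula, charge")
  needr <- c("id", "name", "lowerBound", "upperBound", "subsystem")
  if (!all(needr %in% names(rxn)))
    msg <- c(msg, "reactions must have columns id, name, lowerBound, upperBound, subsystem")
  if (length(msg)) return(msg)
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
  if (nrow(object@S) != nrow(met) || ncol(object@S) != nrow(rxn))
    msg <- c(msg, "S dimensions do not match metabolite/reaction tables")
  if (!identical(rownames(object@S), met$id))
    msg <- c(msg, "rownames(S) must equal metabolite ids")
  if (!identical(colnames(object@S), rxn$id))
    msg <- c(msg, "colnames(S) must equal reaction ids")
  if (any(rxn$lowerBound > rxn$upperBound + 1e-12))
    msg <- c(msg, "lowerBound > upperBound for some reaction")
  if (length(object@biomassId) != 1L || !(object@biomassId %in% rxn$id))
    msg <- c(msg, "biomassId must name one existing reaction")
  if (length(object@objective) &&
      !all(names(object@objective) %in% rxn$id))
    msg <- c(msg, "objective names must be reaction ids")
  if (length(msg)) msg else TRUE
})

#' BiomassComposition: macromolecular biomass composition
#'
#' Mass fractions (g/gDW) of the biomass macromolecular pools. Fractions must
#' each lie in [0, 1] and sum to 1 (within 1e-9), i.e. the biomass equation
#' produces exactly 1 g of dry weight.
#'
#' @slot protein,lipid,carbohydrate,nucleotide,other numeric mass fractions.
#' @examples
#' BiomassComposition(protein = .45, lipid = .15, carbohydrate = .30,
#'                    nucleotide = .06, other = .04)
#' @export
setClass("BiomassComposition",
  representation(protein = "numeric", lipid = "numeric",
                 carbohydrate = "numeric", nucleotide = "numeric",
                 other = "numeric"))

setValidity("BiomassComposition", function(object) {
  f <- c(object@protein, object@lipid, object@carbohydrate,
         object@nucleotide, object@other)
  if (length(f) != 5L || anyNA(f)) return("all five fractions required")
  if (any(f < 0 | f > 1)) return("fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9) return("fractions must sum to 1 (within 1e-9)")
  TRUE
})

#' @rdname BiomassComposition-class
#' @param protein,lipid,carbohydrate,nucleotide,other mass fractions in g/gDW.
#' @return A \code{BiomassComposition} object.
#' @export
BiomassComposition <- function(protein, lipid, carbohydrate, nucleotide, other) {
  new("BiomassComposition", protein = protein, lipid = lipid,
      carbohydrate = carbohydrate, nucleotide = nucleotide, other = other)
}

#' FluxDistribution: a single flux balance solution
#'
#' @slot fluxes named numeric vector of fluxes (mmol/gDW/h; biomass in 1/h);
#'   empty when the problem was not solved to optimality.
#' @slot objectiveValue achieved objective value (NA unless optimal).
#' @slot status one of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}.
#' @export
setClass("FluxDistribution",
  representation(fluxes = "numeric", objectiveValue = "numeric",
                 status = "character"))

setValidity("FluxDistribution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal, infeasible or unbounded")
  TRUE
})

#' FluxRange: per-reaction feasible flux ranges (FVA result)
#'
#' @slot ranges data.frame with columns \code{id}, \code{min}, \code{max}.
#' @export
setClass("FluxRange", representation(ranges = "data.frame"))

setValidity("FluxRange", function(object) {
  r <- object@ranges
  if (!all(c("id", "min", "max") %in% names(r)))
    return("ranges needs columns id, min, max")
  if (any(r$min > r$max + 1e-6)) return("min > max in some range")
  TRUE
})

#' FluxSample: random sample of the flux solution space
#'
#' Rows are vertex solutions obtained by optimizing random-signed,
#' random-weighted objectives; columns are reactions.
#'
#' @slot matrix numeric matrix, n samples x n reactions (column names are
#'   reaction ids).
#' @slot seed integer seed the sample was drawn with.
#' @slot n number of samples.
#' @export
setClass("FluxSample",
  representation(matrix = "matrix", seed = "integer", n = "integer"))

setValidity("FluxSample", function(object) {
  if (nrow(object@matrix) != object@n) return("nrow(matrix) must equal n")
  if (is.null(colnames(object@matrix))) return("matrix needs reaction-id colnames")
  TRUE
})

#' ConditionData: measurements from one steady-state cultivation
#'
#' One turbidostat steady state: measured specific rates and biomass
#' composition used to build a condition-specific model. Uptake and transfer
#' rates are stored positive (consumption/production magnitude); the mapping
#' to signed exchange fluxes happens inside the pipeline.
#'
#' @slot carbonSource metabolite id of the carbon source (e.g. \code{"glyc"}).
#' @slot cnRatio molar carbon-to-nitrogen ratio of the medium.
#' @slot mu specific growth rate, 1/h.
#' @slot substrateUptake specific substrate uptake, mmol/gDW/h (positive).
#' @slot byproductRates named numeric, measured excretion rates in mmol/gDW/h
#'   (positive), named by metabolite id.
#' @slot otr,ctr specific oxygen / carbon dioxide transfer rates, mmol/gDW/h
#'   (positive; OTR is consumption, CTR is production).
#' @slot proteinContent,lipidContent cellular mass fractions, g/gDW.
#' @slot groundTruth list; for synthetic datasets, the generating flux
#'   distribution and noiseless values (empty for real data).
#' @export
setClass("ConditionData",
  representation(carbonSource = "character", cnRatio = "numeric",
                 mu = "numeric", substrateUptake = "numeric",
                 byproductRates = "numeric", otr = "numeric", ctr = "numeric",
                 proteinContent = "numeric", lipidContent = "numeric",
                 groundTruth = "list"))

setValidity("ConditionData", function(object) {
  msg <- character()
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (object@substrateUptake < 0) msg <- c(msg, "substrateUptake must be >= 0")
  ct <- c(object@proteinContent, object@lipidContent)
  if (any(ct < 0 | ct > 1)) msg <- c(msg, "contents must lie in [0, 1]")
  if (length(object@byproductRates) && is.null(names(object@byproductRates)))
    msg <- c(msg, "byproductRates must be named by metabolite id")
  if (length(msg)) msg else TRUE
})

#' ConditionModel: a measured-rate-constrained model
#'
#' Result of \code{\link{constrainCondition}}: the rescaled model with
#' exchange fluxes fixed (then relaxed) to measured values, the achieved
#' constraint values, and the estimated non-growth-associated maintenance.
#'
#' @slot model the constrained \code{MetabolicModel} (exchange bounds already
#'   widened by the relaxation for sampling).
#' @slot ngam maximized ATP-hydrolysis flux (mmol ATP/gDW/h); NA until
#'   \code{\link{estimateNGAM}} has run.
#' @slot fitReport data.frame with one row per constrained quantity:
#'   \code{quantity}, \code{requested}, \code{achieved}.
#' @slot relaxation fractional relaxation applied to constrained exchanges.
#' @slot atpmId id of the ATP-hydrolysis (maintenance) reaction.
#' @slot substrateExchange id of the substrate exchange reaction.
#' @export
setClass("ConditionModel",
  representation(model = "MetabolicModel", ngam = "numeric",
                 fitReport = "data.frame", relaxation = "numeric",
                 atpmId = "character", substrateExchange = "character"))

#' FluxAttribution: pathway-level summary of a flux sample
#'
#' @slot nadphSources named numeric, mean fraction of total NADPH production
#'   per producing reaction (sums to 1).
#' @slot pathwayCarbonFractions named numeric, fraction of consumed substrate
#'   carbon entering each signature pathway (phosphoketolase, ACL, malic
#'   enzyme).
#' @slot predictedRQ mean predicted respiratory quotient (CO2 out / O2 in).
#' @slot predictedByproducts named numeric, mean positive excretion of
#'   non-gas exchanges as carbon-mol fraction of substrate carbon uptake.
#' @export
setClass("FluxAttribution",
  representation(nadphSources = "numeric",
                 pathwayCarbonFractions = "numeric",
                 predictedRQ = "numeric",
                 predictedByproducts = "numeric"))

#' FedBatchPlan: parameters of an exponential feeding design
#'
#' The open-loop exponential feed profile holds the specific growth rate at
#' \code{mu0} provided the culture consumes substrate with yield \code{yxs}:
#' F(t) = yxs * mu0 * x0 * V0 * exp(mu0 t) / (cf - cs).
#'
#' @slot yxs substrate consumed per biomass formed, g substrate/gDW.
#' @slot mu0 design specific growth rate, 1/h.
#' @slot cf feed substrate concentration, g/L.
#' @slot cs0 vessel substrate concentration at feed start, g/L (also the
#'   design-time constant cs in the feed-rate formula).
#' @slot x0 biomass concentration at feed start, gDW/L.
#' @slot v0 volume at feed start, L.
#' @slot duration feeding duration, h.
#' @export
setClass("FedBatchPlan",
  representation(yxs = "numeric", mu0 = "numeric", cf = "numeric",
                 cs0 = "numeric", x0 = "numeric", v0 = "numeric",
                 duration = "numeric"))

setValidity("FedBatchPlan", function(object) {
  msg <- character()
  if (object@cf <= object@cs0) msg <- c(msg, "cf must exceed cs0")
  if (object@cs0 < 0) msg <- c(msg, "cs0 must be >= 0")
  if (object@mu0 < 0) msg <- c(msg, "mu0 must be >= 0")
  if (object@x0 <= 0 || object@v0 <= 0) msg <- c(msg, "x0 and v0 must be > 0")
  if (object@duration < 0) msg <- c(msg, "duration must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname FedBatchPlan-class
#' @param yxs,mu0,cf,cs0,x0,v0,duration see slot documentation.
#' @return A \code{FedBatchPlan}.
#' @examples
#' fedBatchPlan(yxs = 3, mu0 = 0.05, cf = 220, cs0 = 0, x0 = 10.9,
#'              v0 = 0.5, duration = 48)
#' @export
fedBatchPlan <- function(yxs, mu0, cf, cs0 = 0, x0, v0, duration = 48) {
  new("FedBatchPlan", yxs = yxs, mu0 = mu0, cf = cf, cs0 = cs0,
      x0 = x0, v0 = v0, duration = duration)
}

#' FedBatchTrajectory: simulated fed-batch state over time
#'
#' @slot trajectory data.frame with columns \code{t} (h), \code{V} (L),
#'   \code{x} (gDW/L), \code{cs} (g/L) and \code{F} (L/h).
#' @slot substrateLimited TRUE when substrate was driven to zero during the
#'   simulation (consumption clipped).
#' @export
setClass("FedBatchTrajectory",
  representation(trajectory = "data.frame", substrateLimited = "logical"))

setValidity("FedBatchTrajectory", function(object) {
  tr <- object@trajectory
  if (!all(c("t", "V", "x", "cs", "F") %in% names(tr)))
    return("trajectory needs columns t, V, x, cs, F")
  if (any(diff(tr$V) < -1e-9)) return("volume must be non-decreasing")
  if (any(tr$cs < -1e-9) || any(tr$x < -1e-9) || any(tr$F < -1e-12))
    return("negative state values")
  TRUE
})
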