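#' Built-in compound table
#'
#' Molecular properties of the compounds handled by the physiology
#' calculators.
#'
#' @return data.frame with \code{id}, \code{name}, \code{molarMass} (g/mol),
#'   \code{carbon} and \code{nitrogen} atoms per molecule.
#' @export
compoundTable <- function() {
  data.frame(
    id = c("glyc", "xyl", "ac", "xlt", "pyr", "glx", "nh4so4", "co2"),
    name = c("glycerol", "D-xylose", "acetic acid", "xylitol", "pyruvate",
             "glyoxylate", "ammonium sulfate", "carbon dioxide"),
    molarMass = c(92.094, 150.13, 60.052, 152.146, 88.06, 74.035,
                  132.14, 44.01),
    carbon = c(3, 5, 2, 5, 3, 2, 0, 1),
    nitrogen = c(0, 0, 0, 0, 0, 0, 2, 0))
}

.compound <- function(id) {
  tab <- compoundTable()
  i <- match(id, tab$id)
  if (is.na(i)) stop("unknown compound id '", id,
                     "'; see compoundTable() or pass properties explicitly")
  tab[i, ]
}

#' Derive steady-state physiology from a condition dataset
#'
#' Turbidostat identities: the specific lipid production rate is lipid
#' content times growth rate (the lipid pool turns over with the biomass);
#' biomass yield is growth rate over mass-specific substrate uptake; lipid
#' yield is the lipid production rate over the same uptake; volumetric
#' biomass productivity is growth rate times biomass concentration; RQ is
#' CTR over OTR.
#'
#' @param data a \code{\link{ConditionData}}.
#' @param biomassConc steady-state biomass concentration, gDW/L (used only
#'   for the volumetric rate; default 1).
#' @param substrateMolarMass g/mol of the substrate; default looked up from
#'   \code{\link{compoundTable}} by \code{data@carbonSource}.
#' @return One-row data.frame (a physiology summary) with columns \code{mu}
#'   (1/h), \code{y_sx} (gDW/g), \code{y_ls} (g lipid/g), \code{q_bm}
#'   (g/(L h)), \code{r_lip} (g lipid/(gDW h)), \code{rq}, \code{cn_ratio}.
#' @examples
#' d <- makeConditionDataset(buildToyGEM(), "glycerol", 100, 0.2, noiseCV = 0)
#' deriveRates(d, biomassConc = 5)
#' @export
deriveRates <- function(data, biomassConc = 1, substrateMolarMass = NULL) {
  stopifnot(is(data, "ConditionData"))
  if (is.null(substrateMolarMass))
    substrateMolarMass <- .compound(data@carbonSource)$molarMass
  if (data@otr <= 0 && data@ctr > 0)
    stop("RQ undefined: CO2 production measured with zero oxygen transfer")
  uptakeMass <- data@substrateUptake * substrateMolarMass / 1000  # g/gDW/h
  rLip <- data@lipidContent * data@mu
  data.frame(
    mu = data@mu,
    y_sx = if (uptakeMass > 0) data@mu / uptakeMass else 0,
    y_ls = if (uptakeMass > 0) rLip / uptakeMass else 0,
    q_bm = data@mu * biomassConc,
    r_lip = rLip,
    rq = if (data@otr > 0) data@ctr / data@otr else NA_real_,
    cn_ratio = data@cnRatio)
}

#' Carbon recovery of a measured condition
#'
#' Fraction of the consumed substrate carbon recovered in biomass, CO2 and
#' the measured byproducts. Values well below 1 indicate unmeasured excreted
#' products.
#'
#' @param data a \code{\link{ConditionData}}.
#' @param biomassCContent biomass carbon content, mmol C/gDW (default 40).
#' @param carbonNumbers named numeric, carbon atoms per molecule for the
#'   substrate and byproducts; defaults from \code{\link{compoundTable}}.
#' @return Carbon recovery as a fraction of substrate carbon uptake.
#' @export
carbonRecovery <- function(data, biomassCContent = 40, carbonNumbers = NULL) {
  stopifnot(is(data, "ConditionData"))
  if (data@substrateUptake <= 0) stop("substrate uptake must be positive")
  lookupC <- function(id) {
    if (!is.null(carbonNumbers) && id %in% names(carbonNumbers))
      return(carbonNumbers[[id]])
    tab <- compoundTable()
    i <- match(id, tab$id)
    if (is.na(i)) stop("no carbon number known for '", id,
                       "'; supply it via carbonNumbers")
    tab$carbon[i]
  }
  subC <- data@substrateUptake * lookupC(data@carbonSource)
  bioC <- data@mu * biomassCContent
  bypC <- 0
  for (mid in names(data@byproductRates))
    bypC <- bypC + data@byproductRates[[mid]] * lookupC(mid)
  (bioC + data@ctr + bypC) / subC
}

#' Build a medium recipe table
#'
#' @param components data.frame with columns \code{id}, \code{concentration}
#'   (g/L), and optionally \code{carbon}, \code{nitrogen}, \code{molarMass}
#'   (filled from \code{\link{compoundTable}} when missing).
#' @return The completed recipe data.frame.
#' @examples
#' mediumRecipe(data.frame(id = c("glyc", "nh4so4"),
#'                         concentration = c(10, 5)))
#' @export
mediumRecipe <- function(components) {
  components <- as.data.frame(components)
  stopifnot(all(c("id", "concentration") %in% names(components)))
  tab <- compoundTable()
  for (col in c("carbon", "nitrogen", "molarMass")) {
    if (is.null(components[[col]])) components[[col]] <- NA_real_
    miss <- is.na(components[[col]])
    i <- match(components$id[miss], tab$id)
    if (anyNA(i)) stop("unknown compound(s) and no explicit properties: ",
                       paste(components$id[miss][is.na(i)], collapse = ", "))
    components[[col]][miss] <- tab[[col]][i]
  }
  if (any(components$concentration < 0)) stop("negative concentration")
  if (any(components$molarMass <= 0)) stop("molar mass must be positive")
  components
}

#' Molar carbon-to-nitrogen ratio of a medium
#'
#' @param recipe a recipe from \code{\link{mediumRecipe}}.
#' @return mol C / mol N of the medium.
#' @examples
#' cnRatio(mediumRecipe(data.frame(id = c("glyc", "nh4so4"),
#'                                 concentration = c(10, 5))))  # ~4.31
#' @export
cnRatio <- function(recipe) {
  molC <- sum(recipe$concentration / recipe$molarMass * recipe$carbon)
  molN <- sum(recipe$concentration / recipe$molarMass * recipe$nitrogen)
  if (molN <= 0) stop("medium contains no nitrogen source")
  molC / molN
}

#' Fed-batch lipid yield arithmetic
#'
#' End-point yields of a fed-batch run from the lipid titer, final biomass
#' and the substrate consumed per biomass formed.
#'
#' @param lipidTiter g lipid/L at harvest.
#' @param biomass final biomass concentration, gDW/L.
#' @param glycerolPerBiomass substrate consumed per biomass formed, g/gDW
#'   (omit to get only the lipid content).
#' @return List with \code{y_ls} (g lipid/g substrate; NA when
#'   \code{glycerolPerBiomass} is missing) and \code{lipid_content} (g/gDW).
#' @examples
#' fedbatchYieldSummary(6.0, 14.6, 2.3)
#' @export
fedbatchYieldSummary <- function(lipidTiter, biomass,
                                 glycerolPerBiomass = NULL) {
  stopifnot(lipidTiter > 0, biomass > 0)
  yls <- NA_real_
  if (!is.null(glycerolPerBiomass)) {
    stopifnot(glycerolPerBiomass > 0)
    yls <- lipidTiter / (biomass * glycerolPerBiomass)
  }
  list(y_ls = yls, lipid_content = lipidTiter / biomass)
}
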