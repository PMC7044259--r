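#' Rescale the biomass equation to measured protein and lipid content
#'
#' Sets the biomass-equation coefficients of the protein and lipid
#' pseudo-metabolites to the measured mass fractions, keeps nucleotide and
#' "other" pools at their baseline fractions, and scales the storage
#' carbohydrate so the composition sums to 1 g/gDW.
#'
#' @param model a \code{\link{MetabolicModel}} whose biomass reaction
#'   consumes the pseudo-metabolites named in \code{pseudoMets}.
#' @param protein,lipid measured mass fractions, g/gDW.
#' @param baseline a \code{\link{BiomassComposition}} supplying the
#'   nucleotide and other fractions.
#' @param pseudoMets named character vector mapping the pool names
#'   (\code{protein}, \code{lipid}, \code{carbohydrate}, \code{nucleotide},
#'   \code{other}) to metabolite ids; default matches the toy model.
#' @param monomerMass named numeric (g/mol) for the pseudo-metabolite
#'   monomers, in the same pool order.
#' @return The model with an updated biomass equation.
#' @export
rescaleBiomass <- function(model, protein, lipid,
                           baseline = toyBiomassBaseline(),
                           pseudoMets = c(protein = "prot", lipid = "lip",
                                          carbohydrate = "carb",
                                          nucleotide = "nuc", other = "oth"),
                           monomerMass = .monomerMass[c("prot", "lip", "carb",
                                                        "nuc", "oth")]) {
  protein <- unname(protein); lipid <- unname(lipid)
  stopifnot(protein >= 0, lipid >= 0)
  carb <- 1 - protein - lipid - baseline@nucleotide - baseline@other
  if (carb < -1e-12)
    stop("measured protein (", protein, ") + lipid (", lipid,
         ") plus baseline nucleotide/other exceed 1 g/gDW; ",
         "measurements inconsistent with a closed biomass composition")
  carb <- max(carb, 0)
  f <- c(protein = protein, lipid = lipid, carbohydrate = carb,
         nucleotide = baseline@nucleotide, other = baseline@other)
  names(monomerMass) <- names(pseudoMets)
  j <- match(model@biomassId, model@reactions$id)
  for (pool in names(pseudoMets)) {
    mid <- pseudoMets[[pool]]
    if (!mid %in% model@metabolites$id)
      stop("biomass pseudo-metabolite '", mid, "' not in model")
    model@S[mid, j] <- -1000 * f[[pool]] / monomerMass[[pool]]
  }
  model
}

# set up the condition medium: substrate uptake open, other carbon sources
# closed, byproduct secretion open
applyMedium <- function(model, exchangeId, maxUptake = 1000) {
  ex <- exchangeReactions(model)
  cc <- carbonCount(model)
  for (e in ex) {
    metId <- names(which(model@S[, e] != 0))
    hasC <- !is.na(cc[metId]) && cc[metId] > 0 && metId != "co2"
    if (hasC && e != exchangeId)
      model <- setBounds(model, e, lower = 0)
  }
  setBounds(model, exchangeId, lower = -maxUptake, upper = 1000)
}

#' Build a condition-specific model from measured rates
#'
#' Implements the measured-rate constraining procedure: substrate uptake and
#' measured byproduct excretions are fixed to their measured values; growth
#' is fixed to the measured rate or, when that is infeasible, to the highest
#' achievable rate; the O2 and CO2 exchange fluxes are set as close to the
#' measured transfer rates as possible (two-stage: minimize the L1 deviation
#' from OTR/CTR, then fix at the achieved values); finally each constrained
#' exchange is relaxed to +/- \code{relaxation} of its value so the solution
#' space retains an interior for sampling.
#'
#' @param model a \code{\link{MetabolicModel}} (already biomass-rescaled, see
#'   \code{\link{rescaleBiomass}}).
#' @param data a \code{\link{ConditionData}}.
#' @param relaxation fractional half-width of the relaxed exchange window,
#'   default 0.025 (i.e. 97.5--102.5\% of the constrained value).
#' @return A \code{\link{ConditionModel}} (NGAM not yet estimated).
#' @export
constrainCondition <- function(model, data, relaxation = 0.025) {
  stopifnot(is(data, "ConditionData"))
  if (relaxation < 0 || relaxation >= 1)
    stop("relaxation must lie in [0, 1)")
  src <- toyCarbonSource(data@carbonSource)
  exS <- src$exchange
  if (!exS %in% model@reactions$id)
    stop("substrate exchange ", exS, " not in model")
  model <- applyMedium(model, exS)

  fit <- data.frame(quantity = character(), requested = numeric(),
                    achieved = numeric())
  note <- function(q, req, ach) rbind(fit, data.frame(
    quantity = q, requested = req, achieved = ach))

  # substrate uptake (stored positive, exchange flux negative)
  model <- setBounds(model, exS, lower = -data@substrateUptake,
                     upper = -data@substrateUptake)
  fit <- note("substrate_uptake", data@substrateUptake, data@substrateUptake)

  # measured byproducts fixed to measured values; unmeasured ones stay open
  for (mid in names(data@byproductRates)) {
    e <- paste0("EX_", mid)
    if (!e %in% model@reactions$id)
      stop("no exchange reaction for measured byproduct '", mid, "'")
    v <- data@byproductRates[[mid]]
    model <- setBounds(model, e, lower = v, upper = v)
    fit <- note(paste0("byproduct_", mid), v, v)
  }

  # growth: measured mu, or the highest achievable when mu is out of reach
  maxMu <- fba(model, objective = stats::setNames(1, model@biomassId))
  if (maxMu@status != "optimal")
    stop("condition infeasible before fixing growth: substrate uptake ",
         data@substrateUptake, " with fixed byproducts admits no solution (",
         maxMu@status, ")")
  muUse <- min(data@mu, maxMu@objectiveValue)
  j <- match(model@biomassId, model@reactions$id)
  model@reactions$lowerBound[j] <- muUse
  model@reactions$upperBound[j] <- muUse
  fit <- note("growth_rate", data@mu, muUse)

  # two-stage O2/CO2 fit: minimize L1 deviation from (-OTR, CTR), then fix
  exO2 <- "EX_o2"; exCO2 <- "EX_co2"
  d <- lpData(model)
  nr <- length(d$ids)
  targets <- c(-data@otr, data@ctr)
  cols <- match(c(exO2, exCO2), d$ids)
  if (anyNA(cols)) stop("model lacks O2/CO2 exchange reactions")
  # deviation variables: v_gas + dPlus - dMinus = target
  A <- cbind(d$A, matrix(0, nrow(d$A), 4))
  ex1 <- numeric(nr + 4); ex1[cols[1]] <- 1; ex1[nr + 1] <- 1; ex1[nr + 2] <- -1
  ex2 <- numeric(nr + 4); ex2[cols[2]] <- 1; ex2[nr + 3] <- 1; ex2[nr + 4] <- -1
  A <- rbind(A, ex1, ex2)
  b <- c(d$b, targets)
  lb <- c(d$lb, rep(0, 4))
  ub <- c(d$ub, rep(Inf, 4))
  cv <- c(numeric(nr), rep(1, 4))
  r <- solveLP(A, b, cv, lb, ub, maximize = FALSE)
  if (r$status != "optimal")
    stop("condition infeasible while fitting gas exchange rates (status ",
         r$status, "); binding constraints: growth=", muUse,
         ", uptake=", data@substrateUptake)
  vO2 <- r$x[cols[1]]; vCO2 <- r$x[cols[2]]
  model <- setBounds(model, exO2, lower = vO2, upper = vO2)
  model <- setBounds(model, exCO2, lower = vCO2, upper = vCO2)
  fit <- note("o2_exchange", -data@otr, vO2)
  fit <- note("co2_exchange", data@ctr, vCO2)

  # relax every constrained exchange to [ (1-r) v, (1+r) v ] for sampling
  constrained <- c(exS, exO2, exCO2,
                   if (length(data@byproductRates))
                     paste0("EX_", names(data@byproductRates)))
  for (e in unique(constrained)) {
    i <- match(e, model@reactions$id)
    v <- model@reactions$lowerBound[i]   # fixed, lb == ub
    w <- sort(c((1 - relaxation) * v, (1 + relaxation) * v))
    model <- setBounds(model, e, lower = w[1], upper = w[2])
  }
  new("ConditionModel", model = model, ngam = NA_real_, fitReport = fit,
      relaxation = relaxation, atpmId = "ATPM", substrateExchange = exS)
}

#' Estimate non-growth-associated maintenance (NGAM)
#'
#' Maximizes the ATP-hydrolysis flux under all condition constraints; the
#' maximum is the ATP the cell can spend on non-growth processes and is used
#' as the NGAM estimate for the condition.
#'
#' @param cm a \code{\link{ConditionModel}}.
#' @return The \code{ConditionModel} with \code{ngam} filled in.
#' @export
estimateNGAM <- function(cm) {
  stopifnot(is(cm, "ConditionModel"))
  sol <- fba(cm@model, objective = stats::setNames(1, cm@atpmId))
  if (sol@status != "optimal")
    stop("constrained model is ", sol@status, "; cannot estimate NGAM")
  cm@ngam <- sol@objectiveValue
  cm
}

#' Sample the solution space of a constrained condition model
#'
#' Fixes the ATP-hydrolysis flux at no less than (1 - relaxation) times its
#' maximized value, then draws random-objective vertex samples.
#'
#' @param cm a \code{\link{ConditionModel}} (NGAM estimated automatically
#'   when missing).
#' @param n number of samples, default 5000.
#' @param seed integer seed.
#' @return A \code{\link{FluxSample}}.
#' @export
sampleCondition <- function(cm, n = 5000, seed = 1L) {
  if (is.na(cm@ngam)) cm <- estimateNGAM(cm)
  m <- setBounds(cm@model, cm@atpmId,
                 lower = (1 - cm@relaxation) * cm@ngam)
  sampleFluxes(m, n = n, seed = seed)
}

#' Attribute sampled fluxes to NADPH sources and acetyl-CoA pathways
#'
#' For every sample: NADPH source shares are each producing reaction's NADPH
#' production divided by total production; a pathway's carbon fraction is the
#' carbon entering its signature reaction (carbon atoms of consumed
#' non-currency metabolites times flux) divided by the substrate carbon
#' uptake; the respiratory quotient is CO2 efflux over O2 influx; predicted
#' byproducts are positive non-gas exchange fluxes as carbon-mol fractions of
#' uptake. Shares and fractions are averaged over samples.
#'
#' @param cm a \code{\link{ConditionModel}}.
#' @param sample a \code{\link{FluxSample}} from \code{\link{sampleCondition}}.
#' @param registry reaction-id sets, see \code{\link{toyPathwayRegistry}}.
#' @param substrateExchange id of the substrate exchange reaction.
#' @return A \code{\link{FluxAttribution}}.
#' @export
attributeFluxes <- function(cm, sample, registry = toyPathwayRegistry(),
                            substrateExchange = NULL) {
  model <- cm@model
  ids <- model@reactions$id
  regIds <- unique(c(registry$nadph, registry$phosphoketolase,
                     registry$acl, registry$malicEnzyme))
  if (!all(regIds %in% ids))
    stop("registry reaction id(s) not in model: ",
         paste(setdiff(regIds, ids), collapse = ", "))
  M <- sample@matrix
  cc <- carbonCount(model)
  if (is.null(substrateExchange)) substrateExchange <- cm@substrateExchange
  subMet <- names(which(model@S[, substrateExchange] != 0))
  subC <- cc[subMet]

  # NADPH production per producing reaction and sample
  nadphRow <- model@S[registry$nadphMet, ]
  prodMat <- vapply(registry$nadph, function(r) {
    pmax(0, as.numeric(nadphRow[r]) * M[, r])
  }, numeric(nrow(M)))
  prodMat <- matrix(prodMat, nrow = nrow(M),
                    dimnames = list(NULL, registry$nadph))
  tot <- rowSums(prodMat)
  if (any(tot <= 1e-9))
    stop("total NADPH production is zero in ", sum(tot <= 1e-9),
         " sample(s); NADPH source shares undefined")
  shares <- colMeans(prodMat / tot)

  # carbon entering a signature reaction (consumed non-currency carbon)
  carbonIn <- function(rid) {
    coef <- model@S[, rid]
    consumed <- names(coef)[coef < 0]
    consumed <- setdiff(consumed, registry$currencyMets)
    if (!length(consumed)) return(numeric(nrow(M)))
    atoms <- sum(abs(coef[consumed]) * cc[consumed])
    pmax(0, M[, rid]) * atoms
  }
  uptakeC <- pmax(1e-12, -M[, substrateExchange]) * subC
  pathIds <- c(phosphoketolase = registry$phosphoketolase,
               acl = registry$acl, malicEnzyme = registry$malicEnzyme)
  fractions <- vapply(pathIds, function(r) mean(carbonIn(r) / uptakeC),
                      numeric(1))
  names(fractions) <- names(pathIds)

  rq <- mean(M[, registry$co2Exchange] / pmax(1e-12, -M[, registry$o2Exchange]))

  exAll <- exchangeReactions(model)
  gasEx <- c(registry$o2Exchange, registry$co2Exchange)
  bypEx <- setdiff(exAll, c(gasEx, substrateExchange, "EX_nh4"))
  byp <- vapply(bypEx, function(e) {
    metId <- names(which(model@S[, e] != 0))
    if (is.na(cc[metId]) || cc[metId] == 0) return(NA_real_)
    mean(pmax(0, M[, e]) * cc[metId] / uptakeC)
  }, numeric(1))
  names(byp) <- vapply(bypEx, function(e)
    names(which(model@S[, e] != 0)), character(1))
  byp <- byp[!is.na(byp)]

  new("FluxAttribution", nadphSources = shares,
      pathwayCarbonFractions = fractions,
      predictedRQ = rq, predictedByproducts = byp)
}

#' Theoretical maximal lipid yield on a carbon source
#'
#' Fraction of consumed substrate carbon that can at most be directed into
#' lipid: growth is fixed to zero (minimal growth), maintenance stays at its
#' default, substrate uptake is fixed at a reference value, lipid export is
#' opened, CO2 uptake is closed (no net carbon fixation), and lipid export is
#' maximized. The result is (lipid flux x lipid carbon) / (uptake x substrate
#' carbon) and, being a flux ratio, does not depend on the reference uptake.
#'
#' @param model a \code{\link{MetabolicModel}} containing a lipid
#'   pseudo-metabolite with a known carbon count.
#' @param carbonSource \code{"glycerol"}, \code{"xylose"} or
#'   \code{"acetate"} (or a metabolite id).
#' @param uptake reference substrate uptake, mmol/gDW/h.
#' @param lipidMet metabolite id of the lipid species, default \code{"lip"}.
#' @return Yield in [0, 1], carbon fraction.
#' @examples
#' theoreticalMaxLipidYield(buildToyGEM(), "glycerol")
#' @export
theoreticalMaxLipidYield <- function(model, carbonSource, uptake = 10,
                                     lipidMet = "lip") {
  if (!lipidMet %in% model@metabolites$id)
    stop("configuration error: no lipid species '", lipidMet, "' in model")
  cc <- carbonCount(model)
  if (is.na(cc[lipidMet]) || cc[lipidMet] <= 0)
    stop("configuration error: lipid species has no carbon formula")
  src <- toyCarbonSource(carbonSource)
  exS <- src$exchange
  exL <- paste0("EX_", lipidMet)
  if (!exL %in% model@reactions$id) {
    # add a lipid export exchange
    model@reactions <- rbind(model@reactions, data.frame(
      id = exL, name = "lipid export", lowerBound = 0, upperBound = 1000,
      subsystem = "exchange"))
    model@S <- cbind(model@S, Matrix::Matrix(0, nrow(model@S), 1,
                                             sparse = TRUE))
    colnames(model@S)[ncol(model@S)] <- exL
    model@S[lipidMet, exL] <- -1
  }
  model <- applyMedium(model, exS)
  model <- setBounds(model, exS, lower = -uptake, upper = -uptake)
  model <- setBounds(model, exL, lower = 0, upper = 1000)
  model <- setBounds(model, "EX_co2", lower = 0)
  j <- match(model@biomassId, model@reactions$id)
  model@reactions$lowerBound[j] <- 0
  model@reactions$upperBound[j] <- 0
  sol <- fba(model, objective = stats::setNames(1, exL))
  if (sol@status != "optimal")
    stop("yield LP is ", sol@status, " for ", carbonSource)
  as.numeric(sol@objectiveValue * cc[lipidMet] / (uptake * cc[src$met]))
}
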