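#' Generate a synthetic turbidostat condition dataset
#'
#' Emulates one steady-state measurement set from the toy model's own flux
#' solutions. The C/N ratio sets the biomass composition through a stylized
#' nitrogen-limitation trend (lipid content rises, protein falls as C/N
#' increases); the biomass equation is rescaled accordingly; the minimal
#' substrate uptake supporting the requested growth rate is computed by FBA
#' and inflated by \code{uptakeExcess} (cells dissipate the excess as
#' maintenance ATP); the ground-truth flux distribution is the
#' maintenance-maximizing solution at that uptake. Measured quantities are
#' the ground-truth values perturbed by independent Gaussian noise with
#' coefficient of variation \code{noiseCV}, truncated at zero.
#'
#' @param model a toy \code{\link{MetabolicModel}} from
#'   \code{\link{buildToyGEM}}.
#' @param carbonSource \code{"glycerol"}, \code{"xylose"} or \code{"acetate"}.
#' @param cnRatio molar C/N ratio of the medium (sets composition).
#' @param mu target specific growth rate, 1/h.
#' @param noiseCV coefficient of variation of measurement noise, default 0.02.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param uptakeExcess uptake relative to the minimal requirement, default
#'   1.15.
#' @param measuredByproducts metabolite ids whose excretion the analytics
#'   "see" (default xylitol and pyruvate, as an HPLC assay would).
#' @return A \code{\link{ConditionData}}; slot \code{groundTruth} holds the
#'   generating fluxes and noiseless values for recovery tests.
#' @export
makeConditionDataset <- function(model, carbonSource, cnRatio, mu,
                                 noiseCV = 0.02, seed = 1L,
                                 uptakeExcess = 1.15,
                                 measuredByproducts = c("xlt", "pyr")) {
  stopifnot(cnRatio > 0, noiseCV >= 0, mu >= 0, uptakeExcess >= 1)
  comp <- compositionFromCN(cnRatio)
  m <- rescaleBiomass(model, protein = comp["protein"],
                      lipid = comp["lipid"])
  src <- toyCarbonSource(carbonSource)
  m <- applyMedium(m, src$exchange)
  j <- match(m@biomassId, m@reactions$id)
  m@reactions$lowerBound[j] <- mu
  m@reactions$upperBound[j] <- mu
  # minimal uptake at this growth rate (exchange flux is negative: maximize)
  minU <- fba(m, objective = stats::setNames(1, src$exchange))
  if (minU@status != "optimal")
    stop("growth rate ", mu, " infeasible on ", carbonSource,
         " (status ", minU@status, ")")
  uptake <- -minU@objectiveValue * uptakeExcess
  m <- setBounds(m, src$exchange, lower = -uptake, upper = -uptake)
  truth <- fba(m, objective = stats::setNames(1, "ATPM"))
  if (truth@status != "optimal")
    stop("ground-truth solve failed (status ", truth@status, ")")
  v <- truth@fluxes
  bypTruth <- vapply(measuredByproducts, function(mid) {
    e <- paste0("EX_", mid)
    if (e %in% names(v)) max(0, v[[e]]) else 0
  }, numeric(1))
  names(bypTruth) <- measuredByproducts
  true <- list(mu = mu, uptake = uptake, otr = -v[["EX_o2"]],
               ctr = v[["EX_co2"]], byproducts = bypTruth,
               protein = unname(comp["protein"]),
               lipid = unname(comp["lipid"]),
               rq = v[["EX_co2"]] / -v[["EX_o2"]],
               ngam = v[["ATPM"]])

  set.seed(as.integer(seed))
  jitter <- function(x) {
    y <- pmax(0, x * (1 + noiseCV * stats::rnorm(length(x))))
    names(y) <- names(x)
    y
  }
  new("ConditionData",
      carbonSource = src$met, cnRatio = cnRatio,
      mu = jitter(true$mu),
      substrateUptake = jitter(true$uptake),
      byproductRates = jitter(true$byproducts),
      otr = jitter(true$otr), ctr = jitter(true$ctr),
      proteinContent = jitter(true$protein),
      lipidContent = jitter(true$lipid),
      groundTruth = list(fluxes = v, values = true,
                         composition = comp))
}

# stylized composition trend: nitrogen limitation (high C/N) raises lipid and
# lowers protein content, within the ranges seen in oleaginous yeasts
compositionFromCN <- function(cnRatio) {
  lipid <- min(0.60, max(0.10, 0.15 + 0.35 * (cnRatio - 60) / 60))
  protein <- min(0.55, max(0.15, 0.50 - 0.25 * (cnRatio - 60) / 60))
  c(protein = protein, lipid = lipid)
}

#' Write a ConditionData as a TSV measurement table
#'
#' @param data a \code{\link{ConditionData}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeConditionData <- function(data, path) {
  row <- data.frame(
    carbon_source = data@carbonSource, cn_ratio = data@cnRatio,
    mu = data@mu, substrate_uptake = data@substrateUptake,
    otr = data@otr, ctr = data@ctr,
    protein_content = data@proteinContent,
    lipid_content = data@lipidContent)
  for (mid in names(data@byproductRates))
    row[[paste0("byproduct_", mid)]] <- data@byproductRates[[mid]]
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ConditionData from a TSV measurement table
#'
#' @param path TSV path written by \code{\link{writeConditionData}} (or by
#'   hand, same columns: byproducts as \code{byproduct_<metaboliteId>}).
#' @return A \code{\link{ConditionData}}.
#' @export
readConditionData <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (nrow(tab) != 1L)
    stop("expected exactly one condition row, found ", nrow(tab))
  bcols <- grep("^byproduct_", names(tab), value = TRUE)
  byp <- stats::setNames(as.numeric(tab[1, bcols]),
                         sub("^byproduct_", "", bcols))
  new("ConditionData",
      carbonSource = as.character(tab$carbon_source),
      cnRatio = as.numeric(tab$cn_ratio), mu = as.numeric(tab$mu),
      substrateUptake = as.numeric(tab$substrate_uptake),
      byproductRates = byp,
      otr = as.numeric(tab$otr), ctr = as.numeric(tab$ctr),
      proteinContent = as.numeric(tab$protein_content),
      lipidContent = as.numeric(tab$lipid_content),
      groundTruth = list())
}
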