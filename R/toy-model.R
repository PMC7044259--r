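# Pseudo-metabolite "monomer" molar masses (g/mol) used to convert biomass
# mass fractions into mmol/gDW coefficients: alanine-like protein residue,
# anhydroglucose carbohydrate unit, C16 acyl lipid unit, nucleotide monomer,
# small-molecule pool.
.monomerMass <- c(prot = 89, carb = 162, lip = 256, nuc = 330, oth = 62)

#' Default macromolecular composition of the toy model biomass
#'
#' @return A \code{\link{BiomassComposition}} (protein 0.45, lipid 0.15,
#'   carbohydrate 0.30, nucleotide 0.06, other 0.04 g/gDW), a typical
#'   exponential-growth composition for an oleaginous yeast before nitrogen
#'   limitation sets in.
#' @export
toyBiomassBaseline <- function() {
  BiomassComposition(protein = 0.45, lipid = 0.15, carbohydrate = 0.30,
                     nucleotide = 0.06, other = 0.04)
}

#' Build the bundled toy genome-scale model
#'
#' A hand-built, carbon-balanced ~40-reaction network of oleaginous yeast
#' central carbon metabolism: glycerol, xylose and acetate assimilation, the
#' oxidative and non-oxidative pentose phosphate pathway, phosphoketolase,
#' glycolysis/gluconeogenesis, TCA cycle with glyoxylate shunt, ATP-citrate
#' lyase, malic enzyme, oxidative phosphorylation with a configurable P/O
#' ratio, a lumped lipid synthesis (2 NADPH and 1 ATP per acetyl-CoA
#' incorporated, C16 lipid unit), and a macromolecular biomass equation with
#' growth-associated maintenance. Elemental bookkeeping tracks carbon and
#' nitrogen exactly; water and protons are not modeled, so H/O are not
#' conserved.
#'
#' Default medium: glycerol uptake open at 10 mmol/gDW/h, xylose and acetate
#' closed, O2 and ammonium unlimited, byproduct excretion (xylitol, pyruvate,
#' glyoxylate, acetate overflow) open, lipid export closed.
#'
#' @param poRatio ATP produced per NADH oxidized (P/O ratio), default 1.5.
#' @param gam growth-associated maintenance, mmol ATP per gDW biomass
#'   polymerized, default 30.
#' @param includePhosphoketolase,includeACL,includeMalicEnzyme,includeGlyoxylateShunt
#'   include the corresponding pathway (default TRUE).
#' @param composition a \code{\link{BiomassComposition}} for the biomass
#'   equation; default \code{\link{toyBiomassBaseline}}.
#' @return A \code{\link{MetabolicModel}}.
#' @examples
#' m <- buildToyGEM()
#' fba(m)@objectiveValue > 0   # grows on glycerol
#' @export
buildToyGEM <- function(poRatio = 1.5, gam = 30,
                        includePhosphoketolase = TRUE,
                        includeACL = TRUE,
                        includeMalicEnzyme = TRUE,
                        includeGlyoxylateShunt = TRUE,
                        composition = toyBiomassBaseline()) {
  stopifnot(poRatio > 0, gam >= 0)
  met <- function(id, name, formula, charge = 0L)
    data.frame(id = id, name = name, compartment = "c", formula = formula,
               charge = as.integer(charge))
  mets <- rbind(
    met("glyc",  "glycerol",                 "C3H8O3"),
    met("xyl",   "D-xylose",                 "C5H10O5"),
    met("ac",    "acetate",                  "C2H4O2"),
    met("xlt",   "xylitol",                  "C5H12O5"),
    met("pyr",   "pyruvate",                 "C3H4O3"),
    met("glx",   "glyoxylate",               "C2H2O3"),
    met("co2",   "carbon dioxide",           "CO2"),
    met("o2",    "oxygen",                   "O2"),
    met("nh4",   "ammonium",                 "H4N"),
    met("t3p",   "triose 3-phosphate",       "C3H7O6P"),
    met("g6p",   "hexose 6-phosphate",       "C6H13O9P"),
    met("x5p",   "pentose 5-phosphate",      "C5H11O8P"),
    met("accoa", "acetyl-CoA (acetyl unit)", "C2"),
    met("acp",   "acetyl phosphate (acetyl unit)", "C2"),
    met("oaa",   "oxaloacetate",             "C4H4O5"),
    met("cit",   "citrate",                  "C6H8O7"),
    met("akg",   "2-oxoglutarate",           "C5H6O5"),
    met("succ",  "succinate",                "C4H6O4"),
    met("mal",   "malate",                   "C4H6O5"),
    met("lip",   "lipid unit (lumped C16)",  "C16"),
    met("prot",  "protein unit (residue)",   "C3N"),
    met("carb",  "carbohydrate unit",        "C6"),
    met("nuc",   "nucleotide unit",          "C9N4"),
    met("oth",   "other biomass pool",       "C2"),
    met("atp",   "ATP",                      "C10N5"),
    met("adp",   "ADP",                      "C10N5"),
    met("nad",   "NAD+",                     "C21N7"),
    met("nadh",  "NADH",                     "C21N7"),
    met("nadp",  "NADP+",                    "C21N7"),
    met("nadph", "NADPH",                    "C21N7")
  )

  rx <- list()
  addRx <- function(id, name, stoich, lb, ub, subsystem) {
    rx[[id]] <<- list(id = id, name = name, stoich = stoich,
                      lb = lb, ub = ub, subsystem = subsystem)
  }
  BIG <- 1000

  # exchanges: flux > 0 secretes, flux < 0 takes up
  addRx("EX_glyc", "glycerol exchange", c(glyc = -1), -10, BIG, "exchange")
  addRx("EX_xyl",  "xylose exchange",   c(xyl = -1),   0, BIG, "exchange")
  addRx("EX_ac",   "acetate exchange",  c(ac = -1),    0, BIG, "exchange")
  addRx("EX_o2",   "oxygen exchange",   c(o2 = -1), -BIG,   0, "exchange")
  addRx("EX_co2",  "CO2 exchange",      c(co2 = -1),   0, BIG, "exchange")
  addRx("EX_nh4",  "ammonium exchange", c(nh4 = -1), -BIG,  0, "exchange")
  addRx("EX_xlt",  "xylitol exchange",  c(xlt = -1),   0, BIG, "exchange")
  addRx("EX_pyr",  "pyruvate exchange", c(pyr = -1),   0, BIG, "exchange")
  addRx("EX_glx",  "glyoxylate exchange", c(glx = -1), 0, BIG, "exchange")
  addRx("EX_lip",  "lipid export",      c(lip = -1),   0,   0, "exchange")

  # substrate assimilation
  addRx("GDH", "glycerol dehydrogenase (NADP) + DHA kinase",
        c(glyc = -1, nadp = -1, atp = -1, t3p = 1, nadph = 1, adp = 1),
        0, BIG, "glycerol assimilation")
  addRx("GLYK", "glycerol kinase + G3P dehydrogenase",
        c(glyc = -1, atp = -1, nad = -1, t3p = 1, adp = 1, nadh = 1),
        0, BIG, "glycerol assimilation")
  addRx("XR", "xylose reductase (NADPH)",
        c(xyl = -1, nadph = -1, xlt = 1, nadp = 1),
        0, BIG, "xylose assimilation")
  addRx("XDHK", "xylitol dehydrogenase + xylulokinase",
        c(xlt = -1, nad = -1, atp = -1, x5p = 1, nadh = 1, adp = 1),
        0, BIG, "xylose assimilation")
  addRx("ACS", "acetyl-CoA synthase (AMP-forming)",
        c(ac = -1, atp = -2, accoa = 1, adp = 2),
        0, BIG, "acetate assimilation")

  # glycolysis / gluconeogenesis / PPP
  addRx("PFK", "upper glycolysis (PFK + aldolase)",
        c(g6p = -1, atp = -1, t3p = 2, adp = 1), 0, BIG, "glycolysis")
  addRx("FBP", "gluconeogenesis (aldolase + FBPase)",
        c(t3p = -2, g6p = 1), 0, BIG, "gluconeogenesis")
  addRx("PYK", "lower glycolysis (GAPDH..pyruvate kinase)",
        c(t3p = -1, adp = -2, nad = -1, pyr = 1, atp = 2, nadh = 1),
        0, BIG, "glycolysis")
  addRx("GND", "oxidative PPP (G6PDH + 6PGDH)",
        c(g6p = -1, nadp = -2, x5p = 1, co2 = 1, nadph = 2),
        0, BIG, "pentose phosphate pathway")
  addRx("TKT", "non-oxidative PPP (TKT/TAL lumped)",
        c(x5p = -3, g6p = 2, t3p = 1), -BIG, BIG,
        "pentose phosphate pathway")
  if (includePhosphoketolase) {
    addRx("PK", "phosphoketolase",
          c(x5p = -1, acp = 1, t3p = 1), 0, BIG, "phosphoketolase")
    addRx("PTA", "phosphotransacetylase",
          c(acp = -1, accoa = 1), 0, BIG, "phosphoketolase")
    addRx("ACK", "acetate kinase (overflow)",
          c(acp = -1, adp = -1, ac = 1, atp = 1), 0, BIG, "phosphoketolase")
  }

  # pyruvate node and TCA
  addRx("PDH", "pyruvate dehydrogenase",
        c(pyr = -1, nad = -1, accoa = 1, co2 = 1, nadh = 1),
        0, BIG, "TCA cycle")
  addRx("PYC", "pyruvate carboxylase",
        c(pyr = -1, co2 = -1, atp = -1, oaa = 1, adp = 1),
        0, BIG, "anaplerosis")
  addRx("GNG", "PEP carboxykinase + gluconeogenic glycolysis",
        c(oaa = -1, atp = -2, nadh = -1, t3p = 1, co2 = 1, adp = 2, nad = 1),
        0, BIG, "gluconeogenesis")
  addRx("CS", "citrate synthase",
        c(accoa = -1, oaa = -1, cit = 1), 0, BIG, "TCA cycle")
  addRx("IDP", "aconitase + NADP-isocitrate dehydrogenase",
        c(cit = -1, nadp = -1, akg = 1, co2 = 1, nadph = 1),
        0, BIG, "TCA cycle")
  addRx("AKGD", "2-oxoglutarate dehydrogenase .. malate dehydrogenase",
        c(akg = -1, nad = -2, adp = -1, oaa = 1, co2 = 1, nadh = 2, atp = 1),
        0, BIG, "TCA cycle")
  if (includeGlyoxylateShunt) {
    addRx("ICL", "isocitrate lyase",
          c(cit = -1, succ = 1, glx = 1), 0, BIG, "glyoxylate shunt")
    addRx("MAS", "malate synthase",
          c(glx = -1, accoa = -1, mal = 1), 0, BIG, "glyoxylate shunt")
    addRx("SDH", "succinate dehydrogenase + fumarase",
          c(succ = -1, nad = -1, mal = 1, nadh = 1), 0, BIG,
          "glyoxylate shunt")
  }
  addRx("MDH", "malate dehydrogenase",
        c(mal = -1, nad = -1, oaa = 1, nadh = 1), -BIG, BIG, "TCA cycle")
  if (includeMalicEnzyme)
    addRx("ME", "malic enzyme (NADP)",
          c(mal = -1, nadp = -1, pyr = 1, co2 = 1, nadph = 1),
          0, BIG, "malic enzyme")
  if (includeACL)
    addRx("ACL", "ATP-citrate lyase",
          c(cit = -1, atp = -1, accoa = 1, oaa = 1, adp = 1),
          0, BIG, "ATP-citrate lyase")

  # energy metabolism
  addRx("OXPHOS", "oxidative phosphorylation",
        c(nadh = -1, o2 = -0.5, adp = -poRatio, nad = 1, atp = poRatio),
        0, BIG, "oxidative phosphorylation")
  addRx("ATPM", "ATP hydrolysis (non-growth maintenance)",
        c(atp = -1, adp = 1), 0, BIG, "maintenance")

  # biosynthesis
  addRx("LIPS", "lipid synthesis (8 acetyl-CoA per C16 unit)",
        c(accoa = -8, nadph = -16, atp = -8, lip = 1, nadp = 16, adp = 8),
        0, BIG, "lipid synthesis")
  addRx("PROTS", "protein synthesis (lumped)",
        c(pyr = -1, nh4 = -1, atp = -2, nadph = -1,
          prot = 1, adp = 2, nadp = 1), 0, BIG, "biosynthesis")
  addRx("CARBS", "storage carbohydrate synthesis",
        c(g6p = -1, atp = -1, carb = 1, adp = 1), 0, BIG, "biosynthesis")
  addRx("NUCS", "nucleotide synthesis (lumped)",
        c(g6p = -1, pyr = -1, nh4 = -4, atp = -8, nadph = -2,
          nuc = 1, adp = 8, nadp = 2), 0, BIG, "biosynthesis")
  addRx("OTHS", "other biomass pool synthesis",
        c(accoa = -1, atp = -1, oth = 1, adp = 1), 0, BIG, "biosynthesis")

  bm <- biomassStoichiometry(composition, gam)
  addRx("BIOMASS", "biomass equation", bm, 0, BIG, "biomass")

  rxn <- data.frame(
    id = vapply(rx, `[[`, "", "id"),
    name = vapply(rx, `[[`, "", "name"),
    lowerBound = vapply(rx, `[[`, 0, "lb"),
    upperBound = vapply(rx, `[[`, 0, "ub"),
    subsystem = vapply(rx, `[[`, "", "subsystem"))
  S <- matrix(0, nrow(mets), nrow(rxn),
              dimnames = list(mets$id, rxn$id))
  for (r in rx) S[names(r$stoich), r$id] <- r$stoich
  MetabolicModel(mets, rxn, S, biomassId = "BIOMASS",
                 objective = c(BIOMASS = 1))
}

# biomass reaction stoichiometry (mmol precursor per gDW) from a composition
biomassStoichiometry <- function(composition, gam) {
  stopifnot(is(composition, "BiomassComposition"))
  f <- c(prot = composition@protein, lip = composition@lipid,
         carb = composition@carbohydrate, nuc = composition@nucleotide,
         oth = composition@other)
  coefs <- -1000 * f / .monomerMass[names(f)]
  c(coefs, atp = -gam, adp = gam)
}

#' Pathway registry for the toy model
#'
#' Reaction-id sets used by \code{\link{attributeFluxes}}: all NADPH-producing
#' reactions and the signature reactions of the acetyl-CoA-supplying pathways.
#'
#' @return Named list with elements \code{nadph}, \code{phosphoketolase},
#'   \code{acl}, \code{malicEnzyme}, plus the bookkeeping ids
#'   \code{nadphMet}, \code{currencyMets}, \code{o2Exchange},
#'   \code{co2Exchange}.
#' @export
toyPathwayRegistry <- function() {
  list(
    nadph = c("GDH", "GND", "IDP", "ME"),
    phosphoketolase = "PK",
    acl = "ACL",
    malicEnzyme = "ME",
    nadphMet = "nadph",
    currencyMets = c("atp", "adp", "nad", "nadh", "nadp", "nadph",
                     "o2", "co2", "nh4"),
    o2Exchange = "EX_o2",
    co2Exchange = "EX_co2"
  )
}

#' Carbon-source lookup for the toy model
#'
#' @param source one of \code{"glycerol"}, \code{"xylose"}, \code{"acetate"},
#'   or a metabolite id of the toy model.
#' @return List with \code{met} (metabolite id) and \code{exchange}
#'   (exchange reaction id).
#' @export
toyCarbonSource <- function(source) {
  map <- c(glycerol = "glyc", xylose = "xyl", acetate = "ac",
           glyc = "glyc", xyl = "xyl", ac = "ac")
  if (!source %in% names(map)) stop("unknown carbon source: ", source)
  met <- unname(map[source])
  list(met = met, exchange = paste0("EX_", met))
}
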