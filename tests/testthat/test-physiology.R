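mkCondition <- function(mu = 0.24, uptake = 10, otr = 5, ctr = 5,
                        lipid = 0.354, protein = 0.4, cn = 100,
                        byproducts = numeric(0), source = "glyc") {
  new("ConditionData", carbonSource = source, cnRatio = cn, mu = mu,
      substrateUptake = uptake, byproductRates = byproducts,
      otr = otr, ctr = ctr, proteinContent = protein, lipidContent = lipid,
      groundTruth = list())
}

test_that("steady-state rate identities hold", {
  d <- mkCondition(mu = 0.24, lipid = 0.354)
  s <- deriveRates(d, biomassConc = 5)
  expect_equal(s$r_lip, 0.354 * 0.24, tolerance = 1e-12)  # ~0.085 g/gDW/h
  expect_equal(round(s$r_lip, 3), 0.085)
  expect_equal(s$q_bm, 0.24 * 5)
  expect_equal(s$rq, 1)
  # y_ls = lipid_content * y_sx: lipid is part of the biomass
  expect_equal(s$y_ls, d@lipidContent * s$y_sx, tolerance = 1e-12)
  # growth arrest zeroes every production rate
  s0 <- deriveRates(mkCondition(mu = 0), biomassConc = 5)
  expect_equal(c(s0$r_lip, s0$q_bm, s0$y_sx, s0$y_ls), rep(0, 4))
})

test_that("rates are invariant to a consistent change of mass units", {
  d <- mkCondition()
  a <- deriveRates(d, biomassConc = 5)
  # substrate molar mass in mg/mmol with uptake in mmol -> uptake mass in
  # mg; converting titers consistently must rescale yields by exactly 1e3
  b <- deriveRates(d, biomassConc = 5, substrateMolarMass = 92.094 * 1000)
  expect_equal(b$y_sx * 1000, a$y_sx, tolerance = 1e-12)
  expect_equal(b$y_ls * 1000, a$y_ls, tolerance = 1e-12)
  expect_equal(b$rq, a$rq)
})

test_that("RQ is guarded against a zero oxygen transfer", {
  expect_error(deriveRates(mkCondition(otr = 0, ctr = 3)), "RQ undefined")
})

test_that("carbon recovery closes on complete data and drops when products are hidden", {
  m <- buildToyGEM()
  d <- makeConditionDataset(m, "glycerol", 100, 0.2, noiseCV = 0, seed = 1,
                            measuredByproducts = c("xlt", "pyr", "glx", "ac"))
  # biomass C content of the toy model, computed from its composition
  j <- match("BIOMASS", reactions(m)$id)
  cc <- carbonCount(m)
  coef <- as.matrix(stoichiometry(m))[, j]
  pools <- c("prot", "carb", "lip", "nuc", "oth")
  m2 <- rescaleBiomass(m, d@proteinContent, d@lipidContent)
  bioC <- -sum(as.matrix(stoichiometry(m2))[pools, j] * cc[pools])
  rec <- carbonRecovery(d, biomassCContent = bioC,
                        carbonNumbers = c(ac = 2))
  expect_equal(rec, 1, tolerance = 1e-6)
  # dropping measured byproducts can only lower recovery
  d2 <- d
  d2@byproductRates <- d@byproductRates["xlt"]
  expect_lte(carbonRecovery(d2, biomassCContent = bioC), rec + 1e-9)
  # a hidden efflux (carbon leaving unmeasured) lowers recovery by exactly
  # its carbon share of the uptake
  dHid <- d
  hidden <- 0.1 * d@substrateUptake / 3       # mmol pyruvate-like C3 leak
  dHid@ctr <- d@ctr - hidden * 3
  expect_equal(carbonRecovery(dHid, biomassCContent = bioC,
                              carbonNumbers = c(ac = 2)),
               1 - hidden * 3 / (d@substrateUptake * 3), tolerance = 1e-6)
  expect_error(carbonRecovery(mkCondition(uptake = 0)), "positive")
  expect_error(
    carbonRecovery(mkCondition(byproducts = c(mystery = 1))),
    "mystery")
})

test_that("medium C/N ratio follows elemental arithmetic and scale invariance", {
  r <- mediumRecipe(data.frame(id = c("glyc", "nh4so4"),
                               concentration = c(10, 5)))
  expect_equal(cnRatio(r), (10 / 92.094 * 3) / (5 / 132.14 * 2),
               tolerance = 1e-12)
  expect_equal(cnRatio(r), 4.305, tolerance = 1e-3)
  r2 <- r; r2$concentration <- r2$concentration * 2
  expect_equal(cnRatio(r2), cnRatio(r), tolerance = 1e-12)
  expect_error(cnRatio(mediumRecipe(data.frame(id = "glyc",
                                               concentration = 10))),
               "no nitrogen")
})

test_that("fed-batch yield arithmetic reproduces the end-point identities", {
  s <- fedbatchYieldSummary(6.0, 14.6, 2.3)
  expect_equal(round(s$y_ls, 3), 0.179)
  expect_equal(round(s$lipid_content, 3), 0.411)
  # titer = content x biomass round trip is exact
  s2 <- fedbatchYieldSummary(s$lipid_content * 14.6, 14.6, 2.3)
  expect_equal(s2$lipid_content, s$lipid_content, tolerance = 1e-12)
  expect_error(fedbatchYieldSummary(-1, 10, 2), "lipidTiter")
})

test_that("pipeline RQ equals dataset RQ within the relaxation on clean data", {
  m <- buildToyGEM()
  d <- makeConditionDataset(m, "glycerol", 100, 0.2, noiseCV = 0, seed = 1)
  cm <- estimateNGAM(constrainCondition(rescaleBiomass(
    m, d@proteinContent, d@lipidContent), d))
  at <- attributeFluxes(cm, sampleCondition(cm, n = 80, seed = 3))
  rqData <- deriveRates(d)$rq
  expect_lt(abs(at@predictedRQ - rqData) / rqData, 2 * cm@relaxation + 1e-9)
})
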