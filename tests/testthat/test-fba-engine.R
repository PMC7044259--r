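test_that("FBA solves bottleneck chains exactly", {
  m <- chainModel(convUB = 10, exAUB = 5)
  sol <- fba(m, objective = c(EX_B = 1))
  expect_identical(sol@status, "optimal")
  expect_equal(sol@objectiveValue, 5, tolerance = 1e-9)
  m2 <- chainModel(convUB = 3, exAUB = 5)
  expect_equal(fba(m2, objective = c(EX_B = 1))@objectiveValue, 3,
               tolerance = 1e-9)
})

test_that("FBA reports infeasible and unbounded status faithfully", {
  m <- chainModel(convUB = 3, exAUB = 5)
  # force uptake of at least 4 against a conversion cap of 3
  m <- setBounds(m, "EX_A", lower = -5, upper = -4)
  sol <- fba(m, objective = c(EX_B = 1))
  expect_identical(sol@status, "infeasible")
  expect_length(sol@fluxes, 0)
  # open bounds on a through-path -> unbounded objective
  mu <- chainModel()
  mu <- setBounds(mu, "EX_A", lower = -Inf)
  mu <- setBounds(mu, "CONV", upper = Inf)
  mu <- setBounds(mu, "EX_B", upper = Inf)
  expect_identical(fba(mu, objective = c(EX_B = 1))@status, "unbounded")
})

test_that("LP optimum equals exhaustive vertex enumeration on small networks", {
  for (seed in 1:40) {
    m <- randomSmallModel(seed)
    S <- as.matrix(stoichiometry(m))
    lb <- reactions(m)$lowerBound
    ub <- reactions(m)$upperBound
    cc <- rep(0, ncol(S)); names(cc) <- reactions(m)$id
    cc[names(objectiveCoefficients(m))] <- objectiveCoefficients(m)
    oracle <- enumerateLP(S, lb, ub, cc, maximize = TRUE)
    sol <- fba(m, direction = "max")
    if (!oracle$feasible) {
      expect_identical(sol@status, "infeasible")
      next
    }
    expect_identical(sol@status, "optimal")
    expect_equal(sol@objectiveValue, oracle$objective, tolerance = 1e-6)
    expect_lt(maxAbsMassViolation(m, fluxes(sol)), 1e-6)
    expect_true(all(fluxes(sol) >= lb - 1e-6 & fluxes(sol) <= ub + 1e-6))
  }
})

test_that("FBA on the toy model agrees with an independent HiGHS solve", {
  m <- buildToyGEM()
  prob <- list(S = as.matrix(stoichiometry(m)),
               lb = reactions(m)$lowerBound, ub = reactions(m)$upperBound,
               c = as.numeric(reactions(m)$id == "BIOMASS"))
  pf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(prob, pf, digits = NA, matrix = "rowmajor")
  py <- paste(
    "import json,sys,numpy as np",
    "from scipy.optimize import linprog",
    sprintf("p=json.load(open(%s))", deparse(pf)),
    "S=np.array(p['S']);c=np.array(p['c'],float)",
    "r=linprog(-c,A_eq=S,b_eq=np.zeros(S.shape[0]),",
    "  bounds=list(zip(p['lb'],p['ub'])),method='highs')",
    "print(repr(-r.fun))", sep = "\n")
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  ref <- as.numeric(tail(out, 1))
  expect_equal(fba(m)@objectiveValue, ref, tolerance = 1e-6)
})

test_that("FVA collapses determined paths and zeroes blocked reactions", {
  m <- chainModel(convUB = 3, exAUB = 5)
  m <- setBounds(m, "EX_A", lower = -3, upper = -3)  # fully determined chain
  r <- fluxVariability(m)@ranges
  expect_equal(r$min, r$max, tolerance = 1e-8)
  expect_equal(r[r$id == "CONV", "max"], 3, tolerance = 1e-8)
  # a disconnected reaction is blocked at [0, 0]
  m2 <- buildToyGEM(includePhosphoketolase = FALSE)
  mets <- rbind(metabolites(m2),
                data.frame(id = "orphan", name = "orphan", compartment = "c",
                           formula = NA, charge = 0L))
  S <- rbind(as.matrix(stoichiometry(m2)), orphan = 0)
  S <- cbind(S, ORPH = 0); S["orphan", "ORPH"] <- 1
  rxns <- rbind(reactions(m2),
                data.frame(id = "ORPH", name = "orphan maker",
                           lowerBound = 0, upperBound = 1000, subsystem = ""))
  m2 <- MetabolicModel(mets, rxns, S, biomassId = "BIOMASS")
  rr <- fluxVariability(m2, reactions = "ORPH")@ranges
  expect_equal(c(rr$min, rr$max), c(0, 0), tolerance = 1e-8)
})

test_that("sampling is deterministic, feasible, and contained in FVA ranges", {
  m <- buildToyGEM()
  m <- setBounds(m, "BIOMASS", lower = 0.2, upper = 0.2)
  s1 <- sampleFluxes(m, n = 40, seed = 7)
  s2 <- sampleFluxes(m, n = 40, seed = 7)
  expect_identical(fluxMatrix(s1), fluxMatrix(s2))
  expect_identical(s1@n, 40L)
  M <- fluxMatrix(s1)
  for (i in seq_len(nrow(M)))
    expect_lt(maxAbsMassViolation(m, M[i, ]), 1e-6)
  fva <- fluxVariability(m)@ranges
  lo <- fva$min[match(colnames(M), fva$id)]
  hi <- fva$max[match(colnames(M), fva$id)]
  expect_true(all(sweep(M, 2, lo, `-`) >= -1e-6))
  expect_true(all(sweep(M, 2, hi, `-`) <= 1e-6))
  means <- colMeans(M)
  expect_true(all(means >= lo - 1e-6 & means <= hi + 1e-6))
  expect_error(sampleFluxes(m, n = 0), "positive")
})

test_that("a fully determined network yields identical sample rows", {
  m <- chainModel(convUB = 3, exAUB = 5)
  m <- setBounds(m, "EX_A", lower = -3, upper = -3)
  M <- fluxMatrix(sampleFluxes(m, n = 15, seed = 3))
  expect_equal(max(apply(M, 2, function(x) diff(range(x)))), 0,
               tolerance = 1e-9)
})

test_that("sampling is equivariant under reaction reordering", {
  m <- buildToyGEM()
  m <- setBounds(m, "BIOMASS", lower = 0.15, upper = 0.15)
  perm <- rev(seq_len(nrow(reactions(m))))
  mp <- MetabolicModel(metabolites(m), reactions(m)[perm, ],
                       as.matrix(stoichiometry(m))[, perm],
                       biomassId = "BIOMASS",
                       objective = objectiveCoefficients(m))
  M1 <- fluxMatrix(sampleFluxes(m, n = 12, seed = 5))
  M2 <- fluxMatrix(sampleFluxes(mp, n = 12, seed = 5))
  expect_equal(M2[, colnames(M1)], M1, tolerance = 1e-9)
})
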