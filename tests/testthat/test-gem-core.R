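test_that("formula parsing and carbon counting follow Hill notation", {
  expect_equal(parseFormula("C3H8O3")[[1]][["C"]], 3)
  m <- buildToyGEM()
  expect_identical(unname(carbonCount(m, "glyc")), 3L)
  expect_identical(unname(carbonCount(m, "xyl")), 5L)
  expect_identical(unname(carbonCount(m, "nh4")), 0L)   # N only, no carbon
  expect_null(parseFormula("not a formula!")[[1]])
  expect_null(parseFormula(NA_character_)[[1]])
  expect_error(carbonCount(m, "nope"), "unknown metabolite")
})

test_that("model validity catches malformed inputs", {
  m <- buildToyGEM()
  expect_true(validObject(m))
  expect_error(setBounds(m, "PFK", lower = 5, upper = 1),
               "lowerBound > upperBound")
  expect_error(setBounds(m, "NOT_A_RXN", lower = 0), "unknown reaction")
  bad <- reactions(m)
  bad$id[2] <- bad$id[1]
  expect_error(MetabolicModel(metabolites(m), bad,
                              as.matrix(stoichiometry(m)), "BIOMASS"),
               "duplicated")
})

test_that("biomass composition must be a closed unit mass", {
  expect_error(BiomassComposition(.5, .3, .3, .05, .05), "sum to 1")
  expect_error(BiomassComposition(1.2, -.2, 0, 0, 0), "\\[0, 1\\]")
  ok <- BiomassComposition(.45, .15, .30, .06, .04)
  expect_s4_class(ok, "BiomassComposition")
})

test_that("exchange detection equals the declared exchange set of the toy model", {
  m <- buildToyGEM()
  declared <- reactions(m)$id[reactions(m)$subsystem == "exchange"]
  expect_setequal(exchangeReactions(m), declared)
})

test_that("the toy network is carbon- and nitrogen-balanced internally", {
  m <- buildToyGEM()
  expect_identical(nrow(checkMassBalance(m, elements = "C")), 0L)
  expect_identical(nrow(checkMassBalance(m, elements = c("C", "N"))), 0L)
})

test_that("mass-balance checker flags defects, unknowns, and skips pseudo-reactions", {
  m <- buildToyGEM()
  # inject a carbon-losing defect: A(C3) -> B(C2)
  mets <- rbind(metabolites(m),
                data.frame(id = c("defA", "defB"), name = c("A", "B"),
                           compartment = "c", formula = c("C3", "C2"),
                           charge = 0L))
  S <- as.matrix(stoichiometry(m))
  S <- rbind(S, matrix(0, 2, ncol(S), dimnames = list(c("defA", "defB"))))
  S <- cbind(S, DEFECT = 0, SRC = 0)
  S["defA", "DEFECT"] <- -1; S["defB", "DEFECT"] <- 1
  S["defA", "SRC"] <- 1
  rxns <- rbind(reactions(m),
                data.frame(id = c("DEFECT", "SRC"), name = c("defect", "src"),
                           lowerBound = 0, upperBound = 0, subsystem = ""))
  m2 <- MetabolicModel(mets, rxns, S, biomassId = "BIOMASS")
  bal <- checkMassBalance(m2)
  expect_true("DEFECT" %in% bal$reaction)
  row <- bal[bal$reaction == "DEFECT", ]
  expect_equal(row$residual, -1)          # one carbon lost
  expect_equal(row$element, "C")
  # biomass and maintenance are never reported
  expect_false(any(c("BIOMASS", "ATPM") %in% bal$reaction))
  # missing formula -> unknown, not balanced/unbalanced
  mets2 <- metabolites(m2)
  mets2$formula[mets2$id == "defA"] <- NA
  m3 <- MetabolicModel(mets2, rxns, S, biomassId = "BIOMASS")
  bal3 <- checkMassBalance(m3)
  expect_identical(bal3$status[bal3$reaction == "DEFECT"], "unknown")
})

test_that("JSON and SBML round trips preserve S, bounds and objective exactly", {
  m <- buildToyGEM()
  for (ext in c("json", "xml")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    writeGEM(m, f)
    m2 <- readGEM(f)
    expect_identical(as.matrix(stoichiometry(m2)), as.matrix(stoichiometry(m)))
    expect_identical(reactions(m2)$lowerBound, reactions(m)$lowerBound)
    expect_identical(reactions(m2)$upperBound, reactions(m)$upperBound)
    expect_identical(objectiveCoefficients(m2), objectiveCoefficients(m))
    expect_identical(biomassReaction(m2), biomassReaction(m))
    expect_identical(metabolites(m2)$formula, metabolites(m)$formula)
  }
})

test_that("model readers report malformed files and missing biomass", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", f)
  expect_error(readGEM(f), "malformed")
  writeLines('{"metabolites": [{"id": "a"}], "reactions": []}', f)
  expect_error(readGEM(f), "biomass")
  m <- buildToyGEM()
  j <- jsonlite::fromJSON(writeGEM(m, f), simplifyVector = FALSE)
  j$biomass_reaction <- "GONE"
  jsonlite::write_json(j, f, auto_unbox = TRUE, digits = NA)
  expect_error(readGEM(f), "biomass reaction 'GONE' not present")
  expect_error(readGEM("/nonexistent/file.json"), "not found")
})
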