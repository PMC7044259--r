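#' Command-line pipeline dispatcher
#'
#' Programmatic entry point behind the \code{inst/scripts/oleoflux} script.
#' Subcommands: \code{synth} (toy model + synthetic dataset),
#' \code{validate-model} (mass-balance check), \code{fba},
#' \code{condition-run} (constrain, NGAM, sample, attribute),
#' \code{theoretical-yield}, \code{physiology}, \code{fedbatch-plan}.
#' Every output file starts with a provenance header (package version, seed,
#' parameters) as comment lines for TSV, or a \code{provenance} field for
#' JSON. Existing outputs are never overwritten unless \code{--force} is
#' given.
#'
#' @param args character vector of command-line arguments (first element the
#'   subcommand; flags as \code{--name value} or \code{--flag}).
#' @return Integer exit status: 0 ok, 2 configuration error, 3 infeasible
#'   model. Called for its side effects (files under \code{--out-dir}).
#' @export
runPipeline <- function(args) {
  status <- tryCatch({
    if (!length(args)) stop(configError("no subcommand given"))
    cmd <- args[1]
    opts <- parseFlags(args[-1])
    dir <- opts$flags[["out-dir"]] %||% "."
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    seed <- as.integer(opts$flags[["seed"]] %||% "1")
    force <- isTRUE(opts$switches[["force"]])
    switch(cmd,
      "synth" = cmdSynth(opts, dir, seed, force),
      "validate-model" = cmdValidate(opts, dir, force),
      "fba" = cmdFba(opts, dir, seed, force),
      "condition-run" = cmdConditionRun(opts, dir, seed, force),
      "theoretical-yield" = cmdYield(opts, dir, force),
      "physiology" = cmdPhysiology(opts, dir, force),
      "fedbatch-plan" = cmdFedbatch(opts, dir, force),
      stop(configError(paste0("unknown subcommand '", cmd, "'"))))
    0L
  }, oleofluxConfigError = function(e) {
    message("configuration error: ", conditionMessage(e)); 2L
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("infeasible|unbounded", msg)) 3L else 2L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

configError <- function(msg)
  structure(class = c("oleofluxConfigError", "error", "condition"),
            list(message = msg, call = NULL))

parseFlags <- function(args) {
  flags <- list(); switches <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(configError(paste0("unexpected argument '", a, "'")))
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      flags[[key]] <- args[i + 1]; i <- i + 2
    } else {
      switches[[key]] <- TRUE; i <- i + 1
    }
  }
  list(flags = flags, switches = switches)
}

provHeader <- function(seed = NA, params = list()) {
  ver <- as.character(utils::packageVersion("oleoflux"))
  p <- paste(names(params), unlist(params), sep = "=", collapse = " ")
  c(paste0("# oleoflux ", ver),
    paste0("# seed: ", seed),
    if (nzchar(p)) paste0("# params: ", p))
}

checkOverwrite <- function(path, force) {
  if (file.exists(path) && !force)
    stop(configError(paste0("output '", path,
                            "' exists; pass --force to overwrite")))
  path
}

writeTsvWithHeader <- function(df, path, seed, params, force) {
  checkOverwrite(path, force)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provHeader(seed, params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

numFlag <- function(opts, name, default = NULL) {
  v <- opts$flags[[name]]
  if (is.null(v)) {
    if (is.null(default)) stop(configError(paste0("missing --", name)))
    return(default)
  }
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) stop(configError(paste0("--", name, " must be numeric")))
  x
}

loadModelFlag <- function(opts) {
  path <- opts$flags[["model"]]
  if (is.null(path)) return(buildToyGEM())
  readGEM(path)
}

cmdSynth <- function(opts, dir, seed, force) {
  model <- buildToyGEM()
  src <- opts$flags[["source"]] %||% "glycerol"
  cn <- numFlag(opts, "cn", 100)
  mu <- numFlag(opts, "mu", 0.2)
  cv <- numFlag(opts, "noise-cv", 0.02)
  ds <- makeConditionDataset(model, src, cn, mu, noiseCV = cv, seed = seed)
  mp <- checkOverwrite(file.path(dir, "toy_model.json"), force)
  writeGEM(model, mp)
  dp <- checkOverwrite(file.path(dir, "condition.tsv"), force)
  writeConditionData(ds, dp)
  message("wrote ", mp, " and ", dp)
}

cmdValidate <- function(opts, dir, force) {
  model <- loadModelFlag(opts)
  bal <- checkMassBalance(model)
  writeTsvWithHeader(bal, file.path(dir, "mass_balance.tsv"), NA,
                     list(), force)
  message(if (nrow(bal)) paste(nrow(bal), "problem row(s)") else
          "all internal reactions balanced")
}

cmdFba <- function(opts, dir, seed, force) {
  model <- loadModelFlag(opts)
  sol <- fba(model)
  if (sol@status != "optimal") stop("model is ", sol@status)
  df <- data.frame(id = names(sol@fluxes), flux = as.numeric(sol@fluxes))
  writeTsvWithHeader(df, file.path(dir, "fba_fluxes.tsv"), seed,
                     list(objective = sol@objectiveValue), force)
  message("objective: ", format(sol@objectiveValue, digits = 8))
}

cmdConditionRun <- function(opts, dir, seed, force) {
  model <- loadModelFlag(opts)
  dataPath <- opts$flags[["data"]] %||%
    stop(configError("condition-run needs --data <tsv>"))
  data <- readConditionData(dataPath)
  relax <- numFlag(opts, "relax", 0.025)
  if (relax < 0 || relax >= 1)
    stop(configError("--relax must lie in [0, 1)"))
  n <- as.integer(numFlag(opts, "n", 5000))
  registry <- if (!is.null(opts$flags[["registry"]]))
    yaml::read_yaml(opts$flags[["registry"]]) else toyPathwayRegistry()
  model <- rescaleBiomass(model, data@proteinContent, data@lipidContent)
  cm <- constrainCondition(model, data, relaxation = relax)
  cm <- estimateNGAM(cm)
  smp <- sampleCondition(cm, n = n, seed = seed)
  attr <- attributeFluxes(cm, smp, registry = registry)
  writeTsvWithHeader(cm@fitReport, file.path(dir, "fit_report.tsv"), seed,
                     list(relax = relax, ngam = cm@ngam), force)
  writeTsvWithHeader(as.data.frame(smp@matrix),
                     file.path(dir, "flux_sample.tsv"), seed,
                     list(n = n), force)
  out <- list(provenance = list(
                version = as.character(utils::packageVersion("oleoflux")),
                seed = seed, n = n, relax = relax),
              ngam = cm@ngam,
              nadph_sources = as.list(attr@nadphSources),
              pathway_carbon_fractions = as.list(attr@pathwayCarbonFractions),
              predicted_rq = attr@predictedRQ,
              predicted_byproducts = as.list(attr@predictedByproducts))
  jp <- checkOverwrite(file.path(dir, "flux_attribution.json"), force)
  jsonlite::write_json(out, jp, auto_unbox = TRUE, digits = NA)
  message("predicted RQ: ", format(attr@predictedRQ, digits = 4))
}

cmdYield <- function(opts, dir, force) {
  model <- loadModelFlag(opts)
  src <- opts$flags[["source"]] %||% stop(configError("needs --source"))
  y <- theoreticalMaxLipidYield(model, src)
  df <- data.frame(carbon_source = src, max_lipid_carbon_yield = y)
  writeTsvWithHeader(df, file.path(dir, "theoretical_yield.tsv"), NA,
                     list(source = src), force)
  message("max lipid carbon yield on ", src, ": ", format(y, digits = 8))
}

cmdPhysiology <- function(opts, dir, force) {
  dataPath <- opts$flags[["data"]] %||%
    stop(configError("physiology needs --data <tsv>"))
  data <- readConditionData(dataPath)
  xconc <- numFlag(opts, "biomass-conc", 1)
  summ <- deriveRates(data, biomassConc = xconc)
  summ$carbon_recovery <- carbonRecovery(data)
  writeTsvWithHeader(summ, file.path(dir, "physiology.tsv"), NA,
                     list(biomass_conc = xconc), force)
  message("rq ", format(summ$rq, digits = 4),
          ", y_sx ", format(summ$y_sx, digits = 4))
}

cmdFedbatch <- function(opts, dir, force) {
  plan <- fedBatchPlan(
    yxs = numFlag(opts, "yxs"), mu0 = numFlag(opts, "mu0"),
    cf = numFlag(opts, "cf"), cs0 = numFlag(opts, "cs0", 0),
    x0 = numFlag(opts, "x0"), v0 = numFlag(opts, "v0"),
    duration = numFlag(opts, "duration", 48))
  dt <- numFlag(opts, "dt", 0.01)
  tr <- simulateFedBatch(plan, dt = dt)
  writeTsvWithHeader(tr@trajectory, file.path(dir, "fedbatch_trajectory.tsv"),
                     NA, list(mu0 = plan@mu0, yxs = plan@yxs), force)
  feed <- tr@trajectory[, c("t", "F")]
  feed$F_mL_h <- feed$F * 1000
  writeTsvWithHeader(feed, file.path(dir, "feed_profile.tsv"), NA,
                     list(), force)
  message("final biomass ", format(utils::tail(tr@trajectory$x, 1),
                                   digits = 5), " gDW/L")
}
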