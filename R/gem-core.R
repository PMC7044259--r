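#' Construct a MetabolicModel
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{formula}, \code{charge} (missing optional
#'   columns are filled with defaults).
#' @param reactions data.frame with columns \code{id}, \code{name},
#'   \code{lowerBound}, \code{upperBound}, \code{subsystem}.
#' @param S stoichiometric matrix (metabolites x reactions); a base matrix is
#'   converted to a sparse one. Row/column names are set from the id columns.
#' @param biomassId id of the biomass reaction.
#' @param objective named numeric of objective weights; defaults to weight 1
#'   on the biomass reaction.
#' @return A validated \code{\link{MetabolicModel}}.
#' @export
MetabolicModel <- function(metabolites, reactions, S, biomassId,
                           objective = NULL) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- 0L
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  S <- Matrix::Matrix(S, sparse = TRUE)
  dimnames(S) <- list(metabolites$id, reactions$id)
  if (is.null(objective)) {
    objective <- stats::setNames(1, biomassId)
  }
  objective <- stats::setNames(as.numeric(objective), names(objective))
  new("MetabolicModel", metabolites = metabolites, reactions = reactions,
      S = S, biomassId = biomassId, objective = objective)
}

#' @rdname MetabolicModel-class
#' @export
setMethod("metabolites", "MetabolicModel", function(x) x@metabolites)

#' @rdname MetabolicModel-class
#' @export
setMethod("reactions", "MetabolicModel", function(x) x@reactions)

#' @rdname MetabolicModel-class
#' @export
setMethod("stoichiometry", "MetabolicModel", function(x) x@S)

#' @rdname MetabolicModel-class
#' @export
setMethod("biomassReaction", "MetabolicModel", function(x) x@biomassId)

#' @rdname MetabolicModel-class
#' @export
setMethod("objectiveCoefficients", "MetabolicModel", function(x) x@objective)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel with", nrow(object@metabolites), "metabolites and",
      nrow(object@reactions), "reactions\n")
  cat("  biomass reaction:", object@biomassId, "\n")
  ex <- exchangeReactions(object)
  cat("  exchange reactions:", length(ex), "\n")
  invisible(object)
})

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution, status:", object@status)
  if (object@status == "optimal")
    cat(", objective:", format(object@objectiveValue, digits = 6))
  cat("\n")
  invisible(object)
})

setMethod("show", "FluxSample", function(object) {
  cat("FluxSample:", object@n, "samples x", ncol(object@matrix),
      "reactions (seed", object@seed, ")\n")
  invisible(object)
})

setMethod("show", "ConditionModel", function(object) {
  cat("ConditionModel (relaxation", object@relaxation, ")\n")
  cat("  NGAM:", if (is.na(object@ngam)) "not estimated" else
      paste(format(object@ngam, digits = 5), "mmol ATP/gDW/h"), "\n")
  print(object@fitReport, row.names = FALSE)
  invisible(object)
})

setMethod("show", "FluxAttribution", function(object) {
  cat("FluxAttribution\n  predicted RQ:",
      format(object@predictedRQ, digits = 4), "\n")
  cat("  NADPH sources:\n")
  s <- sort(object@nadphSources, decreasing = TRUE)
  for (nm in names(s)[s > 1e-3])
    cat(sprintf("    %-8s %5.1f%%\n", nm, 100 * s[nm]))
  cat("  pathway carbon fractions:\n")
  for (nm in names(object@pathwayCarbonFractions))
    cat(sprintf("    %-16s %5.1f%%\n", nm,
                100 * object@pathwayCarbonFractions[nm]))
  invisible(object)
})

#' @rdname FluxDistribution-class
#' @export
setMethod("fluxes", "FluxDistribution", function(x) x@fluxes)

#' @rdname FluxSample-class
#' @export
setMethod("fluxMatrix", "FluxSample", function(x) x@matrix)

#' Reaction flux bounds
#'
#' @param model a \code{\link{MetabolicModel}}.
#' @return data.frame with \code{id}, \code{lowerBound}, \code{upperBound}.
#' @export
bounds <- function(model) {
  model@reactions[, c("id", "lowerBound", "upperBound")]
}

#' Set flux bounds on one or more reactions
#'
#' @param model a \code{\link{MetabolicModel}}.
#' @param id reaction id(s).
#' @param lower,upper new bounds (recycled; \code{NA} leaves a bound
#'   unchanged).
#' @return The modified model.
#' @export
setBounds <- function(model, id, lower = NA, upper = NA) {
  i <- match(id, model@reactions$id)
  if (anyNA(i)) stop("unknown reaction id(s): ",
                     paste(id[is.na(i)], collapse = ", "))
  lower <- rep_len(lower, length(i))
  upper <- rep_len(upper, length(i))
  keep <- !is.na(lower)
  model@reactions$lowerBound[i[keep]] <- lower[keep]
  keep <- !is.na(upper)
  model@reactions$upperBound[i[keep]] <- upper[keep]
  validObject(model)
  model
}

#' Exchange reactions of a model
#'
#' A reaction is an exchange when it touches exactly one metabolite (a source
#' or sink across the system boundary).
#'
#' @param model a \code{\link{MetabolicModel}}.
#' @return Character vector of exchange reaction ids.
#' @export
exchangeReactions <- function(model) {
  touched <- Matrix::colSums(model@S != 0)
  model@reactions$id[touched == 1L]
}

#' Parse a Hill-notation chemical formula
#'
#' @param formula character vector of formulas such as \code{"C3H8O3"};
#'   \code{NA} or unparseable strings yield \code{NULL} entries.
#' @return A list of named integer vectors (element -> count), one per input.
#' @examples
#' parseFormula("C3H8O3")
#' @export
parseFormula <- function(formula) {
  lapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NULL)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (!length(toks) || sum(nchar(toks)) != nchar(f)) return(NULL)
    el <- sub("[0-9]*$", "", toks)
    ct <- sub("^[A-Z][a-z]?", "", toks)
    ct <- ifelse(nzchar(ct), as.integer(ct), 1L)
    if (anyNA(ct) || any(ct < 0)) return(NULL)
    tapply(ct, el, sum)[unique(el)]
  })
}

#' Carbon atoms per metabolite molecule
#'
#' @param model a \code{\link{MetabolicModel}}.
#' @param id optional metabolite id(s); default all metabolites.
#' @return Named integer vector of carbon counts (0 when the formula has no
#'   carbon; \code{NA} when the formula is absent or unparseable).
#' @examples
#' carbonCount(buildToyGEM(), "glyc")
#' @export
carbonCount <- function(model, id = NULL) {
  met <- model@metabolites
  if (!is.null(id)) {
    i <- match(id, met$id)
    if (anyNA(i)) stop("unknown metabolite id(s): ",
                       paste(id[is.na(i)], collapse = ", "))
    met <- met[i, , drop = FALSE]
  }
  parsed <- parseFormula(met$formula)
  out <- vapply(parsed, function(p) {
    if (is.null(p)) return(NA_integer_)
    c0 <- p["C"]
    if (is.na(c0)) 0L else as.integer(c0)
  }, integer(1))
  stats::setNames(out, met$id)
}

#' Elemental mass-balance check of internal reactions
#'
#' Checks conservation of the requested elements over all internal reactions.
#' Exchange reactions, the biomass equation and maintenance pseudo-reactions
#' (subsystem containing "maintenance" or "biomass") are excluded, since they
#' intentionally cross the elemental boundary. A reaction involving a
#' metabolite without a parseable formula is flagged \code{"unknown"} rather
#' than judged balanced or unbalanced.
#'
#' @param model a \code{\link{MetabolicModel}}.
#' @param elements elements to check; default carbon only (the toy model
#'   tracks C and N exactly but omits water/protons, so H and O are not
#'   conserved there).
#' @return data.frame with columns \code{reaction}, \code{element},
#'   \code{residual}, \code{status} ("unbalanced" or "unknown"); zero rows
#'   means every checked reaction is balanced.
#' @examples
#' nrow(checkMassBalance(buildToyGEM()))  # 0: carbon-balanced by construction
#' @export
checkMassBalance <- function(model, elements = "C") {
  rxn <- model@reactions
  ex <- exchangeReactions(model)
  pseudo <- grepl("maintenance|biomass", rxn$subsystem, ignore.case = TRUE)
  internal <- setdiff(rxn$id[!pseudo], c(ex, model@biomassId))
  parsed <- parseFormula(model@metabolites$formula)
  names(parsed) <- model@metabolites$id
  counts <- vapply(elements, function(e)
    vapply(parsed, function(p) {
      if (is.null(p)) return(NA_real_)
      v <- p[e]
      if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1)), numeric(length(parsed)))
  counts <- matrix(counts, nrow = length(parsed),
                   dimnames = list(names(parsed), elements))
  out <- list()
  for (r in internal) {
    coef <- model@S[, r]
    mets <- names(coef)[coef != 0]
    if (anyNA(counts[mets, , drop = FALSE])) {
      out[[r]] <- data.frame(reaction = r, element = NA_character_,
                             residual = NA_real_, status = "unknown")
      next
    }
    res <- as.numeric(coef[mets] %*% counts[mets, , drop = FALSE])
    bad <- abs(res) > 1e-9
    if (any(bad))
      out[[r]] <- data.frame(reaction = r, element = elements[bad],
                             residual = res[bad], status = "unbalanced")
  }
  if (!length(out))
    return(data.frame(reaction = character(), element = character(),
                      residual = numeric(), status = character()))
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}
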