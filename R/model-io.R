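#' Read a stoichiometric model
#'
#' Reads a model from the package's documented JSON dialect or from SBML
#' Level 3 with the fbc (flux balance constraints) package. The JSON dialect
#' is a flat object with \code{metabolites} (id, name, compartment, formula,
#' charge), \code{reactions} (id, name, lower_bound, upper_bound, subsystem,
#' stoichiometry as a metabolite-id to coefficient map), \code{biomass_reaction}
#' and \code{objective}. Gene associations in SBML are ignored.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"json"} or \code{"sbml"}.
#' @return A \code{\link{MetabolicModel}}.
#' @export
readGEM <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "json") readGEMJson(path) else readGEMSbml(path)
}

#' Write a stoichiometric model
#'
#' @param model a \code{\link{MetabolicModel}}.
#' @param path output file path.
#' @param format \code{"auto"} (by extension), \code{"json"} or \code{"sbml"}.
#' @return \code{path}, invisibly.
#' @export
writeGEM <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "json") writeGEMJson(model, path) else writeGEMSbml(model, path)
  invisible(path)
}

readGEMJson <- function(path) {
  j <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("malformed JSON model file: ",
                                         conditionMessage(e)))
  for (f in c("metabolites", "reactions", "biomass_reaction"))
    if (is.null(j[[f]])) stop("JSON model missing field '", f, "'")
  fld <- function(x, name, default = NA) {
    v <- x[[name]]
    if (is.null(v) || (is.atomic(v) && !length(v))) default else v
  }
  mets <- do.call(rbind, lapply(j$metabolites, function(m) {
    if (is.null(m$id)) stop("parse error in metabolites: entry missing id")
    data.frame(id = m$id, name = as.character(fld(m, "name", m$id)),
               compartment = as.character(fld(m, "compartment", "c")),
               formula = as.character(fld(m, "formula")),
               charge = as.integer(fld(m, "charge", 0L)))
  }))
  ids <- vapply(j$reactions, function(r) {
    if (is.null(r$id)) stop("parse error in reactions: entry missing id")
    r$id
  }, character(1))
  n <- length(ids)
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, ids))
  for (i in seq_len(n)) {
    s <- unlist(j$reactions[[i]]$stoichiometry)
    if (is.null(s) || !length(s))
      stop("parse error in reaction '", ids[i], "': empty stoichiometry")
    if (!all(names(s) %in% mets$id))
      stop("reaction '", ids[i], "' references unknown metabolite(s): ",
           paste(setdiff(names(s), mets$id), collapse = ", "))
    S[names(s), i] <- as.numeric(s)
  }
  rxn <- do.call(rbind, lapply(j$reactions, function(r) {
    data.frame(id = r$id, name = as.character(fld(r, "name", r$id)),
               lowerBound = as.numeric(fld(r, "lower_bound", -1000)),
               upperBound = as.numeric(fld(r, "upper_bound", 1000)),
               subsystem = as.character(fld(r, "subsystem", "")))
  }))
  if (!j$biomass_reaction %in% rxn$id)
    stop("validation error: biomass reaction '", j$biomass_reaction,
         "' not present in model")
  obj <- unlist(j$objective)
  MetabolicModel(mets, rxn, S, biomassId = j$biomass_reaction,
                 objective = if (length(obj)) obj else NULL)
}

writeGEMJson <- function(model, path) {
  rxn <- model@reactions
  sto <- lapply(seq_len(nrow(rxn)), function(i) {
    coef <- model@S[, i]
    as.list(coef[coef != 0])
  })
  out <- list(
    metabolites = model@metabolites,
    reactions = data.frame(id = rxn$id, name = rxn$name,
                           lower_bound = rxn$lowerBound,
                           upper_bound = rxn$upperBound,
                           subsystem = rxn$subsystem),
    biomass_reaction = model@biomassId,
    objective = as.list(model@objective)
  )
  out$reactions$stoichiometry <- sto
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(17),
                           na = "null", pretty = TRUE)
  writeLines(json, path)
}

# SBML Level 3 + fbc. XPath uses local-name() so namespace prefixes in the
# file do not matter.
readGEMSbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file: ",
                                           conditionMessage(e)))
  fbcns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  if (!length(sp)) stop("parse error: SBML file contains no species")
  attrOr <- function(nodes, attr, default) {
    v <- xml2::xml_attr(nodes, attr)
    ifelse(is.na(v), default, v)
  }
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = attrOr(sp, "name", xml2::xml_attr(sp, "id")),
    compartment = attrOr(sp, "compartment", "c"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = suppressWarnings(as.integer(attrOr(sp, "charge", "0"))))
  pars <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  parVal <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (!length(rx)) stop("parse error: SBML file contains no reactions")
  n <- length(rx)
  ids <- xml2::xml_attr(rx, "id")
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, ids))
  lb <- ub <- numeric(n)
  for (i in seq_len(n)) {
    node <- rx[[i]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']",
                      side))
      if (!length(refs)) next
      sids <- xml2::xml_attr(refs, "species")
      if (!all(sids %in% mets$id))
        stop("reaction '", ids[i], "' references unknown species: ",
             paste(setdiff(sids, mets$id), collapse = ", "))
      coef <- as.numeric(attrOr(refs, "stoichiometry", "1"))
      sgn <- if (side == "listOfReactants") -1 else 1
      for (k in seq_along(sids))
        S[sids[k], i] <- S[sids[k], i] + sgn * coef[k]
    }
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    lb[i] <- if (!is.na(lbp) && lbp %in% names(parVal)) parVal[lbp] else -1000
    ub[i] <- if (!is.na(ubp) && ubp %in% names(parVal)) parVal[ubp] else 1000
    rev <- xml2::xml_attr(node, "reversible")
    if (is.na(lbp) && identical(rev, "false") && lb[i] < 0) lb[i] <- 0
  }
  rxn <- data.frame(id = ids, name = attrOr(rx, "name", ids),
                    lowerBound = lb, upperBound = ub,
                    subsystem = attrOr(rx, "subsystem", ""))
  flux <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  objective <- NULL
  if (length(flux)) {
    oid <- xml2::xml_attr(flux, "reaction")
    objective <- stats::setNames(as.numeric(attrOr(flux, "coefficient", "1")),
                                 oid)
  }
  biomassId <- if (length(objective)) names(objective)[1] else {
    cand <- grep("biomass|growth", ids, ignore.case = TRUE, value = TRUE)
    if (length(cand)) cand[1] else
      stop("validation error: no biomass reaction identifiable ",
           "(no fbc objective and no reaction id matching 'biomass')")
  }
  MetabolicModel(mets, rxn, S, biomassId = biomassId, objective = objective)
}

writeGEMSbml <- function(model, path) {
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  rxn <- model@reactions
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>')
  for (cp in unique(model@metabolites$compartment))
    lines <- c(lines, sprintf('      <compartment id="%s" constant="true"/>', cp))
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model@metabolites))) {
    m <- model@metabolites[i, ]
    fattr <- if (!is.na(m$formula))
      sprintf(' fbc:chemicalFormula="%s"', m$formula) else ""
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"%s fbc:charge="%d"/>'),
      m$id, esc(m$name), m$compartment, fattr, m$charge))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (i in seq_len(nrow(rxn))) {
    lines <- c(lines, sprintf(
      '      <parameter id="lb_%s" value="%s" constant="true"/>',
      rxn$id[i], num(rxn$lowerBound[i])))
    lines <- c(lines, sprintf(
      '      <parameter id="ub_%s" value="%s" constant="true"/>',
      rxn$id[i], num(rxn$upperBound[i])))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(rxn))) {
    coef <- model@S[, i]
    reac <- coef[coef < 0]; prod <- coef[coef > 0]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">'),
      rxn$id[i], esc(rxn$name[i]),
      if (rxn$lowerBound[i] < 0) "true" else "false", rxn$id[i], rxn$id[i]))
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>')
      for (k in seq_along(reac))
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          names(reac)[k], num(-reac[k])))
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>')
      for (k in seq_along(prod))
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          names(prod)[k], num(prod[k])))
      lines <- c(lines, '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             '        <fbc:listOfFluxObjectives>')
  for (k in seq_along(model@objective))
    lines <- c(lines, sprintf(
      '          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%s"/>',
      names(model@objective)[k], num(model@objective[k])))
  lines <- c(lines, '        </fbc:listOfFluxObjectives>',
             '      </fbc:objective>', '    </fbc:listOfObjectives>',
             '  </model>', '</sbml>')
  writeLines(lines, path)
}
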