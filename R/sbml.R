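#' Write a metabolic model as SBML Level 3 (fbc version 2)
#'
#' Minimal but standard-conformant serialization: species, reactions with
#' stoichiometric speciesReferences, flux-bound parameters referenced
#' through the fbc attributes, and a maximization objective on the biomass
#' reaction. Tracked-exchange and crowding metadata are carried in
#' annotation elements so a round trip through [read_sbml()] is lossless.
#'
#' @param model a [metabolic_model()]
#' @param path output file
#' @return the path, invisibly
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '<model id="model" fbc:strict="true">',
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies>')
  for (m in rownames(model$S))
    lines <- c(lines, sprintf(
      '<species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(m)))
  lines <- c(lines, '</listOfSpecies>', '<listOfParameters>')
  for (r in colnames(model$S)) {
    lines <- c(lines,
      sprintf('<parameter id="lb_%s" value="%.17g" constant="true"/>', esc(r), model$lb[r]),
      sprintf('<parameter id="ub_%s" value="%.17g" constant="true"/>', esc(r), model$ub[r]))
  }
  lines <- c(lines, '</listOfParameters>', '<listOfReactions>')
  for (r in colnames(model$S)) {
    lines <- c(lines, sprintf(
      '<reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">',
      esc(r), tolower(model$lb[r] < 0), esc(r), esc(r)))
    col <- model$S[, r]
    rea <- names(col)[col < 0]; pro <- names(col)[col > 0]
    if (length(rea)) {
      lines <- c(lines, '<listOfReactants>',
                 sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                         esc(rea), -col[rea]),
                 '</listOfReactants>')
    }
    if (length(pro)) {
      lines <- c(lines, '<listOfProducts>',
                 sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                         esc(pro), col[pro]),
                 '</listOfProducts>')
    }
    lines <- c(lines, '</reaction>')
  }
  lines <- c(lines, '</listOfReactions>',
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    '<fbc:listOfFluxObjectives>',
    sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>', esc(model$objective)),
    '</fbc:listOfFluxObjectives>', '</fbc:objective>', '</fbc:listOfObjectives>',
    '<annotation><colonyFBA:meta xmlns:colonyFBA="https://colonyFBA/meta">',
    paste0('<colonyFBA:exchanges>',
           paste(names(model$exchanges), model$exchanges, sep = ":", collapse = ","),
           '</colonyFBA:exchanges>'))
  if (!is.null(model$crowding)) {
    nz <- model$crowding[model$crowding != 0]
    lines <- c(lines, paste0('<colonyFBA:crowding>',
                             paste(names(nz), nz, sep = ":", collapse = ","),
                             '</colonyFBA:crowding>'))
  }
  lines <- c(lines, '</colonyFBA:meta></annotation>', '</model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Read a metabolic model from SBML (Level 3, fbc)
#'
#' Parses species, reactions (with stoichiometry), fbc flux bounds and the
#' active maximization objective. Tracked-exchange annotations written by
#' [write_sbml()] are honored; otherwise exchange reactions must be
#' supplied through `exchanges`.
#'
#' @param path SBML file
#' @param exchanges optional named character vector (substrate -> reaction
#'   id) overriding or replacing the annotation
#' @return a [metabolic_model()]
#' @export
read_sbml <- function(path, exchanges = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- xml2::xml_attr(sp, "id")
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  lb <- ub <- stats::setNames(numeric(length(rxns)), rxns)
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    lb[i] <- pval[[xml2::xml_attr(r, "lowerFluxBound")]]
    ub[i] <- pval[[xml2::xml_attr(r, "upperFluxBound")]]
    rea <- xml2::xml_find_all(r, "./s:listOfReactants/s:speciesReference", ns)
    for (e in rea)
      S[xml2::xml_attr(e, "species"), i] <-
        S[xml2::xml_attr(e, "species"), i] - as.numeric(xml2::xml_attr(e, "stoichiometry"))
    pro <- xml2::xml_find_all(r, "./s:listOfProducts/s:speciesReference", ns)
    for (e in pro)
      S[xml2::xml_attr(e, "species"), i] <-
        S[xml2::xml_attr(e, "species"), i] + as.numeric(xml2::xml_attr(e, "stoichiometry"))
  }
  obj <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  objective <- xml2::xml_attr(obj, "reaction")
  parse_map <- function(txt) {
    if (is.na(txt) || !nzchar(txt)) return(NULL)
    kv <- strsplit(strsplit(txt, ",")[[1]], ":")
    stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  if (is.null(exchanges)) {
    ex_node <- xml2::xml_find_first(doc, ".//*[local-name()='exchanges']")
    exchanges <- parse_map(xml2::xml_text(ex_node))
    if (is.null(exchanges)) stop("no exchange annotation; supply `exchanges`")
  }
  cr_node <- xml2::xml_find_first(doc, ".//*[local-name()='crowding']")
  crowding <- NULL
  if (!inherits(cr_node, "xml_missing")) {
    cr <- parse_map(xml2::xml_text(cr_node))
    if (!is.null(cr)) crowding <- stats::setNames(as.numeric(cr), names(cr))
  }
  metabolic_model(S, lb, ub, objective, exchanges, crowding = crowding)
}
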