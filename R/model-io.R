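#' Read or write a metabolic model
#'
#' Two on-disk formats are supported.
#' \describe{
#'   \item{json}{A compact dialect mirroring the in-memory structure:
#'     \code{compartments}, \code{metabolites} (id/name/compartment),
#'     \code{reactions} (id, metabolites map, lower_bound, upper_bound,
#'     gene_reaction_rule, subsystem), \code{biomass}, \code{objective}.
#'     Write-then-read reproduces the model exactly.}
#'   \item{sbml}{SBML Level 3 Version 1 with the \code{fbc} version-2
#'     package for bounds, gene-product associations and objectives. The
#'     usual \code{M_}/\code{R_}/\code{G_} id prefixes are applied on write
#'     and stripped on read; subsystems travel in reaction notes
#'     (\code{SUBSYSTEM: ...}); the biomass reaction is recorded as a
#'     second, inactive \code{fbc} objective named \code{biomass}. Files
#'     without gene associations yield empty GPR trees.}
#' }
#'
#' @param path file path.
#' @param format \code{"json"} or \code{"sbml"} (default: from the file
#'   extension, \code{.xml}/\code{.sbml} meaning SBML).
#' @return [readModel()] returns a \linkS4class{MetabolicModel};
#'   [writeModel()] returns \code{path} invisibly.
#' @export
readModel <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") .readModelJson(path) else .readModelSbml(path)
}

#' @rdname readModel
#' @param model a \linkS4class{MetabolicModel}.
#' @export
writeModel <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "json") .writeModelJson(model, path)
  else .writeModelSbml(model, path)
  invisible(path)
}

.writeModelJson <- function(model, path) {
  rxn <- model@reactions
  S <- model@stoichiometry
  rx <- lapply(seq_len(nrow(rxn)), function(j) {
    s <- S[, j]
    s <- s[s != 0]
    list(id = rxn$id[j],
         metabolites = as.list(s),
         lower_bound = rxn$lower_bound[j],
         upper_bound = rxn$upper_bound[j],
         gene_reaction_rule = rxn$gpr[j],
         subsystem = rxn$subsystem[j])
  })
  out <- list(
    compartments = as.list(model@compartments),
    metabolites = lapply(seq_len(nrow(model@metabolites)), function(i)
      list(id = model@metabolites$id[i],
           name = model@metabolites$name[i],
           compartment = model@metabolites$compartment[i])),
    reactions = rx,
    biomass = model@biomassId,
    objective = model@objectiveId
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

.readModelJson <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON model file '",
                                           path, "': ", conditionMessage(e)))
  for (f in c("compartments", "metabolites", "reactions", "biomass",
              "objective"))
    if (is.null(raw[[f]]))
      stop("model file '", path, "' lacks required element '", f, "'")
  comps <- unlist(raw$compartments)
  met <- data.frame(
    id = vapply(raw$metabolites, `[[`, character(1), "id"),
    name = vapply(raw$metabolites, function(m)
      if (is.null(m$name)) m$id else m$name, character(1)),
    compartment = vapply(raw$metabolites, `[[`, character(1), "compartment"),
    stringsAsFactors = FALSE)
  rxn <- data.frame(
    id = vapply(raw$reactions, `[[`, character(1), "id"),
    lower_bound = vapply(raw$reactions, function(r)
      as.numeric(r$lower_bound), numeric(1)),
    upper_bound = vapply(raw$reactions, function(r)
      as.numeric(r$upper_bound), numeric(1)),
    gpr = vapply(raw$reactions, function(r)
      if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule,
      character(1)),
    subsystem = vapply(raw$reactions, function(r)
      if (is.null(r$subsystem)) "" else r$subsystem, character(1)),
    stringsAsFactors = FALSE)
  bad <- rxn$lower_bound > rxn$upper_bound
  if (any(bad))
    stop("model file '", path, "': lower_bound > upper_bound for reaction ",
         paste(rxn$id[bad], collapse = ", "))
  stoich <- lapply(raw$reactions, function(r)
    vapply(r$metabolites, as.numeric, numeric(1)))
  names(stoich) <- rxn$id
  metabolicModel(met, rxn, stoich, comps,
                 biomassId = raw$biomass, objectiveId = raw$objective)
}

## ---- SBML -----------------------------------------------------------------

.xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.gprToFbcXml <- function(tree, indent) {
  pad <- strrep(" ", indent)
  if (is.character(tree))
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                   pad, .xesc(tree)))
  tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
  inner <- vapply(tree$args, .gprToFbcXml, character(1), indent = indent + 2)
  paste0(pad, "<", tag, ">\n", paste(inner, collapse = "\n"),
         "\n", pad, "</", tag, ">")
}

.writeModelSbml <- function(model, path) {
  met <- model@metabolites
  rxn <- model@reactions
  S <- model@stoichiometry
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" name="%s" constant="true"/>',
            names(model@compartments), .xesc(model@compartments)),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="M_%s" name="%s" compartment="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"/>'),
            met$id, .xesc(met$name), met$compartment),
    '    </listOfSpecies>',
    '    <listOfParameters>',
    sprintf('      <parameter id="R_%s_lb" value="%s" constant="true"/>',
            rxn$id, format(rxn$lower_bound, digits = 17)),
    sprintf('      <parameter id="R_%s_ub" value="%s" constant="true"/>',
            rxn$id, format(rxn$upper_bound, digits = 17)),
    '    </listOfParameters>',
    '    <listOfReactions>')
  for (j in seq_len(nrow(rxn))) {
    s <- S[, j]; s <- s[s != 0]
    sub <- s[s < 0]; prod <- s[s > 0]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="R_%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="R_%s_lb" fbc:upperFluxBound="R_%s_ub">'),
      rxn$id[j], tolower(rxn$lower_bound[j] < 0), rxn$id[j], rxn$id[j]))
    if (nzchar(rxn$subsystem[j]))
      lines <- c(lines,
        '        <notes>',
        '          <body xmlns="http://www.w3.org/1999/xhtml">',
        sprintf('            <p>SUBSYSTEM: %s</p>', .xesc(rxn$subsystem[j])),
        '          </body>',
        '        </notes>')
    if (length(sub))
      lines <- c(lines, '        <listOfReactants>',
        sprintf(paste0('          <speciesReference species="M_%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                names(sub), format(-unname(sub), digits = 17)),
        '        </listOfReactants>')
    if (length(prod))
      lines <- c(lines, '        <listOfProducts>',
        sprintf(paste0('          <speciesReference species="M_%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                names(prod), format(unname(prod), digits = 17)),
        '        </listOfProducts>')
    tree <- model@gprs[[j]]
    if (!is.null(tree))
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 .gprToFbcXml(tree, 10), '        </fbc:geneProductAssociation>')
    lines <- c(lines, '      </reaction>')
  }
  genes <- geneIds(model)
  lines <- c(lines, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            model@objectiveId),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '      <fbc:objective fbc:id="biomass" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            model@biomassId),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>')
  if (length(genes))
    lines <- c(lines, '    <fbc:listOfGeneProducts>',
      sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
              genes, .xesc(genes)),
      '    </fbc:listOfGeneProducts>')
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
}

.lname <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

.fbcGprFromXml <- function(node) {
  ln <- xml2::xml_name(node)   # local name, prefix stripped by xml_name
  if (ln == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(sub("^G_", "", g))
  }
  kids <- xml2::xml_children(node)
  args <- lapply(kids, .fbcGprFromXml)
  list(op = if (ln == "and") "and" else "or", args = args)
}

.readModelSbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file '", path,
                                           "': ", conditionMessage(e)))
  comp_nodes <- .lname(doc, "compartment")
  comps <- stats::setNames(
    xml2::xml_attr(comp_nodes, "name"),
    xml2::xml_attr(comp_nodes, "id"))
  comps[is.na(comps)] <- names(comps)[is.na(comps)]
  sp <- .lname(doc, "species")
  met <- data.frame(
    id = sub("^M_", "", xml2::xml_attr(sp, "id")),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  met$name[is.na(met$name)] <- met$id[is.na(met$name)]
  pars <- .lname(doc, "parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rnodes <- .lname(doc, "reaction")
  if (!length(rnodes)) stop("SBML file '", path, "' contains no reactions")
  ids <- sub("^R_", "", xml2::xml_attr(rnodes, "id"))
  lb <- ub <- numeric(length(rnodes))
  gpr <- subsys <- character(length(rnodes))
  stoich <- vector("list", length(rnodes))
  for (j in seq_along(rnodes)) {
    node <- rnodes[[j]]
    lbid <- xml2::xml_attr(node, "lowerFluxBound")
    ubid <- xml2::xml_attr(node, "upperFluxBound")
    lb[j] <- if (!is.na(lbid) && lbid %in% names(parval)) parval[[lbid]]
             else -.FLUX_CAP
    ub[j] <- if (!is.na(ubid) && ubid %in% names(parval)) parval[[ubid]]
             else .FLUX_CAP
    notes <- xml2::xml_text(.lname(node, "p"))
    hit <- grep("^\\s*SUBSYSTEM:", notes, value = TRUE)
    subsys[j] <- if (length(hit)) trimws(sub("^\\s*SUBSYSTEM:\\s*", "", hit[1]))
                 else ""
    gpa <- .lname(node, "geneProductAssociation")
    gpr[j] <- if (length(gpa)) {
      gprToString(.fbcGprFromXml(xml2::xml_children(gpa[[1]])[[1]]))
    } else ""
    reac <- .lname(node, "listOfReactants")
    prod <- .lname(node, "listOfProducts")
    s <- numeric()
    if (length(reac)) {
      rr <- .lname(reac[[1]], "speciesReference")
      s <- c(s, stats::setNames(
        -as.numeric(xml2::xml_attr(rr, "stoichiometry")),
        sub("^M_", "", xml2::xml_attr(rr, "species"))))
    }
    if (length(prod)) {
      pp <- .lname(prod[[1]], "speciesReference")
      s <- c(s, stats::setNames(
        as.numeric(xml2::xml_attr(pp, "stoichiometry")),
        sub("^M_", "", xml2::xml_attr(pp, "species"))))
    }
    stoich[[j]] <- s
  }
  if (any(lb > ub))
    stop("SBML file '", path, "': lower bound above upper bound for ",
         paste(ids[lb > ub], collapse = ", "))
  names(stoich) <- ids
  objs <- .lname(doc, "objective")
  objectiveId <- biomassId <- NA_character_
  for (o in objs) {
    fo <- .lname(o, "fluxObjective")
    rid <- sub("^R_", "", xml2::xml_attr(fo[[1]], "reaction"))
    if (identical(xml2::xml_attr(o, "id"), "biomass")) biomassId <- rid
    else objectiveId <- rid
  }
  if (is.na(objectiveId))
    stop("SBML file '", path, "' declares no active objective")
  if (is.na(biomassId)) biomassId <- objectiveId
  rxn <- data.frame(id = ids, lower_bound = lb, upper_bound = ub,
                    gpr = gpr, subsystem = subsys, stringsAsFactors = FALSE)
  metabolicModel(met, rxn, stoich, comps,
                 biomassId = biomassId, objectiveId = objectiveId)
}
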