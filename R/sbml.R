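## SBML reading and writing on top of xml2.
##
## A deliberately small subset of SBML is supported: level 2 and level 3
## core (compartments, species with boundaryCondition, reactions with
## reactants/products and stoichiometries) plus the FBC v2 flux-bound and
## objective constructs, and identifiers.org annotations on species.
## Models are always written as level 3 version 1 + FBC v2 regardless of
## the input level.

.SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
.RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"

## identifiers.org collection -> source prefix used in chem_xref
.ANNOTATION_PREFIXES <- c(
  "chebi" = "chebi",
  "kegg.compound" = "keggC",
  "kegg.drug" = "keggD",
  "kegg.glycan" = "keggG",
  "bigg.metabolite" = "biggM",
  "seed.compound" = "seedM",
  "metacyc.compound" = "metacycM",
  "hmdb" = "hmdb",
  "lipidmaps" = "lipidmaps",
  "swisslipid" = "slm",
  "reactome" = "reactome",
  "sabiork.compound" = "sabiorkM",
  "envipath" = "envipath",
  "metanetx.chemical" = "mnx")

.sanitizeSId <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", x), x, paste0("x_", x))
}

.parseIdentifierUri <- function(uri) {
  m <- regmatches(uri, regexec("identifiers\\.org/([^/:]+)[:/](.+)$", uri))[[1]]
  if (length(m) == 0L) return(NULL)
  coll <- tolower(m[2]); id <- m[3]
  ## registry ids are sometimes namespaced twice (CHEBI:15377)
  id <- sub(paste0("(?i)^", coll, ":"), "", id, perl = TRUE)
  prefix <- .ANNOTATION_PREFIXES[coll]
  if (is.na(prefix)) prefix <- coll
  paste0(prefix, ":", id)
}

#' Read an SBML model (level 2 or level 3, FBC optional)
#'
#' Flux bounds come from FBC parameters, level 2 kinetic-law parameters
#' named `LOWER_BOUND`/`UPPER_BOUND`, or defaults from the `reversible`
#' flag (`[0, bigM]` irreversible, `[-bigM, bigM]` reversible);
#' non-finite bounds are clamped to `bigM`.  Species annotations are
#' parsed from identifiers.org URIs into `"prefix:id"` pairs.  A species
#' is boundary-flagged by `boundaryCondition="true"` or by living in a
#' compartment named `boundary` or `b`.
#'
#' @param path SBML file.
#' @param bigM bound magnitude substituted for missing/infinite bounds.
#' @return a [GsmnModel-class] object.
#' @export
readSbmlModel <- function(path, bigM = 1000) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("invalid SBML: ", conditionMessage(e)))
  root <- xml2::xml_find_first(doc, "/*[local-name()='sbml']")
  if (inherits(root, "xml_missing")) stop("invalid SBML: no <sbml> root in ", path)
  modelNode <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  level <- xml2::xml_attr(root, "level")
  modelId <- xml2::xml_attr(modelNode, "id")
  if (is.na(modelId)) modelId <- "model"

  comps <- xml2::xml_find_all(doc, "//*[local-name()='listOfCompartments']/*[local-name()='compartment']")
  compIds <- xml2::xml_attr(comps, "id")

  ## FBC parameter values for bound lookups
  params <- xml2::xml_find_all(doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  paramVal <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                              xml2::xml_attr(params, "id"))

  spNodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  spId <- xml2::xml_attr(spNodes, "id")
  spName <- xml2::xml_attr(spNodes, "name")
  spComp <- xml2::xml_attr(spNodes, "compartment")
  spBound <- xml2::xml_attr(spNodes, "boundaryCondition")
  spCharge <- xml2::xml_attr(spNodes, "charge")        # L2 only
  fbcCharge <- xml2::xml_attr(spNodes, "charge", ns = c(fbc = .FBC_NS))
  spFormula <- vapply(spNodes, function(nd) {
    at <- xml2::xml_attrs(nd)
    v <- at[grepl("chemicalFormula$", names(at))]
    if (length(v)) v[[1]] else NA_character_
  }, character(1))
  anns <- vapply(spNodes, function(nd) {
    lis <- xml2::xml_find_all(nd, ".//*[local-name()='li']")
    uris <- unlist(lapply(lis, function(li) {
      at <- xml2::xml_attrs(li)
      unname(at[grepl("resource$", names(at))])
    }))
    refs <- unlist(lapply(uris, .parseIdentifierUri))
    if (length(refs)) paste(unique(refs), collapse = ";") else ""
  }, character(1))
  chargeAttr <- vapply(seq_along(spNodes), function(i) {
    at <- xml2::xml_attrs(spNodes[[i]])
    v <- at[names(at) %in% c("charge", "fbc:charge") | grepl(":charge$", names(at))]
    if (length(v)) suppressWarnings(as.numeric(v[[1]])) else NA_real_
  }, numeric(1))
  species <- data.frame(
    id = spId,
    name = ifelse(is.na(spName), spId, spName),
    compartment = spComp,
    boundary = (!is.na(spBound) & spBound == "true") |
      spComp %in% c("boundary", "b"),
    formula = spFormula,
    charge = chargeAttr,
    annotations = anns,
    stringsAsFactors = FALSE)

  rxNodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  n <- length(rxNodes)
  rid <- xml2::xml_attr(rxNodes, "id")
  rname <- xml2::xml_attr(rxNodes, "name")
  revAttr <- xml2::xml_attr(rxNodes, "reversible")
  ## SBML L2 default for 'reversible' is true; L3 requires it
  reversible <- ifelse(is.na(revAttr), TRUE, revAttr == "true")
  lb <- ub <- numeric(n)
  equations <- vector("list", n)
  compOf <- stats::setNames(species$compartment, species$id)
  for (i in seq_len(n)) {
    nd <- rxNodes[[i]]
    side <- function(listName) {
      refs <- xml2::xml_find_all(nd, paste0(
        "./*[local-name()='", listName, "']/*[local-name()='speciesReference']"))
      if (!length(refs)) return(.emptyTerms())
      sp <- xml2::xml_attr(refs, "species")
      st <- xml2::xml_attr(refs, "stoichiometry")
      st[is.na(st)] <- "1"
      co <- lapply(st, .parseCoeff)
      data.frame(met = sp, num = vapply(co, `[[`, 0, "num"),
                 den = vapply(co, `[[`, 0, "den"),
                 comp = unname(compOf[sp]), stringsAsFactors = FALSE)
    }
    dir <- if (reversible[i]) "BIDIRECTIONAL" else "LR"
    equations[[i]] <- .newEquation(side("listOfReactants"),
                                   side("listOfProducts"), dir)
    ## bounds: FBC attributes first, then L2 kinetic-law parameters
    at <- xml2::xml_attrs(nd)
    lbRef <- at[grepl("lowerFluxBound$", names(at))]
    ubRef <- at[grepl("upperFluxBound$", names(at))]
    lbv <- if (length(lbRef)) paramVal[[lbRef[[1]]]] else NA_real_
    ubv <- if (length(ubRef)) paramVal[[ubRef[[1]]]] else NA_real_
    if (is.na(lbv) || is.na(ubv)) {
      klp <- xml2::xml_find_all(nd, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
      if (length(klp)) {
        kid <- xml2::xml_attr(klp, "id")
        kval <- as.numeric(xml2::xml_attr(klp, "value"))
        if (is.na(lbv) && "LOWER_BOUND" %in% kid)
          lbv <- kval[match("LOWER_BOUND", kid)]
        if (is.na(ubv) && "UPPER_BOUND" %in% kid)
          ubv <- kval[match("UPPER_BOUND", kid)]
      }
    }
    if (is.na(lbv)) lbv <- if (reversible[i]) -bigM else 0
    if (is.na(ubv)) ubv <- bigM
    lb[i] <- max(lbv, -bigM); ub[i] <- min(ubv, bigM)
  }
  objNode <- xml2::xml_find_first(doc, "//*[local-name()='fluxObjective']")
  objective <- if (inherits(objNode, "xml_missing")) character(0) else {
    at <- xml2::xml_attrs(objNode)
    v <- at[grepl("reaction$", names(at))]
    if (length(v)) v[[1]] else character(0)
  }
  new("GsmnModel", modelId = modelId, compartments = compIds,
      species = species,
      reactions = data.frame(id = rid,
                             name = ifelse(is.na(rname), rid, rname),
                             lb = lb, ub = ub, reversible = reversible,
                             stringsAsFactors = FALSE),
      equations = equations, objective = objective)
}

#' Write a model as SBML level 3 + FBC v2
#'
#' @param model a [GsmnModel-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSbmlModel <- function(model, path) {
  stopifnot(is(model, "GsmnModel"))
  doc <- xml2::xml_new_root("sbml",
    xmlns = .SBML_L3_NS, "xmlns:fbc" = .FBC_NS, "xmlns:rdf" = .RDF_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = .sanitizeSId(model@modelId),
                             "fbc:strict" = "true")
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in model@compartments)
    xml2::xml_add_child(loc, "compartment", id = .sanitizeSId(cid),
                        constant = "true")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  sp <- model@species
  for (i in seq_len(nrow(sp))) {
    nd <- xml2::xml_add_child(los, "species",
      id = .sanitizeSId(sp$id[i]), name = sp$name[i],
      compartment = .sanitizeSId(sp$compartment[i]),
      hasOnlySubstanceUnits = "false",
      boundaryCondition = tolower(as.character(sp$boundary[i])),
      constant = "false")
    if (!is.na(sp$charge[i]))
      xml2::xml_set_attr(nd, "fbc:charge", format(sp$charge[i], scientific = FALSE))
    if (!is.na(sp$formula[i]))
      xml2::xml_set_attr(nd, "fbc:chemicalFormula", sp$formula[i])
    if (nzchar(sp$annotations[i])) {
      ann <- xml2::xml_add_child(nd, "annotation")
      bag <- xml2::xml_add_child(ann, "rdf:Bag")
      for (ref in strsplit(sp$annotations[i], ";", fixed = TRUE)[[1]]) {
        prefix <- sub(":.*$", "", ref); id <- sub("^[^:]*:", "", ref)
        coll <- names(.ANNOTATION_PREFIXES)[match(prefix, .ANNOTATION_PREFIXES)]
        if (is.na(coll)) coll <- prefix
        li <- xml2::xml_add_child(bag, "rdf:li")
        xml2::xml_set_attr(li, "rdf:resource",
                           paste0("https://identifiers.org/", coll, ":", id))
      }
    }
  }
  ## shared bound parameters
  rx <- model@reactions
  bounds <- sort(unique(c(rx$lb, rx$ub)))
  pid <- stats::setNames(paste0("bnd_", seq_along(bounds)),
                        vapply(bounds, function(b) format(b, digits = 15), ""))
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (b in bounds)
    xml2::xml_add_child(lop, "parameter", id = pid[[format(b, digits = 15)]],
                        value = format(b, digits = 15), constant = "true")
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(rx))) {
    eq <- model@equations[[i]]
    nd <- xml2::xml_add_child(lor, "reaction",
      id = .sanitizeSId(rx$id[i]), name = rx$name[i],
      reversible = tolower(as.character(rx$lb[i] < 0)),
      fast = "false")
    xml2::xml_set_attr(nd, "fbc:lowerFluxBound", pid[[format(rx$lb[i], digits = 15)]])
    xml2::xml_set_attr(nd, "fbc:upperFluxBound", pid[[format(rx$ub[i], digits = 15)]])
    writeSide <- function(terms, listName) {
      if (nrow(terms) == 0L) return(invisible(NULL))
      ls <- xml2::xml_add_child(nd, listName)
      for (k in seq_len(nrow(terms)))
        xml2::xml_add_child(ls, "speciesReference",
          species = .sanitizeSId(terms$met[k]),
          stoichiometry = format(terms$num[k] / terms$den[k], digits = 15),
          constant = "true")
    }
    writeSide(eq$left, "listOfReactants")
    writeSide(eq$right, "listOfProducts")
  }
  if (length(model@objective)) {
    loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = .sanitizeSId(model@objective[1]),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
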