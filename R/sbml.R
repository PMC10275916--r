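## SBML Level 3 Version 1 + FBC Version 2 input/output, built on xml2.
## Covers the FBC subset a constraint-based model needs: species with
## formula/charge, reactions with flux-bound parameters and gene-product
## associations, the maximisation objective, and provenance notes.  Model,
## bound and GPR content round-trips structurally.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

num_attr <- function(x) sprintf("%.17g", x)

sanitize_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Write a GENRE to SBML (Level 3, FBC v2)
#'
#' Flux bounds become shared constant parameters, GPR rules become
#' gene-product associations, and each reaction's provenance (\code{source},
#' gap-fill step notes) is stored in its notes body so that audit
#' information survives the round trip.
#'
#' @param model a valid \code{genre} with at least one reaction.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_genre(model)
  if (!length(model$reactions)) stop("refusing to write a model with no reactions")

  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
                            level = "3", version = "1",
                            "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sanitize_sid(model$id),
                             name = model$id, "fbc:strict" = "true")

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (comp in names(model$compartments))
    xml2::xml_add_child(lc, "compartment", id = comp,
                        name = model$compartments[[comp]], constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (met in model$metabolites) {
    sp <- xml2::xml_add_child(ls, "species", id = met$id, name = met$name,
                              compartment = met$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(met$charge))
      xml2::xml_set_attr(sp, "fbc:charge", as.character(met$charge))
    if (!is.na(met$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", met$formula)
  }

  ## shared flux-bound parameters, one per distinct value
  bnd <- reaction_bounds(model)
  vals <- sort(unique(c(bnd$lb, bnd$ub)))
  pid <- stats::setNames(paste0("fb_", seq_along(vals)), num_attr(vals))
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in vals)
    xml2::xml_add_child(lp, "parameter", id = pid[[num_attr(v)]],
                        value = num_attr(v), constant = "true")

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (rxn in model$reactions) {
    rx <- xml2::xml_add_child(lr, "reaction", id = rxn$id, name = rxn$name,
                              reversible = if (rxn$lb < 0) "true" else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = pid[[num_attr(rxn$lb)]],
                              "fbc:upperFluxBound" = pid[[num_attr(rxn$ub)]])
    notes <- xml2::xml_add_child(rx, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
    xml2::xml_add_child(body, "p", paste0("source:", rxn$source))
    for (note in rxn$notes) xml2::xml_add_child(body, "p", note)
    gpr_tree <- parse_gpr(rxn$gpr)
    if (!is.null(gpr_tree)) {
      ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_assoc <- function(parent, node) {
        if (node$op == "gene") {
          xml2::xml_add_child(parent, "fbc:geneProductRef",
                              "fbc:geneProduct" = paste0("G_",
                                                         sanitize_sid(node$id)))
        } else {
          el <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
          for (a in node$args) add_assoc(el, a)
        }
      }
      add_assoc(ga, gpr_tree)
    }
    reac <- rxn$stoich[rxn$stoich < 0]
    prod <- rxn$stoich[rxn$stoich > 0]
    if (length(reac)) {
      el <- xml2::xml_add_child(rx, "listOfReactants")
      for (mid in names(reac))
        xml2::xml_add_child(el, "speciesReference", species = mid,
                            stoichiometry = num_attr(-reac[[mid]]),
                            constant = "true")
    }
    if (length(prod)) {
      el <- xml2::xml_add_child(rx, "listOfProducts")
      for (mid in names(prod))
        xml2::xml_add_child(el, "speciesReference", species = mid,
                            stoichiometry = num_attr(prod[[mid]]),
                            constant = "true")
    }
  }

  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective", "fbc:reaction" = model$objective,
                      "fbc:coefficient" = "1")

  genes <- genre_genes(model)
  if (length(genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sanitize_sid(g)),
                          "fbc:label" = g)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GENRE from SBML (Level 3, FBC v2)
#'
#' Inverse of \code{\link{write_sbml}}.  A warning is raised when ids do not
#' follow the expected ModelSEED-style namespace (cpd/rxn/EX_/biomass); a
#' missing FBC objective is a hard error.
#'
#' @param path SBML file path.
#' @param id model id (defaults to the SBML model id).
#' @return a \code{genre}.
#' @export
read_sbml <- function(path, id = NULL) {
  doc <- xml2::xml_root(xml2::read_xml(path))
  ## namespace-agnostic queries: xml_ns_strip leaves element XPath tied to
  ## the old namespaces, so match on local-name() instead
  xp <- function(...) paste0(vapply(c(...), function(n)
    sprintf("*[local-name()='%s']", n), ""), collapse = "/")
  xml2::xml_ns_strip(doc)  # makes fbc: attributes readable by bare name
  mdl <- xml2::xml_find_first(doc, paste0("./", xp("model")))
  if (inherits(mdl, "xml_missing")) stop("not an SBML file: no <model> in ", path)

  gp_label <- character()
  for (gp in xml2::xml_find_all(mdl, paste0(".//", xp("geneProduct")))) {
    gid <- xml2::xml_attr(gp, "id")
    gp_label[[gid]] <- xml2::xml_attr(gp, "label") %||na% gid
  }

  param <- numeric()
  for (p in xml2::xml_find_all(mdl, paste0("./", xp("listOfParameters", "parameter"))))
    param[[xml2::xml_attr(p, "id")]] <- as.numeric(xml2::xml_attr(p, "value"))

  mets <- lapply(xml2::xml_find_all(mdl, paste0("./", xp("listOfSpecies", "species"))),
                 function(sp) {
    metabolite(xml2::xml_attr(sp, "id"),
               name = xml2::xml_attr(sp, "name") %||na%
                 xml2::xml_attr(sp, "id"),
               formula = xml2::xml_attr(sp, "chemicalFormula") %||na%
                 NA_character_,
               charge = {
                 ch <- xml2::xml_attr(sp, "charge")
                 if (is.na(ch)) NA_integer_ else as.integer(ch)
               })
  })

  render_gpr <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      return(gp_label[[gid]] %||% gid)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, function(k) {
      s <- render_gpr(k)
      if (nm == "and" && xml2::xml_name(k) == "or") paste0("(", s, ")") else s
    }, "")
    paste(parts, collapse = paste0(" ", nm, " "))
  }

  rxns <- lapply(xml2::xml_find_all(mdl, paste0("./", xp("listOfReactions", "reaction"))),
                 function(rx) {
    rid <- xml2::xml_attr(rx, "id")
    sto <- numeric()
    for (sr in xml2::xml_find_all(rx, paste0("./", xp("listOfReactants", "speciesReference"))))
      sto[[xml2::xml_attr(sr, "species")]] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(rx, paste0("./", xp("listOfProducts", "speciesReference")))) {
      sp <- xml2::xml_attr(sr, "species")
      prev <- if (sp %in% names(sto)) sto[[sp]] else 0
      sto[[sp]] <- prev + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lbp <- xml2::xml_attr(rx, "lowerFluxBound")
    ubp <- xml2::xml_attr(rx, "upperFluxBound")
    notes <- xml2::xml_text(xml2::xml_find_all(rx, paste0("./", xp("notes", "body", "p"))))
    src <- sub("^source:", "", grep("^source:", notes, value = TRUE)[1])
    if (is.na(src)) src <- "imported"
    other <- notes[!grepl("^source:", notes)]
    ga <- xml2::xml_find_first(rx, paste0("./", xp("geneProductAssociation")))
    gpr <- if (inherits(ga, "xml_missing")) "" else
      render_gpr(xml2::xml_child(ga))
    reaction(rid, sto, name = xml2::xml_attr(rx, "name") %||na% rid,
             lb = if (is.na(lbp)) -1000 else param[[lbp]],
             ub = if (is.na(ubp)) 1000 else param[[ubp]],
             gpr = gpr, source = src, notes = other)
  })

  fo <- xml2::xml_find_first(mdl, paste0(".//", xp("fluxObjective")))
  if (inherits(fo, "xml_missing"))
    stop("SBML file ", path, " declares no FBC flux objective")
  objective <- xml2::xml_attr(fo, "reaction")

  rids <- vapply(rxns, `[[`, "", "id")
  mids <- vapply(mets, `[[`, "", "id")
  odd <- c(mids[!grepl("^cpd", mids)],
           rids[!grepl("^(rxn|EX_|TR_|biomass)", rids)])
  if (length(odd))
    warning("ids outside the expected cpd/rxn namespace: ",
            paste(utils::head(odd, 5), collapse = ", "),
            if (length(odd) > 5) " ..." else "")

  model_id <- id %||% (xml2::xml_attr(mdl, "name") %||na%
                         xml2::xml_attr(mdl, "id"))
  genre(model_id, mets, rxns, objective = objective)
}

`%||na%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a

#' Annotate a model from name/cross-reference dictionaries
#'
#' @param model a \code{genre}.
#' @param dictionaries list with optional named-character elements
#'   \code{metabolites}, \code{reactions} (id -> display name) and optional
#'   \code{cross_refs} (id -> external reference string).
#' @return the annotated model; ids absent from the dictionaries are left
#'   bare and counted in attribute \code{"n_unannotated"}.
#' @export
annotate_model <- function(model, dictionaries) {
  missing <- 0L
  mdict <- dictionaries$metabolites
  for (mid in names(model$metabolites)) {
    if (!is.null(mdict) && mid %in% names(mdict))
      model$metabolites[[mid]]$name <- unname(mdict[[mid]])
    else missing <- missing + 1L
  }
  rdict <- dictionaries$reactions
  for (rid in names(model$reactions)) {
    if (!is.null(rdict) && rid %in% names(rdict))
      model$reactions[[rid]]$name <- unname(rdict[[rid]])
    else missing <- missing + 1L
  }
  xr <- dictionaries$cross_refs
  if (!is.null(xr))
    for (id in intersect(names(xr), c(names(model$metabolites),
                                      names(model$reactions))))
      model$annotations[[id]] <- unname(xr[[id]])
  attr(model, "n_unannotated") <- missing
  model
}
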