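## Core containers: metabolites, reactions, GENRE models.
##
## Records follow the ModelSEED-style namespace: metabolite ids look like
## "cpd#####_c"/"cpd#####_e" (suffix = compartment), reaction ids like
## "rxn#####_c", exchange reactions "EX_<cpd>_e", and the growth objective
## "biomass".  Containers are plain named lists behind light S3 classes, in
## the style of ape's phylo: cheap to build in fixtures, easy to inspect.

## Locale-independent id ordering: models must serialise identically no
## matter the session's collation locale.
id_order <- function(x) order(x, method = "radix")
sort_ids <- function(x) x[id_order(x)]

#' Construct a metabolite record
#'
#' @param id namespaced id ending in "_c" (cytosol) or "_e" (extracellular).
#' @param name human-readable name.
#' @param formula flat elemental formula string (e.g. "C6H12O6") or NA.
#' @param charge integer formal charge or NA.
#' @return a \code{metabolite} record.
#' @export
metabolite <- function(id, name = id, formula = NA_character_,
                       charge = NA_integer_) {
  comp <- metabolite_compartment(id)
  if (is.na(comp))
    stop("metabolite id must end in '_c' or '_e': ", id)
  structure(list(id = id, name = name,
                 formula = if (is.null(formula)) NA_character_ else as.character(formula),
                 charge = if (is.null(charge) || is.na(charge)) NA_integer_ else as.integer(charge),
                 compartment = comp),
            class = "metabolite")
}

metabolite_compartment <- function(id) {
  m <- regmatches(id, regexpr("_[ce]$", id))
  if (!length(m) || m == "") NA_character_ else substring(m, 2)
}

#' Construct a reaction record
#'
#' @param id reaction id ("rxn#####_c", "EX_cpd#####_e" or "biomass").
#' @param stoich named numeric vector of nonzero stoichiometric coefficients
#'   (names are metabolite ids; negative = consumed).
#' @param name human-readable name.
#' @param lb,ub flux bounds in mmol/gDW/h.
#' @param gpr gene-protein-reaction boolean rule ("" when none).
#' @param source provenance tag, one of gene_annotated, gapfilled, exchange,
#'   biomass, media_added, imported.
#' @param notes character vector of free-text notes (e.g. gap-fill step).
#' @return a \code{reaction} record.
#' @export
reaction <- function(id, stoich, name = id, lb = -1000, ub = 1000, gpr = "",
                     source = "imported", notes = character()) {
  stopifnot(length(lb) == 1L, length(ub) == 1L)
  if (lb > ub) stop("reaction ", id, ": lower bound exceeds upper bound")
  stoich <- stoich[stoich != 0]
  if (!length(stoich) || is.null(names(stoich)) || any(names(stoich) == ""))
    stop("reaction ", id, ": stoichiometry must be a named nonzero vector")
  storage.mode(stoich) <- "double"  # JSON/TSV readers must round-trip
  src <- match.arg(source, c("gene_annotated", "gapfilled", "exchange",
                             "biomass", "media_added", "imported"))
  structure(list(id = id, name = name, stoich = stoich,
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 gpr = as.character(gpr), source = src, notes = notes),
            class = "reaction")
}

is_exchange <- function(rxn) {
  rxn$source == "exchange" || grepl("^EX_", rxn$id)
}

#' Construct a GENRE (genome-scale network reconstruction)
#'
#' @param id model identifier.
#' @param metabolites list of \code{metabolite} records.
#' @param reactions list of \code{reaction} records.
#' @param objective id of the objective (biomass) reaction.
#' @param annotations named list of external cross-references per id.
#' @return a \code{genre} object; components are kept sorted by id so that
#'   structurally equal models compare identical.
#' @export
genre <- function(id, metabolites, reactions, objective = "biomass",
                  annotations = list()) {
  names(metabolites) <- vapply(metabolites, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(id = id,
                      metabolites = metabolites[id_order(names(metabolites))],
                      reactions = reactions[id_order(names(reactions))],
                      objective = objective,
                      compartments = c(c = "cytosol", e = "extracellular"),
                      annotations = annotations),
                 class = "genre")
  validate_genre(m)
  m
}

#' Validate GENRE invariants
#'
#' Checks that the objective exists, every referenced metabolite is present,
#' compartment suffixes agree, and bounds are ordered. Called by the
#' constructor; exported for use after manual surgery on a model.
#' @param model a \code{genre}.
#' @return the model, invisibly; errors describe the first violation.
#' @export
validate_genre <- function(model) {
  if (!model$objective %in% names(model$reactions))
    stop("objective reaction '", model$objective, "' is not in the model")
  met_ids <- names(model$metabolites)
  for (met in model$metabolites)
    if (!identical(met$compartment, metabolite_compartment(met$id)))
      stop("metabolite ", met$id, ": compartment field disagrees with id suffix")
  for (rxn in model$reactions) {
    missing <- setdiff(names(rxn$stoich), met_ids)
    if (length(missing))
      stop("reaction ", rxn$id, " references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
    if (rxn$lb > rxn$ub)
      stop("reaction ", rxn$id, ": lower bound exceeds upper bound")
  }
  invisible(model)
}

#' Gene ids of a model
#'
#' The gene set is derived, not stored: the union of gene ids over all GPR
#' rules, so it can never drift out of step with the reactions.
#' @param model a \code{genre}.
#' @return sorted character vector of gene ids.
#' @export
genre_genes <- function(model) {
  g <- unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr)),
              use.names = FALSE)
  sort_ids(unique(g))
}

#' Stoichiometric matrix of a model
#'
#' @param model a \code{genre}.
#' @return sparse Matrix with one row per metabolite, one column per reaction.
#' @export
stoich_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(model$reactions)) {
    s <- model$reactions[[k]]$stoich
    i <- c(i, match(names(s), met_ids))
    j <- c(j, rep.int(k, length(s)))
    x <- c(x, unname(s))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

reaction_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, 0, "lb"),
       ub = vapply(model$reactions, `[[`, 0, "ub"))
}

#' Model statistics snapshot
#'
#' @param model a \code{genre}.
#' @return named list: counts of genes, reactions and metabolites, plus
#'   per-source reaction counts.
#' @export
model_stats <- function(model) {
  src <- vapply(model$reactions, `[[`, "", "source")
  list(genes = length(genre_genes(model)),
       reactions = length(model$reactions),
       metabolites = length(model$metabolites),
       by_source = as.list(table(src)))
}

#' @export
print.genre <- function(x, ...) {
  st <- model_stats(x)
  cat("GENRE '", x$id, "': ", st$reactions, " reactions, ", st$metabolites,
      " metabolites, ", st$genes, " genes; objective: ", x$objective, "\n",
      sep = "")
  invisible(x)
}

#' @export
print.reaction <- function(x, ...) {
  lhs <- x$stoich[x$stoich < 0]; rhs <- x$stoich[x$stoich > 0]
  fmt <- function(s, sgn) paste(paste0(ifelse(abs(s) == 1, "", paste0(abs(s), " ")),
                                       names(s)), collapse = " + ")
  arrow <- if (x$lb < 0 && x$ub > 0) "<=>" else "-->"
  cat(x$id, ": ", fmt(lhs), " ", arrow, " ", fmt(rhs),
      "  [", x$lb, ", ", x$ub, "]",
      if (nzchar(x$gpr)) paste0("  (", x$gpr, ")") else "", "\n", sep = "")
  invisible(x)
}
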