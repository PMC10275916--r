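## Universal reaction database: the curated pool of candidate biochemistry
## from which drafts draw gene-associated reactions and the gap-filler draws
## completions.  Curation removes mass/charge-unbalanced reactions, adds the
## exchange reactions every extracellular metabolite needs, and installs the
## biomass template as the growth objective.

#' Construct a universal database
#'
#' @param metabolites list of \code{metabolite} records.
#' @param reactions list of \code{reaction} records.
#' @param biomass_template a \code{reaction} with \code{source = "biomass"}
#'   installed as reaction "biomass" at curation.
#' @param provenance free-text version note.
#' @return a \code{universal_db}.
#' @export
universal_db <- function(metabolites, reactions, biomass_template,
                         provenance = "unspecified") {
  names(metabolites) <- vapply(metabolites, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (!identical(biomass_template$source, "biomass"))
    stop("biomass_template must have source = 'biomass'")
  structure(list(metabolites = metabolites[id_order(names(metabolites))],
                 reactions = reactions[id_order(names(reactions))],
                 biomass_template = biomass_template,
                 provenance = provenance),
            class = "universal_db")
}

#' @export
print.universal_db <- function(x, ...) {
  cat("Universal database (", x$provenance, "): ", length(x$reactions),
      " reactions, ", length(x$metabolites), " metabolites\n", sep = "")
  invisible(x)
}

#' Parse a flat elemental formula
#'
#' Accepts formulas made of (ElementSymbol)(optional count) tokens, e.g.
#' "C6H12O6".  Anything containing characters outside [A-Za-z0-9] — grouping
#' parentheses, "*" wildcards — is reported as undetermined rather than
#' guessed at.  Pseudo-element symbols such as "R" that fit the token grammar
#' are counted as ordinary elements, so dangling generic groups must cancel
#' across a reaction like any other atom.
#'
#' @param formula formula string.
#' @return named integer vector of element counts, or \code{NULL} when the
#'   formula is missing or unparseable (undetermined). Never errors.
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L || is.na(formula) || !nzchar(formula)) return(NULL)
  if (grepl("[^A-Za-z0-9]", formula)) return(NULL)
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(formula)) return(NULL)
  elem <- sub("[0-9]*$", "", parts)
  cnt <- sub("^[A-Z][a-z]?", "", parts)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  if (anyNA(cnt) || any(cnt <= 0L)) return(NULL)
  counts <- tapply(cnt, elem, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Check the elemental and charge balance of one reaction
#'
#' Sums coefficient-weighted element counts and charges over all
#' participants; the verdict is "balanced" only when every element delta and
#' the charge delta (when all charges are known) is exactly zero.  Exchange,
#' biomass and demand-style boundary reactions are unbalanced by construction
#' and are exempt, recorded as "balanced" with an exemption note, as are
#' transports moving one species between compartments unchanged.
#'
#' @param rxn a \code{reaction}.
#' @param db a \code{universal_db} (or \code{genre}) resolving the
#'   metabolite ids in \code{rxn$stoich}.
#' @param check_charge also require charge balance when all charges known.
#' @return list: \code{id}, \code{verdict} in {balanced, unbalanced,
#'   undetermined}, \code{deltas} (named numeric, product minus substrate),
#'   \code{charge_delta}, \code{exempt} flag.
#' @export
check_balance <- function(rxn, db, check_charge = TRUE) {
  mets <- db$metabolites
  missing <- setdiff(names(rxn$stoich), names(mets))
  if (length(missing))
    stop("reaction ", rxn$id, ": unresolvable metabolite id(s): ",
         paste(missing, collapse = ", "))
  if (is_exchange(rxn) || rxn$source == "biomass" || rxn$id == "biomass")
    return(list(id = rxn$id, verdict = "balanced", deltas = numeric(0),
                charge_delta = 0, exempt = TRUE))
  ## transport of identical species between compartments: all participants
  ## share one base compound id and coefficients cancel
  base <- sub("_[ce]$", "", names(rxn$stoich))
  if (length(unique(base)) == 1L && sum(rxn$stoich) == 0)
    return(list(id = rxn$id, verdict = "balanced", deltas = numeric(0),
                charge_delta = 0, exempt = TRUE))

  deltas <- numeric(0)
  undetermined <- FALSE
  for (mid in names(rxn$stoich)) {
    counts <- parse_formula(mets[[mid]]$formula)
    if (is.null(counts)) { undetermined <- TRUE; break }
    for (el in names(counts)) {
      cur <- if (el %in% names(deltas)) deltas[[el]] else 0
      deltas[[el]] <- cur + rxn$stoich[[mid]] * counts[[el]]
    }
  }
  if (undetermined)
    return(list(id = rxn$id, verdict = "undetermined", deltas = numeric(0),
                charge_delta = NA_real_, exempt = FALSE))
  deltas <- deltas[deltas != 0]
  charges <- vapply(names(rxn$stoich), function(mid) {
    ch <- mets[[mid]]$charge
    if (is.null(ch)) NA_real_ else as.numeric(ch)
  }, 0)
  charge_delta <- if (anyNA(charges)) NA_real_ else sum(rxn$stoich * charges)
  mass_bad <- length(deltas) > 0
  charge_bad <- check_charge && !is.na(charge_delta) && charge_delta != 0
  verdict <- if (mass_bad || charge_bad) "unbalanced" else "balanced"
  list(id = rxn$id, verdict = verdict, deltas = deltas,
       charge_delta = charge_delta, exempt = FALSE)
}

#' Balance report for a whole database
#'
#' @param db a \code{universal_db}.
#' @param check_charge passed to \code{\link{check_balance}}.
#' @return a \code{balance_report}: data.frame with reaction_id, verdict,
#'   deltas (element:delta;... string), charge_delta, exempt.
#' @export
balance_report <- function(db, check_charge = TRUE) {
  rows <- lapply(db$reactions, function(r) {
    b <- check_balance(r, db, check_charge = check_charge)
    data.frame(reaction_id = b$id, verdict = b$verdict,
               deltas = paste(sprintf("%s:%g", names(b$deltas), b$deltas),
                              collapse = ";"),
               charge_delta = b$charge_delta, exempt = b$exempt,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(rep) <- c("balance_report", "data.frame")
  rep
}

#' Curate a universal database
#'
#' Three passes: (i) remove every reaction whose balance verdict is
#' "unbalanced" (undetermined reactions are retained but flagged in the
#' audit report); (ii) add an exchange reaction \code{EX_<cpd>_e} with
#' bounds (-1000, 1000) for every extracellular metabolite that lacks one;
#' (iii) install the biomass template as reaction "biomass".
#'
#' @param raw a \code{universal_db}.
#' @param check_charge remove charge-unbalanced reactions too (all charges
#'   known); set FALSE to curate on mass balance alone.
#' @return list: \code{db} (curated \code{universal_db}), \code{report}
#'   (the full \code{balance_report} for audit), \code{removed} (ids).
#' @export
curate_database <- function(raw, check_charge = TRUE) {
  rep <- balance_report(raw, check_charge = check_charge)
  removed <- rep$reaction_id[rep$verdict == "unbalanced"]
  reactions <- raw$reactions[setdiff(names(raw$reactions), removed)]
  reactions <- reactions[names(reactions) != "biomass"]

  ## every extracellular metabolite gets exactly one exchange reaction
  ext <- names(raw$metabolites)[vapply(raw$metabolites, `[[`, "",
                                       "compartment") == "e"]
  have_ex <- vapply(reactions, is_exchange, TRUE)
  ex_mets <- unlist(lapply(reactions[have_ex],
                           function(r) names(r$stoich)), use.names = FALSE)
  for (mid in setdiff(ext, ex_mets)) {
    ex_id <- paste0("EX_", mid)
    reactions[[ex_id]] <- reaction(ex_id, stats::setNames(-1, mid),
                                   name = paste("Exchange of", mid),
                                   lb = -1000, ub = 1000, source = "exchange")
  }

  bm <- raw$biomass_template
  bm$id <- "biomass"
  reactions[["biomass"]] <- bm
  if (length(reactions) == 0L)
    stop("curation removed every reaction; the database is unusable")
  prov <- if (grepl("\\[curated\\]$", raw$provenance)) raw$provenance else
    paste0(raw$provenance, " [curated]")
  db <- universal_db(raw$metabolites, reactions, raw$biomass_template,
                     provenance = prov)
  list(db = db, report = rep, removed = removed)
}

## ---- serialization ----

met_to_list <- function(m) {
  list(id = m$id, name = m$name,
       formula = if (is.na(m$formula)) NULL else m$formula,
       charge = if (is.na(m$charge)) NULL else m$charge)
}

rxn_to_list <- function(r) {
  list(id = r$id, name = r$name, stoichiometry = as.list(r$stoich),
       lower_bound = r$lb, upper_bound = r$ub, gpr = r$gpr,
       source = r$source, notes = as.list(r$notes))
}

rxn_from_list <- function(x) {
  reaction(x$id, stoich = unlist(x$stoichiometry),
           name = if (is.null(x$name)) x$id else x$name,
           lb = if (is.null(x$lower_bound)) -1000 else x$lower_bound,
           ub = if (is.null(x$upper_bound)) 1000 else x$upper_bound,
           gpr = if (is.null(x$gpr)) "" else x$gpr,
           source = if (is.null(x$source)) "imported" else x$source,
           notes = unlist(x$notes) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a universal database to JSON
#'
#' Layout mirrors the ModelSEED dictionary style: separate "metabolites",
#' "reactions" and "biomass" sections plus a provenance note.
#' @param db a \code{universal_db}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_universal_db <- function(db, path) {
  doc <- list(provenance = db$provenance,
              metabolites = lapply(unname(db$metabolites), met_to_list),
              reactions = lapply(unname(db$reactions), rxn_to_list),
              biomass = rxn_to_list(db$biomass_template))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a universal database from JSON
#'
#' @param path path written by \code{\link{write_universal_db}} (or
#'   hand-curated in the same schema).
#' @return a \code{universal_db}.
#' @export
read_universal_db <- function(path) {
  doc <- jsonlite::read_json(path)
  mets <- lapply(doc$metabolites, function(x)
    metabolite(x$id, name = x$name %||% x$id,
               formula = x$formula %||% NA_character_,
               charge = x$charge %||% NA_integer_))
  rxns <- lapply(doc$reactions, rxn_from_list)
  universal_db(mets, rxns, rxn_from_list(doc$biomass),
               provenance = doc$provenance %||% "unspecified")
}

#' Read a universal database from TSV dictionaries
#'
#' Two tab-separated dictionaries in the ModelSEED distribution style.  The
#' reaction dictionary encodes stoichiometry as "coeff:cpd_id;..." .
#'
#' @param reactions_path TSV with columns id, name, stoichiometry,
#'   lower_bound, upper_bound, gpr, source.
#' @param metabolites_path TSV with columns id, name, formula, charge.
#' @param biomass_id id of the dictionary row to use as biomass template.
#' @return a \code{universal_db}.
#' @export
read_universal_db_tsv <- function(reactions_path, metabolites_path,
                                  biomass_id = "biomass") {
  mt <- utils::read.delim(metabolites_path, stringsAsFactors = FALSE)
  rt <- utils::read.delim(reactions_path, stringsAsFactors = FALSE)
  mets <- lapply(seq_len(nrow(mt)), function(i)
    metabolite(mt$id[i], name = mt$name[i],
               formula = if (is.na(mt$formula[i]) || mt$formula[i] == "")
                 NA_character_ else mt$formula[i],
               charge = if ("charge" %in% names(mt)) mt$charge[i] else NA))
  parse_stoich <- function(s) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    stats::setNames(vapply(kv, function(p) as.numeric(p[1]), 0),
                    vapply(kv, function(p) p[2], ""))
  }
  rxns <- lapply(seq_len(nrow(rt)), function(i)
    reaction(rt$id[i], parse_stoich(rt$stoichiometry[i]), name = rt$name[i],
             lb = if ("lower_bound" %in% names(rt)) rt$lower_bound[i] else -1000,
             ub = if ("upper_bound" %in% names(rt)) rt$upper_bound[i] else 1000,
             gpr = if ("gpr" %in% names(rt)) rt$gpr[i] else "",
             source = if ("source" %in% names(rt)) rt$source[i] else "imported"))
  names(rxns) <- rt$id
  if (!biomass_id %in% rt$id)
    stop("biomass template '", biomass_id, "' not found in reaction dictionary")
  bm <- rxns[[biomass_id]]
  bm$source <- "biomass"
  universal_db(mets, rxns[setdiff(names(rxns), biomass_id)], bm,
               provenance = paste0("tsv:", basename(reactions_path)))
}

#' Write a balance audit report to TSV
#'
#' @param report a \code{balance_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_balance_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
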