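## From protein-annotation evidence to a draft model: parse BLAST-style hit
## tables, filter them, translate subject genes/orthologs to reactions via a
## mapping dictionary, and assemble the gene-associated draft GENRE.

#' Parse a tabular protein-alignment hit file
#'
#' Reads the 12-column tab-separated alignment dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore).  Malformed rows are skipped and counted
#' in a warning; a file with no parseable row is an error.
#'
#' @param path hit table path.
#' @return data.frame of hits: query_gene, subject_gene, percent_identity,
#'   evalue, bitscore; ranked by bitscore descending.
#' @export
parse_hits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 12L && !is.na(suppressWarnings(as.numeric(f[11]))) &&
      !is.na(suppressWarnings(as.numeric(f[12])))
  }, TRUE)
  if (!any(ok)) stop("no parseable hit rows in ", path)
  if (any(!ok))
    warning(sum(!ok), " malformed hit row(s) skipped in ", basename(path))
  fields <- fields[ok]
  hits <- data.frame(
    query_gene = vapply(fields, `[`, "", 1L),
    subject_gene = vapply(fields, `[`, "", 2L),
    percent_identity = as.numeric(vapply(fields, `[`, "", 3L)),
    evalue = as.numeric(vapply(fields, `[`, "", 11L)),
    bitscore = as.numeric(vapply(fields, `[`, "", 12L)),
    stringsAsFactors = FALSE)
  hits[order(-hits$bitscore, hits$query_gene, hits$subject_gene,
             method = "radix"), , drop = FALSE]
}

#' Filter alignment hits
#'
#' Applies e-value and bitscore thresholds, then keeps only the
#' highest-bitscore hit per (query, subject) pair.  With
#' \code{best_per_query = TRUE} only each query's single best subject
#' survives.
#'
#' @param hits data.frame from \code{\link{parse_hits}}.
#' @param max_evalue,min_bitscore retention thresholds (defaults 1e-10, 50).
#' @param best_per_query keep only the best subject per query gene.
#' @return filtered data.frame, bitscore-ranked.
#' @export
filter_hits <- function(hits, max_evalue = 1e-10, min_bitscore = 50,
                        best_per_query = FALSE) {
  stopifnot(is.finite(max_evalue), is.finite(min_bitscore))
  keep <- hits$evalue <= max_evalue & hits$bitscore >= min_bitscore
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  hits <- hits[order(-hits$bitscore, hits$query_gene, hits$subject_gene,
                     method = "radix"), , drop = FALSE]
  key <- if (best_per_query) hits$query_gene else
    paste(hits$query_gene, hits$subject_gene, sep = "\r")
  hits[!duplicated(key), , drop = FALSE]
}

#' Read a gene/ortholog-to-reaction mapping
#'
#' JSON object mapping subject gene or ortholog ids (e.g. KEGG KO ids) to
#' arrays of reaction ids in the universal namespace.  Every reaction id is
#' validated against the database at load.
#'
#' @param path JSON path.
#' @param db universal database used for validation (optional).
#' @return named list: subject id -> character vector of reaction ids.
#' @export
read_gene_reaction_map <- function(path, db = NULL) {
  grm <- lapply(jsonlite::read_json(path), function(x) unlist(x))
  if (!is.null(db)) {
    bad <- setdiff(unique(unlist(grm)), names(db$reactions))
    if (length(bad))
      stop("gene-reaction map references reaction(s) absent from the ",
           "universal database: ", paste(bad, collapse = ", "))
  }
  grm
}

#' Translate hits into draft reaction evidence
#'
#' Every hit whose subject appears in the mapping contributes its query gene
#' as supporting evidence for each mapped reaction.  Subjects absent from
#' the mapping are counted and reported via an attribute, never fatal.
#'
#' @param hits filtered hit data.frame.
#' @param grm mapping from \code{\link{read_gene_reaction_map}}.
#' @return a \code{draft_evidence}: named list reaction id -> sorted unique
#'   supporting query genes, with attribute \code{n_unmapped}.
#' @export
hits_to_evidence <- function(hits, grm) {
  evidence <- list()
  unmapped <- 0L
  for (i in seq_len(nrow(hits))) {
    subj <- hits$subject_gene[i]
    if (is.null(grm[[subj]])) { unmapped <- unmapped + 1L; next }
    for (rid in grm[[subj]])
      evidence[[rid]] <- union(evidence[[rid]], hits$query_gene[i])
  }
  evidence <- lapply(evidence, sort_ids)
  evidence <- evidence[id_order(names(evidence))]
  if (unmapped)
    message(unmapped, " hit(s) had subjects absent from the gene-reaction map")
  structure(evidence, class = "draft_evidence", n_unmapped = unmapped)
}

#' Build a draft GENRE from reaction evidence
#'
#' The draft contains every evidenced reaction copied from the universal
#' database with \code{source = "gene_annotated"} and a GPR that ORs the
#' supporting genes (hit tables carry no subunit structure, so complexes are
#' never inferred); all metabolites those reactions touch; the database
#' biomass as the objective; and media-driven additions: under complete
#' media every database exchange, under a named media each media
#' metabolite's exchange plus, when the draft cannot already move it inside,
#' a reversible transport tagged \code{source = "media_added"}.  Exchange
#' bounds are then set by \code{\link{set_media}}.
#'
#' @param evidence a \code{draft_evidence}.
#' @param db curated \code{universal_db}.
#' @param media a \code{media_condition}.
#' @param id model id.
#' @return a draft \code{genre}.
#' @export
build_draft <- function(evidence, db, media = media_complete(),
                        id = "draft") {
  bad <- setdiff(names(evidence), names(db$reactions))
  if (length(bad))
    stop("evidence references reaction(s) absent from the database: ",
         paste(bad, collapse = ", "))
  if (!length(evidence))
    warning("no reaction evidence; draft contains only biomass and media ",
            "reactions")
  reactions <- list()
  for (rid in names(evidence)) {
    r <- db$reactions[[rid]]
    r$source <- "gene_annotated"
    r$gpr <- paste(evidence[[rid]], collapse = " or ")
    reactions[[rid]] <- r
  }

  bm <- db$biomass_template
  bm$id <- "biomass"
  reactions[["biomass"]] <- bm

  ## media-driven additions
  ex_ids <- names(db$reactions)[vapply(db$reactions, is_exchange, TRUE)]
  if (is_complete_media(media)) {
    for (eid in ex_ids)
      if (is.null(reactions[[eid]])) reactions[[eid]] <- db$reactions[[eid]]
  } else {
    for (mid in names(media$uptake)) {
      eid <- paste0("EX_", mid)
      if (eid %in% names(db$reactions)) {
        if (is.null(reactions[[eid]])) reactions[[eid]] <- db$reactions[[eid]]
      } else {
        reactions[[eid]] <- reaction(eid, stats::setNames(-1, mid),
                                     name = paste("Exchange of", mid),
                                     source = "media_added")
      }
      ## a way in: any present reaction linking this e-metabolite to c;
      ## prefer copying a transport the database already knows
      base <- sub("_e$", "", mid)
      cid <- paste0(base, "_c")
      linking <- function(r) !is_exchange(r) &&
        all(c(mid, cid) %in% names(r$stoich))
      if (!any(vapply(reactions, linking, TRUE))) {
        in_db <- names(db$reactions)[vapply(db$reactions, linking, TRUE)]
        if (length(in_db)) {
          tr <- db$reactions[[in_db[1]]]
          tr$source <- "media_added"
          reactions[[tr$id]] <- tr
        } else {
          tid <- paste0("TR_", base, "_c")
          reactions[[tid]] <- reaction(tid,
                                       stats::setNames(c(-1, 1), c(mid, cid)),
                                       name = paste("Transport of", base),
                                       source = "media_added")
        }
      }
    }
  }

  ## collect touched metabolites (creating cytosolic partners for media
  ## transports that the database lacks)
  met_ids <- sort_ids(unique(unlist(lapply(reactions, function(r)
    names(r$stoich)))))
  mets <- lapply(met_ids, function(mid) {
    if (!is.null(db$metabolites[[mid]])) db$metabolites[[mid]] else
      metabolite(mid)
  })
  model <- genre(id, mets, reactions, objective = "biomass")
  set_media(model, media)
}
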