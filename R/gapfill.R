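## Parsimonious-flux gap-filling.  Rather than minimising the NUMBER of
## reactions added, a single LP over the draft plus every database candidate
## minimises weighted total absolute flux — zero weight on gene-supported
## draft reactions, unit weight on candidates — subject to steady state,
## bounds, and a growth floor on the biomass objective.  Candidates carrying
## flux above a noise threshold at the optimum are the gap-fill set.

#' Parsimonious-flux gap-filling of one draft under one media
#'
#' Builds an extended network (draft plus all database reactions not already
#' present), applies the media, and solves one LP: minimise
#' \code{sum_r w_r (v_r+ + v_r-)} with weight \code{weights$gene} on draft
#' reactions and \code{weights$candidate} on candidates, subject to
#' \code{S v = 0}, the bounds, and biomass flux at least \code{min_growth}.
#' Every candidate whose absolute flux at the optimum exceeds
#' \code{flux_epsilon} is copied into the model with
#' \code{source = "gapfilled"} and an empty GPR (no genetic evidence).
#'
#' @param draft a draft \code{genre}.
#' @param db curated \code{universal_db} sharing the draft's namespace.
#' @param media a \code{media_condition} for this gap-fill step.
#' @param weights list(gene=, candidate=): flux penalty for draft reactions
#'   (default 0: gene-supported flux is free) and for candidates (default 1).
#'   Setting \code{gene} to a small epsilon recovers a strictly parsimonious
#'   variant that also penalises draft flux.
#' @param min_growth growth floor the gap-filled model must attain
#'   (default 0.01).
#' @param flux_epsilon inclusion threshold; candidate activity at or below
#'   it is treated as numerical noise (default \code{FLUX_TOL}).
#' @param step_label note recorded on added reactions ("step1"/"step2").
#' @return list: \code{model} (draft plus additions, media applied),
#'   \code{added} (candidate ids added), \code{candidate_flux} (the LP's
#'   weighted candidate-flux objective value), \code{status}.
#' @export
pfba_gapfill <- function(draft, db, media, weights = list(gene = 0,
                                                          candidate = 1),
                         min_growth = 0.01, flux_epsilon = FLUX_TOL,
                         step_label = "step1") {
  stopifnot(min_growth > 0)
  extended <- extend_with_candidates(draft, db)
  model <- set_media(extended$model, media)
  w <- ifelse(extended$is_candidate, weights$candidate, weights$gene)
  sol <- .min_weighted_flux(model, weights = w, floor_value = min_growth)
  if (sol$status != "optimal")
    stop("no gap-fill solution exists in this database/media ",
         "(growth floor ", min_growth, " is infeasible)")
  cand_ids <- names(model$reactions)[extended$is_candidate]
  added <- cand_ids[sol$activity[match(cand_ids, names(model$reactions))] >
                      flux_epsilon]
  candidate_flux <- sum(w * sol$activity)

  out <- draft
  for (rid in added) {
    r <- db$reactions[[rid]]
    r$source <- "gapfilled"
    r$gpr <- ""
    r$notes <- c(r$notes, paste0("gapfilled:", step_label))
    out$reactions[[rid]] <- r
    for (mid in names(r$stoich))
      if (is.null(out$metabolites[[mid]]))
        out$metabolites[[mid]] <- db$metabolites[[mid]] %||% metabolite(mid)
  }
  out$reactions <- out$reactions[id_order(names(out$reactions))]
  out$metabolites <- out$metabolites[id_order(names(out$metabolites))]
  validate_genre(out)
  list(model = out, added = added, candidate_flux = candidate_flux,
       status = "optimal")
}

## Extended network: draft plus every database reaction not already present.
## Returns the combined model and a logical marking candidate columns.
extend_with_candidates <- function(draft, db) {
  reactions <- draft$reactions
  draft_ids <- names(reactions)
  for (rid in setdiff(names(db$reactions), draft_ids))
    reactions[[rid]] <- db$reactions[[rid]]
  met_ids <- sort_ids(unique(unlist(lapply(reactions, function(r)
    names(r$stoich)))))
  mets <- lapply(met_ids, function(mid)
    draft$metabolites[[mid]] %||% db$metabolites[[mid]] %||% metabolite(mid))
  model <- genre(paste0(draft$id, "+candidates"), mets, reactions,
                 objective = draft$objective)
  list(model = model,
       is_candidate = !(names(model$reactions) %in% draft_ids))
}

#' Two-step parsimonious-flux gap-filling
#'
#' Step 1 gap-fills under complete media (every exchange open), securing the
#' core biosynthetic routes; step 2 gap-fills the step-1 result under the
#' user's media, typically adding the transport/uptake routes the restricted
#' environment requires.  Step 2 is skipped when the user media is complete.
#' Additions are cumulative; a step never removes earlier additions.
#'
#' @param draft a draft \code{genre}.
#' @param db curated \code{universal_db}.
#' @param user_media the target \code{media_condition}.
#' @param weights,min_growth,flux_epsilon passed to
#'   \code{\link{pfba_gapfill}}.
#' @return list: \code{model} (final GENRE with user media applied) and
#'   \code{result}, a \code{gapfill_result} with \code{added_step1},
#'   \code{added_step2}, \code{objective_flux_final} and
#'   \code{total_candidate_flux}.
#' @export
two_step_gapfill <- function(draft, db, user_media,
                             weights = list(gene = 0, candidate = 1),
                             min_growth = 0.01, flux_epsilon = FLUX_TOL) {
  s1 <- tryCatch(
    pfba_gapfill(draft, db, media_complete(), weights = weights,
                 min_growth = min_growth, flux_epsilon = flux_epsilon,
                 step_label = "step1"),
    error = function(e) stop("gap-fill step 1 (complete media): ",
                             conditionMessage(e)))
  if (is_complete_media(user_media)) {
    model <- set_media(s1$model, user_media)
    added2 <- character()
    flux2 <- 0
  } else {
    s2 <- tryCatch(
      pfba_gapfill(s1$model, db, user_media, weights = weights,
                   min_growth = min_growth, flux_epsilon = flux_epsilon,
                   step_label = "step2"),
      error = function(e) stop("gap-fill step 2 (", user_media$name, "): ",
                               conditionMessage(e)))
    model <- set_media(s2$model, user_media)
    added2 <- s2$added
    flux2 <- s2$candidate_flux
  }
  final <- fba(model)
  result <- structure(list(added_step1 = s1$added, added_step2 = added2,
                           objective_flux_final = final$objective_value,
                           total_candidate_flux = s1$candidate_flux + flux2),
                      class = "gapfill_result")
  list(model = model, result = result)
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat("Gap-filling: ", length(x$added_step1), " reaction(s) in step 1, ",
      length(x$added_step2), " in step 2; final objective flux ",
      signif(x$objective_flux_final, 6), "\n", sep = "")
  invisible(x)
}

#' Write a gap-fill audit table
#'
#' @param result a \code{gapfill_result}.
#' @param model the gap-filled \code{genre} (for flux at optimum).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_gapfill_audit <- function(result, model, path) {
  fd <- pfba(model)
  ids <- c(result$added_step1, result$added_step2)
  steps <- c(rep("step1", length(result$added_step1)),
             rep("step2", length(result$added_step2)))
  utils::write.table(
    data.frame(reaction_id = ids, step = steps,
               flux_at_optimum = unname(fd$flux[ids])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
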