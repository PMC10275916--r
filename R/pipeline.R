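## End-to-end reconstruction pipeline and run report.  The same entry point
## backs the command-line script (inst/scripts/genrecon.R) and in-process
## use, so a shell run and a programmatic run with the same inputs and seed
## produce byte-identical SBML.

#' Reconstruct a GENRE from annotation evidence or an existing model
#'
#' Dispatches on input type: Type 1 (annotated protein FASTA) hands the
#' alignment step to an optional external aligner hook and then follows the
#' Type 2 path; Type 2 (tabular alignment hits) parses and filters hits,
#' maps them to reactions, builds the gene-associated draft and two-step
#' gap-fills it; Type 3 (existing SBML GENRE in the same namespace) goes
#' straight to two-step gap-filling.
#'
#' @param input_file path to the FASTA (Type 1), hit table (Type 2) or SBML
#'   model (Type 3).
#' @param file_type 1, 2 or 3.
#' @param universal_db a \code{universal_db} or path to its JSON; curated
#'   automatically when raw.
#' @param gene_reaction_map mapping list or JSON path (Types 1-2).
#' @param media a \code{media_condition}, a media JSON path, or "complete".
#' @param min_growth gap-fill growth floor.
#' @param max_evalue,min_bitscore hit filter thresholds (Types 1-2).
#' @param best_per_query keep only each query's best subject hit.
#' @param out output SBML path (NULL: no file written).
#' @param save_draft also write the pre-gap-fill draft next to \code{out}.
#' @param seed integer seed for any randomness downstream (LP solving is
#'   deterministic; the seed is recorded in the report).
#' @param aligner_cmd NULL, or an external aligner command template
#'   containing \code{\{input\}} and \code{\{output\}} placeholders used for
#'   Type 1 input.  Without it Type 1 input is refused with instructions to
#'   supply Type 2 hits instead.
#' @param model_id id for the reconstructed model.
#' @return list: \code{model} (final \code{genre}), \code{report}
#'   (\code{run_report}), \code{draft}, \code{gapfill}
#'   (\code{gapfill_result}), \code{sbml_path}.
#' @export
reconstruct <- function(input_file, file_type, universal_db,
                        gene_reaction_map = NULL, media = "complete",
                        min_growth = 0.01, max_evalue = 1e-10,
                        min_bitscore = 50, best_per_query = FALSE,
                        out = NULL, save_draft = FALSE, seed = 42,
                        aligner_cmd = NULL, model_id = NULL) {
  if (!file_type %in% 1:3) stop("file_type must be 1, 2 or 3")
  if (!file.exists(input_file)) stop("input file not found: ", input_file)
  orig_type <- file_type
  set.seed(as.integer(seed))
  warnings_seen <- character()
  note <- function(msg) warnings_seen <<- c(warnings_seen, msg)

  db <- if (is.character(universal_db)) read_universal_db(universal_db) else
    universal_db
  if (!grepl("\\[curated\\]$", db$provenance)) {
    cur <- curate_database(db)
    if (length(cur$removed))
      note(paste0("curation removed ", length(cur$removed),
                  " unbalanced reaction(s)"))
    db <- cur$db
  }
  media_obj <- resolve_media(media)
  if (is.null(model_id))
    model_id <- tools::file_path_sans_ext(basename(input_file))

  if (file_type == 1) {
    if (is.null(aligner_cmd))
      stop("Type 1 input needs an external protein aligner; none is ",
           "configured. Align your FASTA against the gene namespace ",
           "yourself (e.g. DIAMOND/BLASTp, tabular output format 6) and ",
           "rerun with the hit table as Type 2 input, or pass aligner_cmd.")
    hits_path <- tempfile(fileext = ".tsv")
    cmd <- sub("{output}", hits_path,
               sub("{input}", input_file, aligner_cmd, fixed = TRUE),
               fixed = TRUE)
    status <- system(cmd)
    if (status != 0 || !file.exists(hits_path))
      stop("external aligner failed (exit ", status, "): ", cmd)
    input_file <- hits_path
    file_type <- 2
  }

  if (file_type == 2) {
    if (is.null(gene_reaction_map))
      stop("Type 2 input needs a gene_reaction_map")
    grm <- if (is.character(gene_reaction_map))
      read_gene_reaction_map(gene_reaction_map, db) else gene_reaction_map
    hits <- withCallingHandlers(parse_hits(input_file), warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    })
    hits <- filter_hits(hits, max_evalue = max_evalue,
                        min_bitscore = min_bitscore,
                        best_per_query = best_per_query)
    evidence <- hits_to_evidence(hits, grm)
    if (attr(evidence, "n_unmapped") > 0)
      note(paste0(attr(evidence, "n_unmapped"),
                  " hit(s) missing from the gene-reaction map"))
    draft <- withCallingHandlers(
      build_draft(evidence, db, media = media_obj, id = model_id),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
  } else {
    draft <- read_sbml(input_file, id = model_id)
  }

  gf <- two_step_gapfill(draft, db, media_obj, min_growth = min_growth)
  model <- gf$model
  report <- run_report(draft, model, gf$result,
                       input_type = paste0("type", orig_type),
                       media_name = media_obj$name, seed = seed,
                       warnings = warnings_seen)
  sbml_path <- NULL
  if (!is.null(out)) {
    write_sbml(model, out)
    sbml_path <- out
    if (save_draft)
      write_sbml(draft, file.path(dirname(out),
                                  paste0("draft_", basename(out))))
  }
  list(model = model, report = report, draft = draft, gapfill = gf$result,
       sbml_path = sbml_path)
}

resolve_media <- function(media) {
  if (inherits(media, "media_condition")) return(media)
  if (identical(media, "complete")) return(media_complete())
  if (is.character(media) && file.exists(media)) return(read_media(media))
  stop("media must be a media_condition, 'complete', or a media JSON path")
}

#' Build a run report
#'
#' Snapshot of draft-versus-final model statistics plus gap-filling
#' outcome, mirroring what the pipeline prints after a reconstruction.
#'
#' @param draft,final draft and final \code{genre}s.
#' @param gapfill_result a \code{gapfill_result}.
#' @param input_type,media_name,seed run metadata.
#' @param warnings character vector of collected warnings.
#' @return a \code{run_report}.
#' @export
run_report <- function(draft, final, gapfill_result, input_type, media_name,
                       seed = NA_integer_, warnings = character()) {
  ds <- model_stats(draft); fs <- model_stats(final)
  rep <- list(draft_counts = ds[c("genes", "reactions", "metabolites")],
              final_counts = fs[c("genes", "reactions", "metabolites")],
              gapfilled_step1 = length(gapfill_result$added_step1),
              gapfilled_step2 = length(gapfill_result$added_step2),
              gapfilled_total = length(gapfill_result$added_step1) +
                length(gapfill_result$added_step2),
              objective_flux = gapfill_result$objective_flux_final,
              input_type = input_type, media = media_name, seed = seed,
              warnings = warnings)
  stopifnot(rep$final_counts$reactions >= rep$draft_counts$reactions,
            rep$final_counts$metabolites >= rep$draft_counts$metabolites)
  structure(rep, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Reconstruction report (", x$input_type, ", media: ", x$media, ")\n",
      sep = "")
  cat(sprintf("  draft:  %d genes, %d reactions, %d metabolites\n",
              x$draft_counts$genes, x$draft_counts$reactions,
              x$draft_counts$metabolites))
  cat(sprintf("  final:  %d genes, %d reactions, %d metabolites\n",
              x$final_counts$genes, x$final_counts$reactions,
              x$final_counts$metabolites))
  cat(sprintf("  gap-filled: %d (step 1: %d, step 2: %d)\n",
              x$gapfilled_total, x$gapfilled_step1, x$gapfilled_step2))
  cat(sprintf("  final objective flux: %.6g\n", x$objective_flux))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Write a run report to JSON
#' @param report a \code{run_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a reaction-evidence table to TSV
#' @param evidence a \code{draft_evidence}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_evidence_table <- function(evidence, path) {
  utils::write.table(
    data.frame(reaction_id = names(evidence),
               genes = vapply(evidence, paste, "", collapse = ";")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
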