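# Shared fixture builders and the independent brute-force gap-fill oracle.
# The oracle enumerates candidate subsets and solves a plain feasibility-
# minimisation LP per subset, built directly from the stoichiometric matrix;
# it never calls the gap-filling code under test.

# curated db + evidence-built draft for a seeded toy pathway
fixture_bundle <- function(seed, pathway_length = 4, n_decoy = 3,
                           n_unbalanced = 1, bypass = NULL,
                           drop = integer(), redundant_on = NULL) {
  fx <- make_universal_fixture(seed, pathway_length = pathway_length,
                               n_decoy = n_decoy,
                               n_unbalanced = n_unbalanced, bypass = bypass)
  cur <- curate_database(fx$db)
  drop_ids <- if (is.numeric(drop)) fx$truth$pathway_rxns[drop] else drop
  hf <- make_hit_fixture(fx$truth, drop = drop_ids,
                         redundant_on = redundant_on)
  ht <- tempfile(fileext = ".tsv")
  write_hit_table(hf$hits, ht)
  evidence <- hits_to_evidence(filter_hits(parse_hits(ht)), hf$grm)
  draft <- build_draft(evidence, cur$db, media = fx$truth$media,
                       id = sprintf("toy%d", seed))
  list(fx = fx, truth = fx$truth, db = cur$db, report = cur$report,
       removed = cur$removed, hf = hf, draft = draft, drop = drop_ids,
       media = fx$truth$media)
}

# minimum candidate flux for one fixed candidate subset (feasibility LP),
# or NA when the subset cannot reach min_growth
subset_candidate_flux <- function(draft, db, subset, media, min_growth) {
  rxns <- draft$reactions
  for (rid in subset) rxns[[rid]] <- db$reactions[[rid]]
  mids <- sort(unique(unlist(lapply(rxns, function(r) names(r$stoich)))))
  mets <- lapply(mids, function(m) db$metabolites[[m]] %||%
                   draft$metabolites[[m]])
  names(mets) <- mids
  model <- genre("oracle", mets, rxns, objective = draft$objective)
  model <- set_media(model, media)

  S <- as.matrix(stoich_matrix(model))
  n <- ncol(S)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  w <- as.numeric(names(model$reactions) %in% subset)
  io <- match(model$objective, names(model$reactions))
  Ale <- matrix(0, 1, 2 * n); Ale[1, io] <- -1; Ale[1, n + io] <- 1
  sol <- solve_lp(c(w, w), A_eq = cbind(S, -S), b_eq = rep(0, nrow(S)),
                  A_le = Ale, b_le = -min_growth,
                  lb = rep(0, 2 * n), ub = c(pmax(ub, 0), pmax(-lb, 0)))
  if (sol$status != "optimal") NA_real_ else sol$objval
}

# exhaustive enumeration over every candidate subset
oracle_min_candidate_flux <- function(draft, db, media, min_growth = 0.01) {
  candidates <- setdiff(names(db$reactions), names(draft$reactions))
  stopifnot(length(candidates) <= 12)
  best <- Inf
  best_subset <- NULL
  for (mask in 0:(2^length(candidates) - 1)) {
    subset <- candidates[bitwAnd(mask, 2^(seq_along(candidates) - 1)) > 0]
    val <- subset_candidate_flux(draft, db, subset, media, min_growth)
    if (!is.na(val) && val < best - 1e-12) {
      best <- val
      best_subset <- subset
    }
  }
  list(objective = best, subset = best_subset)
}

# hand-built parallel-route toy: uptake A, then a 2-step and a 3-step route
# from A to B, biomass consumes B
parallel_route_model <- function(uptake = 10) {
  mets <- lapply(c("cpd97001_e", "cpd97001_c", "cpd97002_c", "cpd97003_c",
                   "cpd97004_c", "cpd97005_c", "cpd97006_c"),
                 function(m) metabolite(m, formula = "C2H4O2", charge = 0L))
  A_e <- "cpd97001_e"; A <- "cpd97001_c"; B <- "cpd97006_c"
  X <- "cpd97002_c"; Y1 <- "cpd97003_c"; Y2 <- "cpd97004_c"
  rx <- list(
    reaction("EX_cpd97001_e", setNames(-1, A_e), lb = -uptake, ub = 1000,
             source = "exchange"),
    reaction("rxn97000_c", setNames(c(-1, 1), c(A_e, A)), lb = -1000),
    reaction("rxn97001_c", setNames(c(-1, 1), c(A, X)), lb = 0),
    reaction("rxn97002_c", setNames(c(-1, 1), c(X, B)), lb = 0),
    reaction("rxn97003_c", setNames(c(-1, 1), c(A, Y1)), lb = 0),
    reaction("rxn97004_c", setNames(c(-1, 1), c(Y1, Y2)), lb = 0),
    reaction("rxn97005_c", setNames(c(-1, 1), c(Y2, B)), lb = 0),
    reaction("biomass", setNames(-1, B), lb = 0, source = "biomass"))
  genre("parallel", mets, rx, objective = "biomass")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
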