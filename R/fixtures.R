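## Deterministic toy-fixture generator.  Every artifact the pipeline reads
## (universal databases, hit tables, gene-reaction maps, media, SBML models)
## can be generated at toy scale with KNOWN ground truth: which reactions
## were seeded unbalanced, which completion a gap-filler must find, which
## genes are essential.  Fixtures are topological/stoichiometric toys in the
## ModelSEED-style namespace (cpd9####_*, rxn9####_c), not real biochemistry.

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

rand_formula <- function() {
  sprintf("C%dH%dO%d", sample(3:12, 1), sample(4:24, 1), sample(1:10, 1))
}

#' Generate a toy universal database with known ground truth
#'
#' The database contains: a balanced linear pathway from one extracellular
#' carbon source through \code{pathway_length} cytosolic conversions into a
#' single biomass precursor (uptake transport included, 1:1 stoichiometry
#' throughout, so the designed biomass yield per unit uptake is exactly 1);
#' \code{n_decoy} balanced decoy reactions disconnected from the pathway;
#' \code{n_unbalanced} reactions whose product coefficient was perturbed by
#' +1, making them elementally unbalanced; and optionally a short/long
#' bypass pair replacing one pathway edge (the direct edge reaction is then
#' absent from the database, so a gap there can only be closed through a
#' bypass; the short route is the flux-minimal completion).
#'
#' The raw database deliberately omits the carbon-source exchange reaction
#' so that curation must add it.
#'
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param pathway_length number of cytosolic pathway conversions (>= 2).
#' @param n_decoy number of balanced decoy reactions.
#' @param n_unbalanced number of seeded-unbalanced reactions.
#' @param bypass NULL, or \code{c(short = s, long = l)} with
#'   \code{1 <= s < l}: lengths of the two alternative routes across the
#'   severed pathway edge.
#' @param uptake_rate media uptake bound for the carbon source (default 10).
#' @return list: \code{db} (raw \code{universal_db}) and \code{truth}, a
#'   record of seeded answers (unbalanced ids, pathway reaction ids, gene
#'   and ortholog assignments, the media, designed yield, bypass sets,
#'   essential/redundant genes).
#' @export
make_universal_fixture <- function(seed, pathway_length = 5, n_decoy = 4,
                                   n_unbalanced = 2, bypass = NULL,
                                   uptake_rate = 10) {
  stopifnot(pathway_length >= 2, n_decoy >= 0, n_unbalanced >= 0)
  if (!is.null(bypass)) {
    if (bypass[["short"]] < 1 || bypass[["long"]] <= bypass[["short"]])
      stop("bypass must satisfy 1 <= short < long")
  }
  with_seed_local(seed, {
    chain_formula <- rand_formula()
    mets <- list()
    rxns <- list()

    src_e <- "cpd91000_e"; src_c <- "cpd91000_c"
    mets[[src_e]] <- metabolite(src_e, name = "carbon source (ext)",
                                formula = chain_formula, charge = 0L)
    chain <- c(src_c, sprintf("cpd910%02d_c", seq_len(pathway_length)))
    for (mid in chain)
      mets[[mid]] <- metabolite(mid, formula = chain_formula, charge = 0L)

    transport_id <- "rxn91000_c"
    rxns[[transport_id]] <- reaction(
      transport_id, stats::setNames(c(-1, 1), c(src_e, src_c)),
      name = "carbon source transport", lb = -1000, ub = 1000)

    gap_edge <- if (is.null(bypass)) NA_integer_ else
      max(2L, ceiling(pathway_length / 2))
    pathway <- transport_id
    for (i in seq_len(pathway_length)) {
      rid <- sprintf("rxn910%02d_c", i)
      if (!is.null(bypass) && i == gap_edge) next  # severed edge: bypass only
      rxns[[rid]] <- reaction(rid,
                              stats::setNames(c(-1, 1),
                                              c(chain[i], chain[i + 1])),
                              name = sprintf("pathway step %d", i),
                              lb = 0, ub = 1000)
      pathway <- c(pathway, rid)
    }

    bypass_truth <- NULL
    if (!is.null(bypass)) {
      mk_route <- function(len, tag, cpd_base, rxn_base) {
        inter <- if (len > 1)
          sprintf("cpd9%d%02d_c", cpd_base, seq_len(len - 1)) else character()
        for (mid in inter)
          mets[[mid]] <<- metabolite(mid, formula = chain_formula,
                                     charge = 0L)
        nodes <- c(chain[gap_edge], inter, chain[gap_edge + 1])
        ids <- sprintf("rxn9%d%02d_c", rxn_base, seq_len(len))
        for (k in seq_len(len))
          rxns[[ids[k]]] <<- reaction(ids[k],
                                      stats::setNames(c(-1, 1),
                                                      c(nodes[k], nodes[k + 1])),
                                      name = sprintf("%s bypass step %d", tag, k),
                                      lb = 0, ub = 1000)
        ids
      }
      short_ids <- mk_route(bypass[["short"]], "short", 4, 4)
      long_ids <- mk_route(bypass[["long"]], "long", 5, 5)
      bypass_truth <- list(short = short_ids, long = long_ids,
                           gap_edge = gap_edge)
    }

    for (d in seq_len(n_decoy)) {
      f <- rand_formula()
      a <- sprintf("cpd920%02da_c", d); b <- sprintf("cpd920%02db_c", d)
      mets[[a]] <- metabolite(a, formula = f, charge = 0L)
      mets[[b]] <- metabolite(b, formula = f, charge = 0L)
      rid <- sprintf("rxn920%02d_c", d)
      rxns[[rid]] <- reaction(rid, stats::setNames(c(-1, 1), c(a, b)),
                              name = sprintf("decoy %d", d), lb = 0, ub = 1000)
    }

    unbalanced_ids <- character()
    for (u in seq_len(n_unbalanced)) {
      f <- rand_formula()
      a <- sprintf("cpd930%02da_c", u); b <- sprintf("cpd930%02db_c", u)
      mets[[a]] <- metabolite(a, formula = f, charge = 0L)
      mets[[b]] <- metabolite(b, formula = f, charge = 0L)
      rid <- sprintf("rxn930%02d_c", u)
      ## balanced would be 1:1; the +1 coefficient perturbation unbalances it
      rxns[[rid]] <- reaction(rid, stats::setNames(c(-1, 2), c(a, b)),
                              name = sprintf("seeded unbalanced %d", u),
                              lb = 0, ub = 1000)
      unbalanced_ids <- c(unbalanced_ids, rid)
    }

    precursor <- chain[length(chain)]
    biomass <- reaction("biomass", stats::setNames(-1, precursor),
                        name = "biomass assembly", lb = 0, ub = 1000,
                        source = "biomass")

    db <- universal_db(unname(mets), unname(rxns), biomass,
                       provenance = sprintf("toy fixture seed %d", seed))

    stem <- sub("_c$", "", sub("^rxn", "", pathway))
    genes <- stats::setNames(paste0("g", stem), pathway)
    subjects <- stats::setNames(paste0("K", stem), pathway)
    media <- media_condition("minimal",
                             uptake = stats::setNames(uptake_rate, src_e))
    truth <- list(seed = seed,
                  source_met = src_e, exchange_id = paste0("EX_", src_e),
                  chain_mets = chain, pathway_rxns = pathway,
                  transport_id = transport_id,
                  genes = genes, subjects = subjects,
                  unbalanced_ids = unbalanced_ids,
                  decoy_ids = grep("^rxn920", names(rxns), value = TRUE),
                  bypass = bypass_truth,
                  media = media, uptake_rate = uptake_rate, yield = 1)
    list(db = db, truth = truth)
  })
}

#' Generate a hit-table fixture for a toy database
#'
#' Emits one synthetic query gene and one alignment hit row per pathway
#' reaction NOT in \code{drop}, mapped through a generated gene-reaction
#' map; the dropped reactions are the known gap-fill answer.  One reaction
#' may carry a second, redundant isozyme gene to exercise OR logic in
#' essentiality screens.
#'
#' @param truth ground-truth record from \code{\link{make_universal_fixture}}.
#' @param drop reaction ids (subset of the pathway) to withhold evidence for.
#' @param redundant_on pathway reaction id that should receive a second
#'   supporting gene (NULL for none).
#' @return list: \code{hits} (12-column outfmt-6-style data.frame),
#'   \code{grm} (subject -> reaction ids), \code{genes} (gene -> reaction),
#'   \code{essential_genes}, \code{nonessential_genes} (seeded answer for
#'   the generated draft under the fixture media, valid when
#'   \code{drop} is empty).
#' @export
make_hit_fixture <- function(truth, drop = character(),
                             redundant_on = NULL) {
  stopifnot(all(drop %in% truth$pathway_rxns))
  keep <- setdiff(truth$pathway_rxns, drop)
  genes <- truth$genes[keep]
  subjects <- truth$subjects[keep]
  if (!is.null(redundant_on)) {
    stopifnot(redundant_on %in% keep)
    extra_gene <- paste0(truth$genes[[redundant_on]], "_iso")
  }
  row_for <- function(gene, subject) {
    data.frame(query = gene, subject = subject,
               pident = 95.0, length = 300L, mismatch = 5L, gapopen = 0L,
               qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
               evalue = 1e-50, bitscore = 500,
               stringsAsFactors = FALSE)
  }
  rows <- mapply(row_for, genes, subjects, SIMPLIFY = FALSE)
  if (!is.null(redundant_on))
    rows <- c(rows, list(row_for(extra_gene, truth$subjects[[redundant_on]])))
  hits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  grm <- as.list(stats::setNames(keep, subjects))
  essential <- unname(genes)
  nonessential <- character()
  if (!is.null(redundant_on)) {
    pair <- c(truth$genes[[redundant_on]], extra_gene)
    essential <- setdiff(essential, pair)
    nonessential <- pair
  }
  list(hits = hits, grm = grm,
       genes = stats::setNames(keep, unname(genes)),
       essential_genes = sort_ids(essential),
       nonessential_genes = sort_ids(nonessential))
}

#' Write a hit-table fixture to an outfmt-6 style TSV
#' @param hits data.frame from \code{\link{make_hit_fixture}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a gene-reaction map fixture to JSON
#' @param grm named list subject -> reaction ids.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_reaction_map <- function(grm, path) {
  jsonlite::write_json(lapply(grm, as.list), path, auto_unbox = TRUE)
  invisible(path)
}

#' Write a media fixture to JSON
#' @param media a \code{media_condition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_media <- function(media, path) {
  doc <- if (is_complete_media(media)) list(name = media$name, complete = TRUE)
  else list(name = media$name, uptake = as.list(media$uptake))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate the two-step gap-filling fixture
#'
#' A toy in which growth on complete media needs one missing internal
#' reaction (the step-1 answer) while growth on the minimal user media
#' additionally needs the carbon-source uptake transport (the step-2
#' answer):
#' source A (exchange, transport T_A, conversion r1 to B) and a side door
#' B (exchange, transport T_B) feed precursor C consumed by biomass.  The
#' draft carries gene evidence for T_B and r1 only, so step 1 under
#' complete media must add r2 (B -> C) and step 2 under "A only" media
#' must add T_A.
#'
#' @param seed integer seed (controls formulas only; topology is fixed).
#' @param uptake_rate uptake bound on A in the minimal media.
#' @return list: \code{db} (raw \code{universal_db}), \code{draft}
#'   (evidence-only \code{genre} built against the curated db), \code{media}
#'   (the minimal user media), \code{truth} with \code{step1}/\code{step2}
#'   expected addition sets.
#' @export
make_two_step_fixture <- function(seed, uptake_rate = 10) {
  with_seed_local(seed, {
    f <- rand_formula()
    ids <- c(A_e = "cpd96001_e", A_c = "cpd96001_c", B_e = "cpd96002_e",
             B_c = "cpd96002_c", C_c = "cpd96003_c")
    mets <- lapply(ids, function(x) metabolite(x, formula = f, charge = 0L))
    rxn_TA <- reaction("rxn96001_c",
                       stats::setNames(c(-1, 1), ids[c("A_e", "A_c")]),
                       name = "transport A", lb = -1000, ub = 1000)
    rxn_r1 <- reaction("rxn96002_c",
                       stats::setNames(c(-1, 1), ids[c("A_c", "B_c")]),
                       name = "A to B", lb = 0, ub = 1000)
    rxn_TB <- reaction("rxn96003_c",
                       stats::setNames(c(-1, 1), ids[c("B_e", "B_c")]),
                       name = "transport B", lb = -1000, ub = 1000)
    rxn_r2 <- reaction("rxn96004_c",
                       stats::setNames(c(-1, 1), ids[c("B_c", "C_c")]),
                       name = "B to C", lb = 0, ub = 1000)
    biomass <- reaction("biomass", stats::setNames(-1, ids[["C_c"]]),
                        name = "biomass assembly", lb = 0, ub = 1000,
                        source = "biomass")
    db <- universal_db(unname(mets), list(rxn_TA, rxn_r1, rxn_TB, rxn_r2),
                       biomass,
                       provenance = sprintf("two-step fixture seed %d", seed))
    cur <- curate_database(db)
    evidence <- structure(list(rxn96002_c = "g96002", rxn96003_c = "g96003"),
                          class = "draft_evidence")
    names(evidence) <- c(rxn_r1$id, rxn_TB$id)
    draft <- build_draft(evidence, cur$db, media = media_complete(),
                         id = "two_step_draft")
    media <- media_condition("A_only",
                             uptake = stats::setNames(uptake_rate,
                                                      ids[["A_e"]]))
    list(db = db, curated = cur$db, draft = draft, media = media,
         truth = list(step1 = rxn_r2$id, step2 = rxn_TA$id,
                      uptake_rate = uptake_rate, yield = 1))
  })
}
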