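# Hit parsing/filtering, evidence mapping and draft construction.

hit_row <- function(q, s, evalue = 1e-50, bitscore = 500) {
  paste(q, s, "98.2", "300", "5", "0", "1", "300", "1", "300",
        format(evalue), format(bitscore), sep = "\t")
}

test_that("parse_hits reads outfmt-6 rows and skips malformed ones", {
  p <- tempfile()
  writeLines(c(hit_row("g1", "K00001"), "broken row",
               hit_row("g2", "K00002", 1e-3, 40)), p)
  expect_warning(h <- parse_hits(p), "malformed")
  expect_equal(nrow(h), 2)
  expect_equal(h$query_gene[1], "g1")
  expect_equal(h$subject_gene[1], "K00001")
  expect_equal(h$evalue[1], 1e-50)
  expect_equal(h$bitscore[1], 500)

  writeLines(character(), p)
  expect_error(parse_hits(p), "no parseable")
})

test_that("filter_hits applies thresholds and keeps best per pair", {
  p <- tempfile()
  writeLines(c(hit_row("g1", "K1", 1e-50, 500),
               hit_row("g1", "K1", 1e-40, 300),   # duplicate pair, worse
               hit_row("g1", "K2", 1e-3, 500),    # fails evalue
               hit_row("g2", "K1", 1e-30, 10)),   # fails bitscore
             p)
  h <- parse_hits(p)
  f <- filter_hits(h, max_evalue = 1e-10, min_bitscore = 50)
  expect_equal(nrow(f), 1)
  expect_equal(f$bitscore, 500)
  expect_equal(nrow(filter_hits(h[0, ])), 0)

  # best-per-query mode collapses to one subject per query
  writeLines(c(hit_row("g1", "K1", 1e-50, 300), hit_row("g1", "K2", 1e-60, 400)),
             p)
  f <- filter_hits(parse_hits(p), best_per_query = TRUE)
  expect_equal(nrow(f), 1)
  expect_equal(f$subject_gene, "K2")
})

test_that("hits_to_evidence unions genes per reaction and counts unmapped", {
  p <- tempfile()
  writeLines(c(hit_row("g1", "K1"), hit_row("g2", "K2"),
               hit_row("g3", "K99999")), p)
  hits <- filter_hits(parse_hits(p))
  grm <- list(K1 = "rxn00005_c", K2 = "rxn00005_c")
  expect_message(ev <- hits_to_evidence(hits, grm), "1 hit")
  expect_equal(ev[["rxn00005_c"]], c("g1", "g2"))
  expect_equal(attr(ev, "n_unmapped"), 1L)
})

test_that("the draft carries OR GPRs, evidence genes only, and no gap-filled reactions", {
  b <- fixture_bundle(17, redundant_on = NULL)
  draft <- b$draft
  src <- vapply(draft$reactions, `[[`, "", "source")
  expect_false(any(src == "gapfilled"))
  annotated <- names(src)[src == "gene_annotated"]
  expect_setequal(annotated, b$truth$pathway_rxns)
  for (rid in annotated)
    expect_true(nzchar(draft$reactions[[rid]]$gpr))
  expect_setequal(genre_genes(draft), unname(b$truth$genes))

  # OR over supporting genes
  rxn3 <- make_universal_fixture(18)$truth$pathway_rxns[3]
  b2 <- fixture_bundle(18, pathway_length = 5, redundant_on = rxn3)
  rid <- b2$truth$pathway_rxns[3]
  gpr <- b2$draft$reactions[[rid]]$gpr
  expect_match(gpr, " or ")
  expect_setequal(gpr_genes(gpr),
                  c(b2$truth$genes[[rid]], paste0(b2$truth$genes[[rid]], "_iso")))
})

test_that("empty evidence with complete media yields biomass plus all exchanges", {
  fx <- make_universal_fixture(23, pathway_length = 3, n_decoy = 2,
                               n_unbalanced = 0)
  db <- curate_database(fx$db)$db
  ev <- structure(list(), class = "draft_evidence", n_unmapped = 0L)
  expect_warning(draft <- build_draft(ev, db, media = media_complete()),
                 "no reaction evidence")
  ex_ids <- names(db$reactions)[vapply(db$reactions, genrecon:::is_exchange,
                                       TRUE)]
  expect_setequal(names(draft$reactions), c("biomass", ex_ids))
  expect_equal(genre_genes(draft), character())
})

test_that("a fully evidenced draft attains the designed closed-form growth", {
  # linear chain, 1:1 stoichiometry: optimum = uptake bound x yield
  b <- fixture_bundle(29, pathway_length = 5)
  fd <- fba(b$draft)
  expect_equal(fd$status, "optimal")
  expect_equal(fd$objective_value,
               b$truth$uptake_rate * b$truth$yield, tolerance = 1e-8)
})

test_that("build_draft is deterministic", {
  b1 <- fixture_bundle(31)
  b2 <- fixture_bundle(31)
  expect_identical(b1$draft, b2$draft)
})

test_that("evidence referencing unknown reactions is refused", {
  b <- fixture_bundle(5)
  ev <- structure(list(rxn99999_c = "gX"), class = "draft_evidence")
  expect_error(build_draft(ev, b$db), "rxn99999_c")
})
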