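# Parsimonious-flux gap-filling: LP vs brute-force oracle, parsimony
# selection, two-step media semantics, evidence preservation.

test_that("a draft that already grows gains nothing", {
  b <- fixture_bundle(51)
  gf <- pfba_gapfill(b$draft, b$db, b$media)
  expect_equal(gf$added, character())
  expect_identical(gf$model$reactions, b$draft$reactions)
  expect_equal(gf$candidate_flux, 0, tolerance = 1e-9)
})

test_that("a single missing pathway reaction is recovered exactly", {
  b <- fixture_bundle(52, pathway_length = 5, n_decoy = 5, drop = 3)
  gf <- pfba_gapfill(b$draft, b$db, b$media)
  expect_setequal(gf$added, b$drop)
  added <- gf$model$reactions[[b$drop]]
  expect_equal(added$source, "gapfilled")
  expect_equal(added$gpr, "")
  # growth restored
  expect_gte(fba(gf$model)$objective_value, 0.01 - 1e-9)
})

test_that("gap-fill additions match the brute-force subset oracle", {
  for (seed in c(61, 62, 63)) {
    b <- fixture_bundle(seed, pathway_length = 4, n_decoy = 3,
                        drop = (seed %% 4) + 1)
    gf <- pfba_gapfill(b$draft, b$db, b$media)
    oracle <- oracle_min_candidate_flux(b$draft, b$db, b$media)
    expect_equal(gf$candidate_flux, oracle$objective, tolerance = 1e-6)
  }
})

test_that("the flux-cheaper bypass is selected over the longer one", {
  b <- fixture_bundle(71, pathway_length = 5, n_decoy = 2,
                      bypass = c(short = 2, long = 3))
  gf <- pfba_gapfill(b$draft, b$db, b$media)
  expect_setequal(gf$added, b$truth$bypass$short)
  # objective equals the independently solved short-route completion LP
  short_val <- subset_candidate_flux(b$draft, b$db, b$truth$bypass$short,
                                     b$media, 0.01)
  long_val <- subset_candidate_flux(b$draft, b$db, b$truth$bypass$long,
                                    b$media, 0.01)
  expect_equal(gf$candidate_flux, short_val, tolerance = 1e-9)
  expect_lt(short_val, long_val)
})

test_that("an unfillable gap is a hard, labelled error", {
  b <- fixture_bundle(81, drop = 2)
  # remove the dropped reaction from the database too: no completion exists
  db <- b$db
  db$reactions[[b$drop]] <- NULL
  expect_error(pfba_gapfill(b$draft, db, b$media), "no gap-fill solution")
  expect_error(two_step_gapfill(b$draft, db, b$media), "step 1")
})

test_that("draft reactions and GPRs survive gap-filling unchanged", {
  b <- fixture_bundle(82, drop = 2)
  gf <- two_step_gapfill(b$draft, b$db, b$media)
  for (rid in names(b$draft$reactions)) {
    r0 <- b$draft$reactions[[rid]]
    r1 <- gf$model$reactions[[rid]]
    expect_identical(r1$gpr, r0$gpr)
    expect_identical(r1$stoich, r0$stoich)
    expect_identical(r1$source, r0$source)
  }
})

test_that("enlarging the candidate database never worsens the objective", {
  b <- fixture_bundle(83, pathway_length = 4, n_decoy = 2, drop = 2)
  gf_small <- pfba_gapfill(b$draft, b$db, b$media)
  big <- fixture_bundle(83, pathway_length = 4, n_decoy = 5, drop = 2)
  gf_big <- pfba_gapfill(big$draft, big$db, big$media)
  expect_lte(gf_big$candidate_flux, gf_small$candidate_flux + 1e-9)
})

test_that("gap-filling under fixed inputs is deterministic", {
  b <- fixture_bundle(84, drop = 1)
  g1 <- pfba_gapfill(b$draft, b$db, b$media)
  g2 <- pfba_gapfill(b$draft, b$db, b$media)
  expect_identical(g1$added, g2$added)
  expect_identical(g1$model, g2$model)
})

test_that("two-step gap-filling separates core and media completions", {
  ts <- make_two_step_fixture(seed = 90)
  gf <- two_step_gapfill(ts$draft, ts$curated, ts$media)
  expect_setequal(gf$result$added_step1, ts$truth$step1)
  expect_setequal(gf$result$added_step2, ts$truth$step2)
  expect_length(intersect(gf$result$added_step1, gf$result$added_step2), 0)
  # step notes label provenance
  expect_match(gf$model$reactions[[ts$truth$step2]]$notes, "gapfilled:step2",
               all = FALSE)
  # final model grows on the user media
  expect_gte(gf$result$objective_flux_final, 0.01 - 1e-9)

  # complete user media skips step 2 by construction
  gf2 <- two_step_gapfill(ts$draft, ts$curated, media_complete())
  expect_equal(gf2$result$added_step2, character())
})

test_that("an evidence-free draft is gap-filled into a growing model", {
  fx <- make_universal_fixture(91, pathway_length = 3, n_decoy = 2,
                               n_unbalanced = 0)
  db <- curate_database(fx$db)$db
  ev <- structure(list(), class = "draft_evidence", n_unmapped = 0L)
  suppressWarnings(draft <- build_draft(ev, db, media = media_complete()))
  gf <- two_step_gapfill(draft, db, fx$truth$media)
  expect_gte(gf$result$objective_flux_final, 0.01 - 1e-9)
  # the whole uptake chain had to come from the database
  expect_true(all(fx$truth$pathway_rxns %in%
                    c(gf$result$added_step1, gf$result$added_step2)))
})
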