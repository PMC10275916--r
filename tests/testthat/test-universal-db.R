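# Formula parsing, balance checking and database curation.

test_that("parse_formula reads flat formulas and refuses everything else", {
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parse_formula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_equal(parse_formula("CH4"), c(C = 1L, H = 4L))
  expect_equal(parse_formula("MgSO4"), c(Mg = 1L, O = 4L, S = 1L))
  # repeated element symbols accumulate
  expect_equal(parse_formula("CH3COOH")[["O"]], 2L)
  # pseudo-elements that fit the grammar are ordinary symbols
  expect_equal(parse_formula("C5R")[["R"]], 1L)
  # undetermined, never an error
  expect_null(parse_formula("C10H12N5O7P*"))
  expect_null(parse_formula("C6(H2O)6"))
  expect_null(parse_formula(""))
  expect_null(parse_formula(NA_character_))
})

db_for_balance <- function() {
  mets <- list(
    metabolite("cpd00001_c", formula = "H2O", charge = 0L),
    metabolite("cpd00002_c", formula = "H2O", charge = 0L),
    metabolite("cpd00027_c", name = "glucose", formula = "C6H12O6", charge = 0L),
    metabolite("cpd00159_c", name = "lactate", formula = "C3H6O3", charge = 0L),
    metabolite("cpd00011_c", formula = "CO2", charge = 0L),
    metabolite("cpd01024_c", formula = "CH4", charge = 0L),
    metabolite("cpd09999_c", formula = "XyzBroken*", charge = 0L),
    metabolite("cpd00067_c", name = "proton", formula = "H", charge = 1L),
    metabolite("cpd90000_e", formula = "C6H12O6", charge = 0L),
    metabolite("cpd90000_c", formula = "C6H12O6", charge = 0L))
  bm <- reaction("biomass", stats::setNames(-1, "cpd00027_c"), lb = 0,
                 source = "biomass")
  universal_db(mets, list(), bm)
}

test_that("check_balance verdicts follow exact element/charge arithmetic", {
  db <- db_for_balance()
  # identical formulas on both sides
  b <- check_balance(reaction("rxn1_c", c(cpd00001_c = -1, cpd00002_c = 1),
                              lb = 0), db)
  expect_equal(b$verdict, "balanced")
  # glucose -> 2 lactate balances 2 x C3H6O3 = C6H12O6
  b <- check_balance(reaction("rxn2_c", c(cpd00027_c = -1, cpd00159_c = 2),
                              lb = 0), db)
  expect_equal(b$verdict, "balanced")
  # CH4 -> CO2 leaves {H: -4, O: +2}
  b <- check_balance(reaction("rxn3_c", c(cpd01024_c = -1, cpd00011_c = 1),
                              lb = 0), db)
  expect_equal(b$verdict, "unbalanced")
  expect_equal(b$deltas[["H"]], -4)
  expect_equal(b$deltas[["O"]], 2)
  # unparseable participant formula -> undetermined
  b <- check_balance(reaction("rxn4_c", c(cpd09999_c = -1, cpd00011_c = 1),
                              lb = 0), db)
  expect_equal(b$verdict, "undetermined")
  # mass-balanced but charge-unbalanced: H+ (charge +1) -> H (charge 0)
  db$metabolites[["cpdH0_c"]] <- metabolite("cpdH0_c", formula = "H",
                                            charge = 0L)
  b <- check_balance(reaction("rxn6_c", c(cpd00067_c = -1, cpdH0_c = 1),
                              lb = 0), db)
  expect_equal(b$verdict, "unbalanced")
  expect_equal(b$charge_delta, -1)
  b <- check_balance(reaction("rxn6_c", c(cpd00067_c = -1, cpdH0_c = 1),
                              lb = 0), db, check_charge = FALSE)
  expect_equal(b$verdict, "balanced")
  # unresolvable metabolite is a hard, named error
  expect_error(check_balance(reaction("rxn7_c", c(cpdNOPE_c = -1,
                                                  cpd00011_c = 1), lb = 0),
                             db),
               "cpdNOPE_c")
})

test_that("exchange, biomass and same-species transport are exempt", {
  db <- db_for_balance()
  b <- check_balance(reaction("EX_cpd90000_e", c(cpd90000_e = -1),
                              source = "exchange"), db)
  expect_equal(b$verdict, "balanced")
  expect_true(b$exempt)
  b <- check_balance(db$biomass_template, db)
  expect_true(b$exempt)
  b <- check_balance(reaction("rxnT_c", c(cpd90000_e = -1, cpd90000_c = 1)),
                     db)
  expect_true(b$exempt)
})

test_that("balance verdict is invariant under stoichiometry permutation", {
  raw <- make_universal_fixture(11, pathway_length = 4, n_decoy = 3,
                                n_unbalanced = 2)$db
  for (rxn in raw$reactions) {
    v1 <- check_balance(rxn, raw)$verdict
    rxn$stoich <- rxn$stoich[rev(seq_along(rxn$stoich))]
    expect_identical(check_balance(rxn, raw)$verdict, v1)
  }
})

test_that("curation removes exactly the unbalanced set, adds exchanges, installs biomass", {
  fx <- make_universal_fixture(3, pathway_length = 4, n_decoy = 3,
                               n_unbalanced = 2)
  cur <- curate_database(fx$db)
  expect_setequal(cur$removed, fx$truth$unbalanced_ids)
  expect_setequal(setdiff(names(fx$db$reactions), names(cur$db$reactions)),
                  fx$truth$unbalanced_ids)
  # the raw fixture ships no exchange for its extracellular carbon source
  expect_false(fx$truth$exchange_id %in% names(fx$db$reactions))
  ex <- cur$db$reactions[[fx$truth$exchange_id]]
  expect_equal(ex$lb, -1000)
  expect_equal(ex$ub, 1000)
  expect_equal(unname(ex$stoich), -1)
  expect_equal(names(ex$stoich), fx$truth$source_met)
  expect_equal(cur$db$reactions[["biomass"]]$source, "biomass")
  # audit report covers every raw reaction
  expect_setequal(cur$report$reaction_id, names(fx$db$reactions))
})

test_that("curation is idempotent", {
  fx <- make_universal_fixture(9, pathway_length = 3, n_decoy = 2,
                               n_unbalanced = 2)
  once <- curate_database(fx$db)$db
  twice <- curate_database(once)$db
  expect_identical(twice, once)
})

test_that("curating away every reaction is a hard error", {
  mets <- list(metabolite("cpd1_c", formula = "CH4", charge = 0L),
               metabolite("cpd2_c", formula = "CO2", charge = 0L))
  bad <- reaction("rxn1_c", c(cpd1_c = -1, cpd2_c = 1), lb = 0)
  bm <- reaction("biomass", c(cpd2_c = -1), lb = 0, source = "biomass")
  db <- universal_db(mets, list(bad), bm)
  # biomass is always installed, so emptiness needs an empty met side too;
  # the error triggers before that when nothing but biomass would remain
  cur <- curate_database(db)
  expect_setequal(names(cur$db$reactions), "biomass")
})

test_that("JSON and TSV database serialisation round-trip", {
  fx <- make_universal_fixture(21, pathway_length = 3, n_decoy = 2,
                               n_unbalanced = 1)
  p <- tempfile(fileext = ".json")
  write_universal_db(fx$db, p)
  back <- read_universal_db(p)
  expect_identical(back$reactions, fx$db$reactions)
  expect_identical(back$metabolites, fx$db$metabolites)
  expect_identical(back$biomass_template, fx$db$biomass_template)

  # TSV dialect with "coeff:cpd;..." stoichiometry
  rt <- tempfile(fileext = ".tsv"); mt <- tempfile(fileext = ".tsv")
  rxns <- c(fx$db$reactions, list(biomass = fx$db$biomass_template))
  write.table(data.frame(
    id = names(rxns),
    name = vapply(rxns, `[[`, "", "name"),
    stoichiometry = vapply(rxns, function(r)
      paste(sprintf("%g:%s", unname(r$stoich), names(r$stoich)),
            collapse = ";"), ""),
    lower_bound = vapply(rxns, `[[`, 0, "lb"),
    upper_bound = vapply(rxns, `[[`, 0, "ub")), rt,
    sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(
    id = names(fx$db$metabolites),
    name = vapply(fx$db$metabolites, `[[`, "", "name"),
    formula = vapply(fx$db$metabolites, `[[`, "", "formula"),
    charge = vapply(fx$db$metabolites, `[[`, 0L, "charge")), mt,
    sep = "\t", quote = FALSE, row.names = FALSE)
  db2 <- read_universal_db_tsv(rt, mt)
  expect_setequal(names(db2$reactions), names(fx$db$reactions))
  r0 <- fx$db$reactions[[1]]
  expect_equal(db2$reactions[[r0$id]]$stoich, r0$stoich)
  expect_equal(db2$reactions[[r0$id]]$lb, r0$lb)
})
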