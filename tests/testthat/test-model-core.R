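# Media application, FBA/pFBA, GPR logic, essentiality, flux sampling.

chain_model <- function(uptake = 10, internal_ub = 1000) {
  mets <- lapply(c("cpd98001_e", "cpd98001_c", "cpd98002_c"),
                 function(m) metabolite(m, formula = "CH2O", charge = 0L))
  rx <- list(
    reaction("EX_cpd98001_e", c(cpd98001_e = -1), lb = -uptake, ub = 1000,
             source = "exchange"),
    reaction("rxn98001_c", c(cpd98001_e = -1, cpd98001_c = 1), lb = -1000,
             gpr = "g1"),
    reaction("rxn98002_c", c(cpd98001_c = -1, cpd98002_c = 1), lb = 0,
             ub = internal_ub, gpr = "g2 or g3"),
    reaction("biomass", c(cpd98002_c = -1), lb = 0, source = "biomass"))
  genre("chain", mets, rx, objective = "biomass")
}

test_that("set_media opens, restricts and warns as specified", {
  m <- chain_model()
  m2 <- set_media(m, media_complete())
  ex <- names(m2$reactions)[vapply(m2$reactions, genrecon:::is_exchange, TRUE)]
  expect_true(all(vapply(m2$reactions[ex], `[[`, 0, "lb") == -1000))

  md <- media_condition("glc", uptake = c(cpd98001_e = 10))
  m3 <- set_media(m, md)
  expect_equal(m3$reactions[["EX_cpd98001_e"]]$lb, -10)
  expect_equal(m3$reactions[["EX_cpd98001_e"]]$ub, 1000)

  md2 <- media_condition("ghost", uptake = c(cpd99999_e = 5))
  expect_warning(m4 <- set_media(m, md2), "no exchange")
  expect_equal(m4$reactions[["EX_cpd98001_e"]]$lb, 0) # everything closed
})

test_that("FBA reproduces closed-form chain optima", {
  expect_equal(fba(chain_model(uptake = 10))$objective_value, 10,
               tolerance = 1e-9)
  # internal bottleneck caps growth
  expect_equal(fba(chain_model(uptake = 10, internal_ub = 4))$objective_value,
               4, tolerance = 1e-9)
  # closed exchanges: nothing in, nothing grows
  m <- set_media(chain_model(), media_condition("empty",
                                                uptake = c(cpd98001_e = 1)))
  m$reactions[["EX_cpd98001_e"]]$lb <- 0
  expect_equal(fba(m)$objective_value, 0, tolerance = 1e-9)
  # invariance under reaction/metabolite reordering
  m <- chain_model()
  m$reactions <- rev(m$reactions)
  m$metabolites <- rev(m$metabolites)
  expect_equal(fba(m)$objective_value, 10, tolerance = 1e-9)
})

test_that("pFBA keeps the optimum but routes flux through the shorter path", {
  m <- parallel_route_model(uptake = 10)
  pf <- pfba(m)
  expect_equal(pf$objective_value, 10, tolerance = 1e-8)
  # the 3-step route is dead at the parsimonious optimum
  expect_lt(max(abs(pf$flux[c("rxn97003_c", "rxn97004_c", "rxn97005_c")])),
            1e-7)
  expect_gt(min(pf$flux[c("rxn97001_c", "rxn97002_c")]), 10 - 1e-7)
  # hand-derived totals: uptake 10 + transport 10 + 2 x 10 + biomass 10
  expect_equal(pf$total_flux, 50, tolerance = 1e-7)
  # the 3-step alternative costs strictly more flux
  m_long <- m
  for (rid in c("rxn97001_c", "rxn97002_c"))
    m_long$reactions[[rid]]$ub <- 0
  expect_equal(pfba(m_long)$total_flux, 60, tolerance = 1e-7)
})

test_that("pFBA total flux is minimal among sampled optimal alternatives", {
  m <- parallel_route_model(uptake = 10)
  pf <- pfba(m)
  # pin the objective at its optimum and sample feasible alternatives
  m2 <- m
  m2$reactions[["biomass"]]$lb <- 10
  s <- sample_fluxes(m2, n = 40, seed = 7)
  totals <- rowSums(abs(s))
  expect_true(all(pf$total_flux <= totals + 1e-6))
})

test_that("GPR evaluation follows boolean semantics", {
  expect_true(evaluate_gpr("g1 or g2", knocked = "g1"))
  expect_false(evaluate_gpr("g1 and g2", knocked = "g1"))
  expect_true(evaluate_gpr("", knocked = "g1"))
  expect_true(evaluate_gpr("(g1 and g2) or g3", knocked = c("g1")))
  expect_false(evaluate_gpr("(g1 or g2) and g3", knocked = c("g1", "g3")))
  expect_setequal(gpr_genes("(g1 and g2) or g1"), c("g1", "g2"))
  expect_error(parse_gpr("g1 and"), "malformed")
  expect_error(parse_gpr("(g1 or g2"), "malformed")
  expect_error(parse_gpr("g1 g2"), "malformed")
})

test_that("single-gene deletion matches pathway structure", {
  m <- chain_model()
  res <- single_gene_deletion(m)
  expect_true(res$essential[res$gene == "g1"])   # unique transport
  expect_false(any(res$essential[res$gene %in% c("g2", "g3")])) # isozymes
  # make the isozyme pair a required complex instead
  m$reactions[["rxn98002_c"]]$gpr <- "g2 and g3"
  res <- single_gene_deletion(m)
  expect_true(all(res$essential[res$gene %in% c("g2", "g3")]))
  # a model that cannot grow has no defined essentiality
  m0 <- chain_model()
  m0$reactions[["EX_cpd98001_e"]]$lb <- 0
  expect_error(single_gene_deletion(m0), "does not grow")
})

test_that("flux samples are steady-state, in-bounds and seed-reproducible", {
  b <- fixture_bundle(41, pathway_length = 4)
  model <- b$draft
  s1 <- sample_fluxes(model, n = 50, seed = 1)
  s2 <- sample_fluxes(model, n = 50, seed = 1)
  expect_identical(s1, s2) # bitwise
  s3 <- sample_fluxes(model, n = 50, seed = 2)
  expect_false(identical(s1, s3))

  S <- as.matrix(stoich_matrix(model))
  expect_lt(max(abs(S %*% t(s1))), 1e-6)
  bnd <- genrecon:::reaction_bounds(model)
  expect_true(all(t(s1) >= bnd$lb - 1e-6))
  expect_true(all(t(s1) <= bnd$ub + 1e-6))
})

test_that("a single-point feasible region yields identical samples", {
  m <- chain_model(uptake = 10)
  # force uptake exactly 10: every flux in the chain is then determined
  m$reactions[["EX_cpd98001_e"]]$ub <- -10
  s <- sample_fluxes(m, n = 10, seed = 3)
  expect_equal(max(apply(s, 2, function(x) diff(range(x)))), 0,
               tolerance = 1e-9)
  expect_equal(unname(s[1, "biomass"]), 10, tolerance = 1e-7)
})
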