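test_that("composition dimension arithmetic is 2n+4 variables, 2m+2 rows", {
  toy <- get_toy()
  # without cell-specific deletions the closed form holds exactly
  tc0 <- compose_two_cell(toy,
                          veg = cell_spec("Vegetative"),
                          het = cell_spec("Heterocyst"))
  n <- n_reactions(toy); m <- n_metabolites(toy)
  expect_equal(unname(model_dimensions(tc0)),
               unname(two_cell_dimensions(n, m)))
  expect_equal(unname(two_cell_dimensions(10, 8)), c(24L, 18L))
  expect_equal(unname(two_cell_dimensions(1, 1)), c(6L, 4L))
  # deletions remove columns but keep balance rows
  tc <- get_diazo_tc()
  removed <- 1 + 5   # NIT from vegetative; 5 reactions from heterocyst
  expect_equal(unname(model_dimensions(tc)),
               unname(two_cell_dimensions(n, m)) - c(removed, 0L))
})

test_that("a zero photon budget stops autotrophic growth", {
  tc <- set_condition(compose_two_cell(get_toy(), photon_max = 0),
                      "diazotrophic_auto")
  # with the maintenance demand enforced, a dark autotroph is not even
  # feasible -- starvation, not zero growth
  expect_equal(fba(tc)$status, "infeasible")
  relaxed <- set_bounds(tc, c("Vegetative_NGAM", "Heterocyst_NGAM"), lb = 0)
  s <- fba(relaxed)
  expect_equal(s$status, "optimal")
  expect_lt(abs(s$objective_value), 1e-9)
})

test_that("cell-specific deletions silence the deleted function", {
  tc <- get_diazo_tc()
  expect_false("Heterocyst_PSII" %in% tc$reactions$id)
  expect_true("Vegetative_PSII" %in% tc$reactions$id)
  expect_false("Vegetative_NIT" %in% tc$reactions$id)
  s <- fba(tc)
  # heterocysts evolve no O2: nothing in that copy produces it
  expect_equal(metabolite_turnover(tc, s, "Heterocyst_o2_c"),
               max(0, -s$fluxes[["Heterocyst_EX_o2"]]) +
                 max(0, 0), tolerance = 1e-6)
})

test_that("optimal solutions satisfy the photon budget and biomass coupling", {
  tc <- get_diazo_tc()
  s <- fba(tc)
  expect_equal(s$status, "optimal")
  vg <- s$fluxes[["Vegetative_BIOMASS"]]
  hg <- s$fluxes[["Heterocyst_BIOMASS"]]
  expect_equal(hg, 0.1 * vg, tolerance = 1e-9)
  uptake <- -(s$fluxes[["Vegetative_EX_photon"]] +
                s$fluxes[["Heterocyst_EX_photon"]])
  expect_gte(s$fluxes[["photon_slack"]], -1e-9)
  expect_equal(uptake + s$fluxes[["photon_slack"]], tc$photon_max,
               tolerance = 1e-6)
  expect_equal(total_growth(s, tc), 1.1 * vg, tolerance = 1e-12)
})

test_that("condition presets rewire the uptakes they document", {
  tc <- get_diazo_tc()
  lbof <- function(m, id) m$reactions$lower_bound[m$reactions$id == id]
  expect_equal(lbof(tc, "Vegetative_EX_no3"), 0)
  expect_equal(lbof(tc, "Heterocyst_EX_no3"), 0)
  expect_equal(lbof(tc, "Heterocyst_EX_n2"), -1000)
  expect_equal(lbof(tc, "Vegetative_EX_n2"), 0)
  expect_equal(lbof(tc, "Heterocyst_EX_hco3"), 0)
  ht <- set_condition(tc, "heterotrophic")
  expect_equal(lbof(ht, "Vegetative_EX_photon"), 0)
  expect_equal(lbof(ht, "Vegetative_EX_frc"), -1)
  expect_equal(lbof(ht, "Vegetative_EX_hco3"), 0)
  expect_error(set_condition(tc, "mystery"))
})

test_that("nitrate is a relaxation of the diazotrophic condition", {
  tc <- get_diazo_tc()
  g_diazo <- fba(tc)$objective_value
  g_no3 <- fba(set_condition(tc, "nitrate_auto"))$objective_value
  expect_gte(g_no3, g_diazo - 1e-8)
  expect_gt(g_diazo, 0.001)
})

test_that("without the shuttles the filament cannot fix nitrogen", {
  tc <- get_diazo_tc()
  closed <- set_bounds(tc, tc$shuttle_ids, lb = 0, ub = 0)
  expect_lt(abs(fba(closed)$objective_value), 1e-9)
})

test_that("raising the heterocyst fraction does not raise growth", {
  toy <- get_toy()
  g <- vapply(c(0.05, 0.075, 0.10), function(f) {
    fba(set_condition(compose_two_cell(toy, heterocyst_fraction = f),
                      "diazotrophic_auto"))$objective_value
  }, numeric(1))
  expect_true(all(diff(g) <= 1e-9))
  expect_gt(g[1], g[3])   # the trend is strict on the toy
})

test_that("sucrose flows vegetative -> heterocyst in the L1 solution", {
  tc <- get_diazo_tc()
  opt <- fba(tc)$objective_value
  l1 <- l1_minimal_solution(tc, fixed = stats::setNames(list(opt),
                                                        tc$objective_id))
  expect_gt(l1$fluxes[["SHUTTLE_suc_p"]], 1e-6)
  # and the shuttle stays vegetative->heterocyst across all optima
  rng <- fva(set_bounds(tc, tc$objective_id, lb = opt - 1e-9),
             "SHUTTLE_suc_p", fraction_of_optimum = 0)
  expect_gte(rng$min, -1e-8)
})

test_that("relative growth behaves as a relaxation ratio", {
  toy <- get_toy()
  # closing the extra source reproduces the reference: ratio 1
  expect_equal(relative_growth(toy, "EX_frc", uptake = 0), 1,
               tolerance = 1e-9)
  # fructose adds carbon and energy: ratio above 1
  expect_gt(relative_growth(toy, "EX_frc", uptake = 1), 1)
  dead <- set_bounds(toy, "EX_photon", lb = 0)
  dead <- set_bounds(dead, "EX_hco3", lb = 0)
  expect_error(relative_growth(dead, "EX_frc"), "zero")
})
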