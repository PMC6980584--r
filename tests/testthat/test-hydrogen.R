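test_that("no net hydrogen is secreted at the optimal growth rate", {
  tc <- get_diazo_tc()
  s <- fba(tc)
  expect_lt(abs(s$fluxes[["Heterocyst_EX_h2"]]), 1e-8)
  expect_lt(abs(s$fluxes[["Vegetative_EX_h2"]]), 1e-8)
})

test_that("forcing H2 in the vegetative cell raises its O2 production", {
  tc <- get_diazo_tc()
  gstar <- 0.7 * fba(tc)$objective_value
  o2_need <- vapply(c(0, 0.05, 0.1, 0.2), function(h) {
    m <- fix_net_flux(tc, tc$objective_id, gstar)
    m <- fix_net_flux(m, "Vegetative_EX_h2", h)
    fba(m, objective_coefs = c(Vegetative_EX_o2 = 1),
        maximize = FALSE)$objective_value
  }, numeric(1))
  expect_true(all(diff(o2_need) > 1e-8))
})

test_that("forcing H2 in the heterocyst lowers its O2 consumption ceiling", {
  tc <- get_diazo_tc()
  gstar <- 0.7 * fba(tc)$objective_value
  o2_cons <- vapply(c(0, 0.05, 0.1, 0.2), function(h) {
    m <- fix_net_flux(tc, tc$objective_id, gstar)
    m <- fix_net_flux(m, "Heterocyst_EX_h2", h)
    -fba(m, objective_coefs = c(Heterocyst_EX_o2 = 1),
         maximize = FALSE)$objective_value
  }, numeric(1))
  expect_true(all(diff(o2_cons) < -1e-8))
})

test_that("the H2 = 0 surface row reproduces 1-D O2 robustness", {
  tc <- get_diazo_tc()
  ex <- h2_experiment("Heterocyst")
  o2 <- c(-0.2, -0.05, 0)
  surf <- h2_o2_surface(tc, ex, h2_grid = 0, o2_grid = o2)
  oned <- vapply(o2, function(v) {
    m <- fix_net_flux(tc, "Heterocyst_EX_h2", 0)
    fba(fix_net_flux(m, "Heterocyst_EX_o2", v))$objective_value
  }, numeric(1))
  expect_equal(unname(surf[1, ]), oned, tolerance = 1e-6)
  # growth falls with forced H2 at constant O2 exchange
  surf2 <- h2_o2_surface(tc, ex, h2_grid = c(0, 0.1, 0.2), o2_grid = o2)
  expect_true(all(apply(surf2, 2, diff) <= 1e-9))
})

test_that("H2 range at suboptimal growth is consistent and FVA-checked", {
  tc <- get_diazo_tc()
  ex <- h2_experiment("Heterocyst")
  rng <- h2_range_at_suboptimal_growth(tc, ex)
  expect_gte(rng$h2_min, -1e-9)
  expect_gt(rng$h2_max, 0.01)
  # both L1 distributions satisfy the growth fixing
  expect_equal(unname(rng$sol_min$fluxes[tc$objective_id]),
               rng$growth_fixed, tolerance = 1e-9)
  expect_equal(unname(rng$sol_max$fluxes[tc$objective_id]),
               rng$growth_fixed, tolerance = 1e-9)
  # FVA of the H2 exchange at the same growth floor agrees
  m <- set_bounds(tc, tc$objective_id, lb = rng$growth_fixed,
                  ub = rng$growth_fixed)
  rr <- fva(m, "Heterocyst_EX_h2", fraction_of_optimum = 0)
  expect_equal(rr$min, rng$h2_min, tolerance = 1e-6)
  expect_equal(rr$max, rng$h2_max, tolerance = 1e-6)
})

test_that("relaxing growth from 100% to 90% frees hydrogen", {
  tc <- get_diazo_tc()
  full <- h2_range_at_suboptimal_growth(tc, h2_experiment("Heterocyst",
                                                          growth_fraction = 1))
  part <- h2_range_at_suboptimal_growth(tc, h2_experiment("Heterocyst",
                                                          growth_fraction = 0.9))
  expect_lte(full$h2_max, part$h2_max + 1e-8)
})

test_that("deleting every H2-evolving reaction zeroes the maximum", {
  tc <- get_diazo_tc()
  ex <- h2_experiment("Heterocyst")
  # keep the filament alive on nitrate while all H2 sources are gone
  m <- set_condition(tc, "nitrate_auto")
  m <- remove_reactions(m, c("Heterocyst_NIT",
                             "Heterocyst_HOXN", "Heterocyst_HOXP",
                             "Heterocyst_HUP"))
  rng <- h2_range_at_suboptimal_growth(m, ex)
  expect_lt(abs(rng$h2_max), 1e-8)
})

test_that("differential flux classification is threshold-consistent", {
  tc <- get_diazo_tc()
  ex <- h2_experiment("Heterocyst")
  rng <- h2_range_at_suboptimal_growth(tc, ex)
  rep_ <- differential_flux(tc, rng$sol_min, rng$sol_max, ex)
  expect_true(nrow(rep_$up) > 0)
  expect_length(intersect(rep_$up$reaction_id, rep_$down$reaction_id), 0)
  expect_equal(nrow(rep_$up) + nrow(rep_$down) + rep_$unchanged,
               n_reactions(tc))
  # identical solutions leave everything unchanged
  same <- differential_flux(tc, rng$sol_min, rng$sol_min, ex)
  expect_equal(nrow(same$up), 0L)
  expect_equal(nrow(same$down), 0L)
  # Hup recycling is not higher in the max-H2 state
  hup_min <- rng$sol_min$fluxes[["Heterocyst_HUP"]]
  hup_max <- rng$sol_max$fluxes[["Heterocyst_HUP"]]
  expect_lte(hup_max, hup_min + 1e-8)
})

test_that("the Hox fraction is a fraction and vanishes without Hox", {
  tc <- get_diazo_tc()
  ex <- h2_experiment("Heterocyst")
  rng <- h2_range_at_suboptimal_growth(tc, ex)
  f <- hox_fraction(tc, rng$sol_max, ex)
  expect_gte(f, 0); expect_lte(f, 1)
  expect_gt(f, 0.1)   # Hox carries real H2 flux in the max state
  ko <- knockout_reactions(tc, c("Heterocyst_HOXN", "Heterocyst_HOXP"))
  rng2 <- h2_range_at_suboptimal_growth(ko, ex)
  expect_equal(hox_fraction(ko, rng2$sol_max, ex), 0)
})

test_that("knockouts move maximal H2 the way the biology predicts", {
  tc <- get_diazo_tc()
  ex <- h2_experiment("Heterocyst")
  hup <- knockout_h2(tc, ex, "Heterocyst_HUP")
  expect_gte(hup$h2_max_ko, hup$h2_max_wt - 1e-8)
  hox <- knockout_h2(tc, ex, c("Heterocyst_HOXN", "Heterocyst_HOXP"))
  expect_lte(hox$h2_max_ko, hox$h2_max_wt + 1e-8)
  expect_lt(hox$h2_max_ko, hox$h2_max_wt - 1e-3)   # strictly worse
  # an inactive reaction (fructose uptake is closed here) changes nothing
  inert <- knockout_h2(tc, ex, "Vegetative_EX_frc")
  expect_equal(inert$h2_max_ko, inert$h2_max_wt, tolerance = 1e-8)
})

test_that("hydrogen analyses run identically on the regulated model", {
  em <- get_expanded()
  expr <- make_expression(get_toy(), toy_scenario("psii_bottleneck"))
  rm_ <- suppressWarnings(add_expression_constraints(em, expr, C = 0.05))
  ex <- h2_experiment("Heterocyst")
  rng <- h2_range_at_suboptimal_growth(rm_, ex)
  expect_gt(rng$h2_max, 0)
  expect_gte(rng$h2_min, -1e-9)
  rep_ <- differential_flux(rm_, rng$sol_min, rng$sol_max, ex)
  expect_gte(rep_$hox_fraction_max, 0)
  expect_lte(rep_$hox_fraction_max, 1)
  surf <- h2_o2_surface(rm_, ex, h2_grid = c(0, 0.1), o2_grid = c(-0.1, 0))
  expect_true(all(is.finite(surf)))
  expect_true(all(apply(surf, 2, diff) <= 1e-9))
})
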