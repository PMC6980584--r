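test_that("reversible reactions split into two supported directions", {
  m <- new_metabolic_model(
    id = "rev",
    metabolites = data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                             compartment = "cytoplasm"),
    reactions = data.frame(id = c("EX_A", "R1", "EX_B"),
                           lower_bound = c(-5, -1000, 0),
                           upper_bound = 1000,
                           gpr = c("", "g1", ""), subsystem = ""),
    stoich = list(EX_A = c(A_c = -1), R1 = c(A_c = -1, B_c = 1),
                  EX_B = c(B_c = -1)),
    objective_id = "EX_B")
  em <- to_irreversible_no_or(m)
  expect_setequal(em$mapping$expanded_id[em$mapping$orig_id == "R1"],
                  c("R1", "R1_rev"))
  expect_setequal(em$K[["g1"]], c("R1", "R1_rev"))
  expect_true(all(em$model$reactions$lower_bound >= 0))
})

test_that("OR rules duplicate reactions into per-isozyme copies", {
  m <- new_metabolic_model(
    id = "iso",
    metabolites = data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                             compartment = "cytoplasm"),
    reactions = data.frame(id = c("EX_A", "R1", "EX_B"),
                           lower_bound = c(-5, 0, 0), upper_bound = 1000,
                           gpr = c("", "(g1 and g2) or g3", ""),
                           subsystem = ""),
    stoich = list(EX_A = c(A_c = -1), R1 = c(A_c = -1, B_c = 1),
                  EX_B = c(B_c = -1)),
    objective_id = "EX_B")
  em <- to_irreversible_no_or(m)
  copies <- em$mapping$expanded_id[em$mapping$orig_id == "R1"]
  expect_length(copies, 2L)
  expect_setequal(em$K[["g1"]], "R1_iso1")
  expect_setequal(em$K[["g2"]], "R1_iso1")
  expect_setequal(em$K[["g3"]], "R1_iso2")
  # the isozyme copies jointly reproduce the original flux space
  expect_equal(fba(em$model)$objective_value, fba(m)$objective_value,
               tolerance = 1e-8)
})

test_that("expansion preserves the FBA optimum of the two-cell toy", {
  tc <- get_diazo_tc()
  em <- get_expanded()
  expect_equal(fba(em$model)$objective_value, fba(tc)$objective_value,
               tolerance = 1e-6)
  # and random feasible points project both ways: mapped fluxes of the
  # expanded optimum are feasible for the original model
  sol <- fba(em$model)
  v <- map_fluxes(em, sol)
  S <- stoich_matrix(tc)
  expect_lt(max(abs(S %*% v[colnames(S)])), 1e-6)
  lbv <- stats::setNames(tc$reactions$lower_bound, tc$reactions$id)
  ubv <- stats::setNames(tc$reactions$upper_bound, tc$reactions$id)
  expect_true(all(v >= lbv[names(v)] - 1e-9))
  expect_true(all(v <= ubv[names(v)] + 1e-9))
})

test_that("zero expression forces the supported reactions to zero", {
  em <- get_expanded()
  expr <- make_expression(get_toy(), toy_scenario("baseline"))
  expr$E_veg[expr$gene_id == "rbpc_toy"] <- 0
  rm0 <- suppressWarnings(add_expression_constraints(em, expr, C = 0.05))
  sol <- regulated_fba(rm0)
  expect_equal(unname(sol$mapped_fluxes["Vegetative_RBPC"]), 0,
               tolerance = 1e-9)
  # without carbon fixation in the vegetative cell the filament starves
  expect_lt(sol$objective_value, 1e-6)
})

test_that("generous capacity reproduces the unregulated optimum", {
  em <- get_expanded()
  expr <- make_expression(get_toy(), toy_scenario("psii_bottleneck"))
  unreg <- fba(em$model)$objective_value
  rmBig <- suppressWarnings(add_expression_constraints(em, expr, C = 1e6))
  expect_lt(abs(regulated_fba(rmBig)$objective_value - unreg), 1e-6)
})

test_that("regulated growth is monotone non-decreasing in C", {
  em <- get_expanded()
  expr <- make_expression(get_toy(), toy_scenario("psii_bottleneck"))
  g <- vapply(c(0.01, 0.02, 0.05, 0.2, 1), function(C) {
    rm_ <- suppressWarnings(add_expression_constraints(em, expr, C))
    regulated_fba(rm_)$objective_value
  }, numeric(1))
  expect_true(all(diff(g) >= -1e-8))
  # the bottleneck really binds at small C
  expect_lt(g[1], fba(em$model)$objective_value - 1e-4)
})

test_that("the PSII bottleneck caps PSII flux at E x C", {
  em <- get_expanded()
  expr <- make_expression(get_toy(), toy_scenario("psii_bottleneck"))
  rm_ <- suppressWarnings(add_expression_constraints(em, expr, C = 0.05))
  expect_equal(rm_$n_added_rows, rm_$n_added_vars)
  sol <- regulated_fba(rm_)
  expect_equal(unname(sol$mapped_fluxes["Vegetative_PSII"]), 56 * 0.05,
               tolerance = 1e-6)
  expect_lt(sol$objective_value, fba(em$model)$objective_value)
})

test_that("scan_C recovers a planted observation and a clean error curve", {
  em <- get_expanded()
  expr <- make_expression(get_toy(), toy_scenario("psii_bottleneck"))
  grid <- 10^seq(-3, 0, length.out = 7)
  planted_C <- grid[3]
  rm_ <- suppressWarnings(add_expression_constraints(em, expr, planted_C))
  fac <- em$model$total_growth_factor
  observed <- fac * regulated_fba(rm_)$objective_value
  out <- scan_C(em, expr, c_grid = grid, observed_growth = observed)
  expect_equal(out$C_opt, planted_C)
  expect_equal(min(out$curve$rel_error), 0, tolerance = 1e-9)
  expect_false(any(is.na(out$curve$predicted)))
  # predictions are non-decreasing along the grid
  expect_true(all(diff(out$curve$predicted) >= -1e-8))
  # the prediction at the recovered C matches the planted growth within 2%
  pred <- out$curve$predicted[out$curve$C == out$C_opt]
  expect_lt(abs(pred - observed) / observed, 0.02)
  expect_error(scan_C(em, expr, c_grid = grid, observed_growth = 0),
               "positive")
})

test_that("only the planted bottleneck gene carries a shadow price", {
  em <- get_expanded()
  expr <- make_expression(get_toy(), toy_scenario("psii_bottleneck"))
  rm_ <- suppressWarnings(add_expression_constraints(em, expr, C = 0.05))
  sol <- regulated_fba(rm_)
  sp <- gene_shadow_prices(rm_, sol)
  hot <- sp[abs(sp$dual) > 1e-8, ]
  expect_equal(nrow(hot), 1L)
  expect_equal(hot$cell, "Vegetative")
  expect_equal(hot$gene, "psbJ_toy")
  expect_gt(hot$dual, 0)
  expect_equal(hot$per_expression_unit, hot$dual * 0.05)
})

test_that("the bottleneck dual matches a finite-difference perturbation", {
  em <- get_expanded()
  expr <- make_expression(get_toy(), toy_scenario("psii_bottleneck"))
  C <- 0.05
  rm_ <- suppressWarnings(add_expression_constraints(em, expr, C))
  sol <- regulated_fba(rm_)
  sp <- gene_shadow_prices(rm_, sol)
  dual <- sp$dual[sp$cell == "Vegetative" & sp$gene == "psbJ_toy"]
  # bump E by one unit: rhs moves by C, objective by about dual * C
  h <- 1
  expr2 <- expr
  expr2$E_veg[expr2$gene_id == "psbJ_toy"] <- 56 + h
  rm2 <- suppressWarnings(add_expression_constraints(em, expr2, C))
  fd <- (regulated_fba(rm2)$objective_value - sol$objective_value) / (h * C)
  expect_equal(dual, fd, tolerance = 1e-5)
})

test_that("complementary slackness holds for every gene row", {
  em <- get_expanded()
  expr <- make_expression(get_toy(), toy_scenario("psii_bottleneck"))
  rm_ <- suppressWarnings(add_expression_constraints(em, expr, C = 0.05))
  sol <- regulated_fba(rm_)
  sp <- gene_shadow_prices(rm_, sol)
  expect_true(all(abs(sp$dual * sp$slack) < 1e-6))
  expect_true(all(sp$slack > -1e-9))
})

test_that("genes without supported reactions are skipped with a warning", {
  em <- get_expanded()
  expr <- make_expression(get_toy(), toy_scenario("baseline"))
  # nif_toy maps to nothing in the vegetative copy (nitrogenase removed)
  expect_warning(add_expression_constraints(em, expr, C = 0.05),
                 "skipped")
})
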