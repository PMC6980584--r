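test_that("a single-path chain carries exactly its uptake limit", {
  m <- chain_model(uptake = 5)
  s <- fba(m)
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 5, tolerance = 1e-9)
  expect_equal(unname(s$fluxes), c(-5, 5, 5), tolerance = 1e-9)
  expect_lt(s$residual, 1e-6)
})

test_that("FBA on small branched networks matches the brute-force oracle", {
  set.seed(31)
  for (k in 1:10) {
    # random 2-metabolite, <=5-reaction network with a feasible interior
    n <- sample(3:5, 1)
    A <- matrix(sample(c(-1, 0, 1, 2), 2 * n, replace = TRUE), 2, n)
    lb <- ifelse(stats::runif(n) < 0.4, -3, 0)
    ub <- rep(4, n)
    obj <- round(stats::runif(n, -1, 1), 1)
    got <- solve_lp(obj, A, c(0, 0), lb, ub)
    if (got$status != "optimal") next
    want <- brute_force_lp(obj, A, c(0, 0), lb, ub)
    expect_equal(got$objective, want$objective, tolerance = 1e-8)
  }
})

test_that("FVA collapses to a point on a fully determined chain", {
  m <- chain_model(5)
  out <- fva(m, fraction_of_optimum = 1)
  expect_equal(out$min, out$max, tolerance = 1e-8)
  expect_equal(out$max[out$reaction_id == "V1"], 5, tolerance = 1e-8)
})

test_that("FVA spreads a fixed total over parallel duplicate branches", {
  m <- parallel_model(10)
  out <- fva(m, c("V1", "V2"), fraction_of_optimum = 1)
  expect_equal(out$min, c(0, 0), tolerance = 1e-8)
  expect_equal(out$max, c(10, 10), tolerance = 1e-8)
  # pinning one branch inside its range keeps the optimum intact
  opt <- fba(m)$objective_value
  pinned <- set_bounds(m, "V1", lb = 3, ub = 3)
  expect_gte(fba(pinned)$objective_value, opt - 1e-8)
})

test_that("FVA at fraction 0 reduces to plain bound propagation", {
  m <- chain_model(5)
  out <- fva(m, fraction_of_optimum = 0)
  expect_equal(out$min[out$reaction_id == "EX_B"], 0, tolerance = 1e-8)
  expect_equal(out$max[out$reaction_id == "EX_B"], 5, tolerance = 1e-8)
})

test_that("L1 minimisation finds the shortest-path norm", {
  m <- parallel_model(10)
  l1 <- l1_minimal_solution(m, fixed = list(EX_B = 10))
  expect_equal(l1$status, "optimal")
  # |EX_A| + (V1 + V2) + EX_B = 30 however the branches split
  expect_equal(l1$l1_norm, 30, tolerance = 1e-8)
})

test_that("L1 solution preserves a fixed objective and beats plain FBA", {
  toy <- get_toy()
  s <- fba(toy)
  l1 <- l1_minimal_solution(toy, fixed = stats::setNames(
    list(s$objective_value), toy$objective_id))
  expect_equal(unname(l1$fluxes[toy$objective_id]), s$objective_value,
               tolerance = 1e-6)
  expect_lte(l1$l1_norm, sum(abs(s$fluxes[toy$reactions$id])) + 1e-8)
  expect_lt(l1$residual, 1e-6)
})

test_that("closing all exchanges leaves the zero flux vector", {
  toy <- get_toy()
  ex <- toy$reactions$id[is_exchange_reaction(toy)]
  m <- set_bounds(toy, ex, lb = 0, ub = 0)
  m <- set_bounds(m, "NGAM", lb = 0)   # no maintenance without inputs
  l1 <- l1_minimal_solution(m)
  expect_equal(l1$status, "optimal")
  expect_equal(l1$l1_norm, 0, tolerance = 1e-8)
})

test_that("2-D robustness recovers the optimum at an optimal fixing", {
  toy <- get_toy()
  s <- fba(toy)
  g <- robustness_2d(toy, "EX_photon", s$fluxes[["EX_photon"]],
                     "EX_hco3", s$fluxes[["EX_hco3"]])
  expect_equal(dim(g), c(1L, 1L))
  expect_equal(g[1, 1], s$objective_value, tolerance = 1e-6)
  # infeasible cells are NA, not zero
  bad <- robustness_2d(toy, "EX_photon", 0, "BIOMASS", 1)
  expect_true(is.na(bad[1, 1]))
})

test_that("metabolite turnover sums positive production", {
  m <- chain_model(2)
  s <- fba(m)
  expect_equal(metabolite_turnover(m, s, "A_c"), 2, tolerance = 1e-9)
  closed <- set_bounds(m, "EX_A", lb = 0)
  s0 <- fba(closed)
  expect_equal(metabolite_turnover(closed, s0, "A_c"), 0, tolerance = 1e-9)
  expect_error(metabolite_turnover(m, s, "nope_c"), "unknown")
})
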