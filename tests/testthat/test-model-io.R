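test_that("equation strings parse to signed stoichiometry maps", {
  p <- parse_equation("2 H[c] + 0.5 O2[c] -> H2O[c]", "r1")
  expect_equal(p$stoich[c("H_c", "O2_c", "H2O_c")],
               c(H_c = -2, O2_c = -0.5, H2O_c = 1))
  expect_false(p$reversible)
  expect_true(parse_equation("A[c] <-> B[p]")$reversible)
  # one-sided equations describe boundary exchanges
  ex <- parse_equation("A[e] <->")
  expect_equal(ex$stoich, c(A_e = -1))
  expect_equal(ex$metabolites$compartment, "extracellular")
  expect_error(parse_equation("A[q] -> B[c]", "r2"), "compartment")
  expect_error(parse_equation("A[c] B[c]", "r3"), "malformed")
})

test_that("a minimal tabular model loads with m=2, n=1", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation\tlower_bound\tupper_bound\tgpr\tsubsystem",
               "R1\tA[c] -> B[c]\t0\t1000\t\t"), tf)
  m <- load_model(tf, "tabular")
  expect_equal(n_metabolites(m), 2L)
  expect_equal(n_reactions(m), 1L)
  expect_equal(m$reactions$lower_bound, 0)
})

test_that("duplicate reaction ids in a tabular file are rejected", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation\tlower_bound\tupper_bound\tgpr\tsubsystem",
               "R1\tA[c] -> B[c]\t0\t1000\t\t",
               "R1\tB[c] -> A[c]\t0\t1000\t\t"), tf)
  expect_error(load_model(tf, "tabular"), "duplicate")
})

test_that("tabular write/load round-trips the toy network", {
  toy <- get_toy()
  tf <- tempfile(fileext = ".tsv")
  write_model(toy, tf, "tabular")
  back <- load_model(tf, "tabular")
  expect_identical(back$reactions$id, toy$reactions$id)
  expect_identical(back$reactions$gpr, toy$reactions$gpr)
  expect_equal(back$reactions$lower_bound, toy$reactions$lower_bound)
  expect_equal(back$reactions$upper_bound, toy$reactions$upper_bound)
  expect_identical(back$objective_id, toy$objective_id)
  for (id in toy$reactions$id) {
    a <- toy$stoich[[id]]; b <- back$stoich[[id]]
    expect_equal(b[sort(names(b))], a[sort(names(a))], tolerance = 1e-12)
  }
})

test_that("SBML write/read round-trips ids, bounds, GPRs and formulas", {
  toy <- get_toy()
  toy$reactions$gpr[toy$reactions$id == "PSII"] <- "(g1 and g2) or g3"
  xf <- tempfile(fileext = ".xml")
  write_model(toy, xf, "sbml")
  back <- load_model(xf, "sbml")
  expect_identical(back$reactions$id, toy$reactions$id)
  expect_identical(back$reactions$gpr, toy$reactions$gpr)
  expect_equal(back$reactions$lower_bound, toy$reactions$lower_bound)
  expect_identical(back$objective_id, toy$objective_id)
  expect_identical(back$reactions$subsystem, toy$reactions$subsystem)
  for (id in toy$reactions$id) {
    a <- toy$stoich[[id]]; b <- back$stoich[[id]]
    expect_equal(b[sort(names(b))], a[sort(names(a))], tolerance = 1e-12)
  }
  f1 <- stats::setNames(toy$metabolites$formula, toy$metabolites$id)
  f2 <- stats::setNames(back$metabolites$formula, back$metabolites$id)
  f1[is.na(f1)] <- ""; f2[is.na(f2)] <- ""
  expect_equal(f2[names(f1)], f1)
})

test_that("degenerate models are rejected when writing", {
  toy <- get_toy()
  empty <- toy
  empty$reactions <- empty$reactions[0, ]
  empty$stoich <- list()
  expect_error(write_model(empty, tempfile(), "tabular"), "must contain")
})

test_that("model validation catches broken invariants", {
  toy <- get_toy()
  bad <- toy
  bad$reactions$lower_bound[1] <- 2000
  expect_error(validate_model(bad), "lower_bound")
  bad2 <- toy
  bad2$metabolites$compartment[1] <- "vacuole"
  expect_error(validate_model(bad2), "compartment")
  bad3 <- toy
  bad3$stoich[[1]] <- c(nonexistent_c = 1)
  expect_error(validate_model(bad3), "unknown metabolite")
})
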