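# Brute-force LP oracle: enumerate all basic solutions (every basis of m
# columns x every lower/upper assignment of the nonbasic variables) of
#   max obj'x  s.t.  A x = b, lb <= x <= ub,
# and return the best feasible one. Exponential; fixtures keep n <= 6.
brute_force_lp <- function(obj, A, b, lb, ub, tol = 1e-9) {
  A <- as.matrix(A)
  # drop linearly dependent rows (keeping them only for feasibility checks)
  qt <- qr(t(A))
  keep <- sort(qt$pivot[seq_len(qt$rank)])
  A_full <- A; b_full <- b
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  m <- nrow(A); n <- ncol(A)
  best <- -Inf; best_x <- NULL
  for (basis in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, basis, drop = FALSE]
    if (abs(det(B)) < 1e-12) next
    nb <- setdiff(seq_len(n), basis)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nb)))
    if (!length(nb)) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      at_up <- if (length(nb)) unlist(grid[g, ]) else logical(0)
      x[nb] <- ifelse(at_up, ub[nb], lb[nb])
      if (any(!is.finite(x[nb]))) next
      rhs <- b - if (length(nb)) A[, nb, drop = FALSE] %*% x[nb] else 0
      xb <- solve(B, rhs)
      x[basis] <- xb
      if (all(x >= lb - tol) && all(x <= ub + tol) &&
          max(abs(A_full %*% x - b_full)) < 1e-7) {
        val <- sum(obj * x)
        if (val > best + 1e-12) {
          best <- val; best_x <- x
        }
      }
    }
  }
  list(objective = best, x = best_x)
}

# three-reaction linear chain: EX_A (uptake up to 5) -> A -> B -> EX_B
chain_model <- function(uptake = 5) {
  new_metabolic_model(
    id = "chain",
    metabolites = data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                             compartment = "cytoplasm"),
    reactions = data.frame(
      id = c("EX_A", "V1", "EX_B"),
      lower_bound = c(-uptake, 0, 0), upper_bound = 1000,
      gpr = "", subsystem = ""),
    stoich = list(EX_A = c(A_c = -1),
                  V1 = c(A_c = -1, B_c = 1),
                  EX_B = c(B_c = -1)),
    objective_id = "EX_B")
}

# fixed demand split over two parallel identical branches
parallel_model <- function(supply = 10) {
  new_metabolic_model(
    id = "parallel",
    metabolites = data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                             compartment = "cytoplasm"),
    reactions = data.frame(
      id = c("EX_A", "V1", "V2", "EX_B"),
      lower_bound = c(-supply, 0, 0, 0), upper_bound = 1000,
      gpr = "", subsystem = ""),
    stoich = list(EX_A = c(A_c = -1),
                  V1 = c(A_c = -1, B_c = 1),
                  V2 = c(A_c = -1, B_c = 1),
                  EX_B = c(B_c = -1)),
    objective_id = "EX_B")
}

# cached toy fixtures shared across test files (building them is cheap but
# they are used many times)
toy_cache <- new.env(parent = emptyenv())

get_toy <- function() {
  if (is.null(toy_cache$toy)) toy_cache$toy <- make_toy_model()
  toy_cache$toy
}

get_diazo_tc <- function() {
  if (is.null(toy_cache$tc)) {
    toy_cache$tc <- set_condition(compose_two_cell(get_toy()),
                                  "diazotrophic_auto")
  }
  toy_cache$tc
}

get_expanded <- function() {
  if (is.null(toy_cache$em)) toy_cache$em <- to_irreversible_no_or(get_diazo_tc())
  toy_cache$em
}

# dual objective of the bounded LP, for strong-duality checks
dual_objective <- function(sol, lp_rhs, lb, ub) {
  d <- sol$reduced_costs
  contrib <- pmax(d * lb, d * ub)
  contrib[d == 0] <- 0
  sum(sol$duals * lp_rhs) + sum(contrib)
}
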