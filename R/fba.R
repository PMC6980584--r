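#' Flux balance analysis
#'
#' Solves `max c'v` subject to steady state `S v = b`, any extra equality
#' rows carried by the model (photon budget, biomass coupling, gene
#' expression rows), and flux bounds. Dual values are returned for every
#' equality row (metabolite balances and extra constraints).
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction whose flux is maximised (defaults to the
#'   model objective); alternatively `objective_coefs`, a named numeric
#'   vector over variables, for composite objectives.
#' @param objective_coefs optional named objective coefficient vector
#'   (overrides `objective_id`).
#' @param maximize maximise (default) or minimise.
#' @return a `flux_solution`: list with `status`, `objective_value`,
#'   `fluxes` (named, reactions then extra variables), `duals` (named by
#'   metabolite / constraint row), `reduced_costs`, `residual`
#'   (`max |S v - b|`).
#' @export
fba <- function(model, objective_id = model$objective_id,
                objective_coefs = NULL, maximize = TRUE) {
  lp <- .model_lp(model)
  if (is.null(objective_coefs)) {
    if (is.na(objective_id) || !objective_id %in% lp$var_ids) {
      stop("objective reaction not in model: ", objective_id)
    }
    obj <- stats::setNames(numeric(length(lp$var_ids)), lp$var_ids)
    obj[objective_id] <- 1
  } else {
    bad <- setdiff(names(objective_coefs), lp$var_ids)
    if (length(bad)) stop("objective names unknown variable: ", bad[1])
    obj <- stats::setNames(numeric(length(lp$var_ids)), lp$var_ids)
    obj[names(objective_coefs)] <- objective_coefs
  }
  res <- solve_lp(obj, lp$A, lp$rhs, lp$lb, lp$ub, maximize = maximize)
  .as_flux_solution(res, lp)
}

# assemble the LP data for a model: variables are reaction fluxes followed
# by extra variables; rows are metabolite balances followed by extra rows
.model_lp <- function(model) {
  S <- stoich_matrix(model)
  var_ids <- model$reactions$id
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(model$extra_vars) && nrow(model$extra_vars)) {
    var_ids <- c(var_ids, model$extra_vars$id)
    lb <- c(lb, model$extra_vars$lower_bound)
    ub <- c(ub, model$extra_vars$upper_bound)
  }
  b <- stats::setNames(numeric(nrow(S)), rownames(S))
  if (!is.null(model$b)) b[names(model$b)] <- model$b
  A <- as.matrix(S)
  if (ncol(A) < length(var_ids)) {
    A <- cbind(A, matrix(0, nrow(A), length(var_ids) - ncol(A)))
  }
  colnames(A) <- var_ids
  row_ids <- rownames(S)
  rhs <- unname(b)
  for (con in model$extra_constraints) {
    row <- stats::setNames(numeric(length(var_ids)), var_ids)
    bad <- setdiff(names(con$coefs), var_ids)
    if (length(bad)) stop("constraint '", con$name,
                          "' references unknown variable: ", bad[1])
    row[names(con$coefs)] <- con$coefs
    A <- rbind(A, row)
    row_ids <- c(row_ids, con$name)
    rhs <- c(rhs, con$rhs)
  }
  rownames(A) <- row_ids
  list(A = A, rhs = rhs, lb = lb, ub = ub, var_ids = var_ids,
       row_ids = row_ids, n_rxn = nrow(model$reactions))
}

.as_flux_solution <- function(res, lp) {
  sol <- list(status = res$status,
              objective_value = res$objective,
              fluxes = stats::setNames(res$x, lp$var_ids),
              duals = stats::setNames(res$duals, lp$row_ids),
              reduced_costs = stats::setNames(res$reduced_costs, lp$var_ids),
              residual = NA_real_)
  if (res$status == "optimal") {
    sol$residual <- max(abs(lp$A %*% res$x - lp$rhs))
  }
  class(sol) <- "flux_solution"
  sol
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", objective = %.6g (residual %.1e)", x$objective_value,
                x$residual))
  }
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective retaining
#' at least `fraction_of_optimum` of its unconstrained optimum.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to scan (default: all).
#' @param fraction_of_optimum number in `[0, 1]`.
#' @param objective_id objective reaction.
#' @return data.frame with columns `reaction_id`, `min`, `max`.
#' @export
fva <- function(model, reaction_ids = model$reactions$id,
                fraction_of_optimum = 1, objective_id = model$objective_id) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  base <- fba(model, objective_id)
  if (base$status != "optimal") {
    stop("FVA base problem is ", base$status)
  }
  if (fraction_of_optimum > 0) {
    floor_v <- fraction_of_optimum * base$objective_value
    k <- match(objective_id, model$reactions$id)
    model$reactions$lower_bound[k] <- max(model$reactions$lower_bound[k],
                                          floor_v)
  }
  lp <- .model_lp(model)
  out <- data.frame(reaction_id = reaction_ids, min = NA_real_,
                    max = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(reaction_ids)) {
    obj <- stats::setNames(numeric(length(lp$var_ids)), lp$var_ids)
    obj[reaction_ids[i]] <- 1
    lo <- solve_lp(obj, lp$A, lp$rhs, lp$lb, lp$ub, maximize = FALSE)
    hi <- solve_lp(obj, lp$A, lp$rhs, lp$lb, lp$ub, maximize = TRUE)
    out$min[i] <- lo$objective
    out$max[i] <- hi$objective
  }
  out
}

#' L1-minimal flux distribution
#'
#' Among all flux vectors satisfying the model constraints and the supplied
#' fixings, returns one minimising the Manhattan norm `sum_i |v_i|` over the
#' reaction fluxes (slack variables are not penalised). Reversible fluxes
#' are split into non-negative forward/backward parts for the norm.
#'
#' @param model a `metabolic_model`.
#' @param fixed named list / vector: reaction id -> single value (flux fixed)
#'   or length-2 numeric (interval bounds).
#' @return a `flux_solution` whose `objective_value` is the flux of the
#'   model objective reaction and with an extra `l1_norm` element holding
#'   the minimised norm.
#' @export
l1_minimal_solution <- function(model, fixed = list()) {
  if (length(fixed)) {
    for (id in names(fixed)) {
      val <- fixed[[id]]
      if (length(val) == 1L) val <- c(val, val)
      model <- set_bounds(model, id, lb = val[1], ub = val[2])
    }
  }
  lp <- .model_lp(model)
  nr <- lp$n_rxn
  nv <- length(lp$var_ids)
  # reversible fluxes (l < 0 < u) are split into v = p - q, p,q >= 0;
  # one-signed fluxes keep their column with cost +/-1
  split <- which(seq_len(nv) <= nr & lp$lb < 0 & lp$ub > 0)
  A2 <- cbind(lp$A, -lp$A[, split, drop = FALSE])
  lb2 <- lp$lb; ub2 <- lp$ub
  lb2[split] <- 0
  lb2 <- c(lb2, rep(0, length(split)))
  ub2 <- c(ub2, -lp$lb[split])
  cost <- numeric(nv)
  cost[seq_len(nr)] <- 1
  neg <- which(seq_len(nv) <= nr & lp$ub <= 0)
  cost[neg] <- -1
  cost <- c(cost, rep(1, length(split)))
  res <- solve_lp(cost, A2, lp$rhs, lb2, ub2, maximize = FALSE)
  if (res$status != "optimal") {
    sol <- .as_flux_solution(list(status = res$status, objective = NA_real_,
                                  x = rep(NA_real_, nv),
                                  duals = rep(NA_real_, length(lp$row_ids)),
                                  reduced_costs = rep(NA_real_, nv)), lp)
    sol$l1_norm <- NA_real_
    return(sol)
  }
  v <- res$x[seq_len(nv)]
  v[split] <- res$x[split] - res$x[nv + seq_along(split)]
  sol <- .as_flux_solution(list(status = "optimal",
                                objective = NA_real_,
                                x = v, duals = res$duals,
                                reduced_costs = rep(NA_real_, nv)), lp)
  sol$l1_norm <- sum(abs(v[seq_len(nr)]))
  sol$objective_value <- if (!is.na(model$objective_id) &&
                             model$objective_id %in% lp$var_ids) {
    unname(sol$fluxes[model$objective_id])
  } else NA_real_
  sol
}

#' Two-dimensional robustness analysis
#'
#' Objective optimum over a grid of fixed values for two fluxes. Infeasible
#' grid cells are reported as `NA` (zero growth and infeasibility are
#' distinct outcomes).
#'
#' @param model a `metabolic_model`.
#' @param rxn_a,rxn_b reaction ids to fix.
#' @param grid_a,grid_b numeric grids of fixed flux values.
#' @param objective_id objective reaction.
#' @return numeric matrix `length(grid_a) x length(grid_b)` of objective
#'   values, with `dimnames` the grid values.
#' @export
robustness_2d <- function(model, rxn_a, grid_a, rxn_b, grid_b,
                          objective_id = model$objective_id) {
  stopifnot(all(is.finite(grid_a)), all(is.finite(grid_b)))
  out <- matrix(NA_real_, length(grid_a), length(grid_b),
                dimnames = list(format(grid_a, trim = TRUE),
                                format(grid_b, trim = TRUE)))
  for (i in seq_along(grid_a)) {
    mi <- set_bounds(model, rxn_a, lb = grid_a[i], ub = grid_a[i])
    for (j in seq_along(grid_b)) {
      mij <- set_bounds(mi, rxn_b, lb = grid_b[j], ub = grid_b[j])
      s <- fba(mij, objective_id)
      if (s$status == "optimal") out[i, j] <- s$objective_value
    }
  }
  out
}

#' Metabolite turnover in a flux solution
#'
#' Total production rate (= total consumption rate at steady state) of a
#' metabolite: `sum_i max(0, S_ji * v_i)`.
#'
#' @param model a `metabolic_model`.
#' @param solution an optimal `flux_solution`.
#' @param metabolite_id metabolite id.
#' @return turnover in mmol/gDCW/h.
#' @export
metabolite_turnover <- function(model, solution, metabolite_id) {
  if (!metabolite_id %in% model$metabolites$id) {
    stop("unknown metabolite: ", metabolite_id)
  }
  if (solution$status != "optimal") stop("solution is not optimal")
  tot <- 0
  for (k in seq_len(n_reactions(model))) {
    st <- model$stoich[[k]]
    if (metabolite_id %in% names(st)) {
      tot <- tot + max(0, st[[metabolite_id]] *
                         solution$fluxes[[model$reactions$id[k]]])
    }
  }
  tot
}
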