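#' Hydrogen production experiment description
#'
#' Bundles the ids and parameters of the hydrogen analyses: the cell whose
#' H2 secretion is studied, its H2 and O2 exchange reactions, the
#' bidirectional (Hox), uptake (Hup) and nitrogenase reaction ids, the
#' growth fraction of the suboptimal-growth analyses, and the flux-change
#' threshold of the differential report. Defaults follow the toy two-cell
#' naming (`<cell>_<reaction>`).
#'
#' @param cell `"Heterocyst"` or `"Vegetative"`.
#' @param growth_fraction growth is fixed to this fraction of the optimal
#'   rate (default 0.90).
#' @param h2_exchange_id,o2_exchange_id exchange reaction ids (original,
#'   unexpanded ids).
#' @param hox_ids,hup_ids,nitrogenase_ids hydrogen-cycling reaction ids.
#' @param flux_change_threshold |flux difference| below which a reaction
#'   counts as unchanged.
#' @export
h2_experiment <- function(cell = c("Heterocyst", "Vegetative"),
                          growth_fraction = 0.90,
                          h2_exchange_id = paste0(cell, "_EX_h2"),
                          o2_exchange_id = paste0(cell, "_EX_o2"),
                          hox_ids = paste0(cell, c("_HOXN", "_HOXP")),
                          hup_ids = paste0(cell, "_HUP"),
                          nitrogenase_ids = paste0(cell, "_NIT"),
                          flux_change_threshold = 1e-6) {
  cell <- match.arg(cell)
  stopifnot(growth_fraction > 0, growth_fraction <= 1)
  structure(list(cell = cell, growth_fraction = growth_fraction,
                 h2_exchange_id = h2_exchange_id,
                 o2_exchange_id = o2_exchange_id,
                 hox_ids = hox_ids, hup_ids = hup_ids,
                 nitrogenase_ids = nitrogenase_ids,
                 flux_change_threshold = flux_change_threshold),
            class = "h2_experiment")
}

# uniform access to plain and expanded/regulated models
.h2_model <- function(x) if (inherits(x, "expanded_model")) x$model else x

.h2_orig_ids <- function(x) {
  if (inherits(x, "expanded_model")) unique(x$mapping$orig_id) else
    x$reactions$id
}

# objective coefficients selecting the net flux of an original reaction
.net_coefs <- function(x, orig_id) {
  if (inherits(x, "expanded_model")) {
    hits <- x$mapping[x$mapping$orig_id == orig_id, , drop = FALSE]
    if (!nrow(hits)) stop("unknown reaction: ", orig_id)
    stats::setNames(hits$dir, hits$expanded_id)
  } else {
    if (!orig_id %in% x$reactions$id) stop("unknown reaction: ", orig_id)
    stats::setNames(1, orig_id)
  }
}

.h2_solve <- function(x, ...) {
  sol <- fba(.h2_model(x), ...)
  if (inherits(x, "expanded_model") && sol$status == "optimal") {
    sol$mapped_fluxes <- map_fluxes(x, sol)
  }
  sol
}

.h2_l1 <- function(x) {
  sol <- l1_minimal_solution(.h2_model(x))
  if (inherits(x, "expanded_model") && sol$status == "optimal") {
    sol$mapped_fluxes <- map_fluxes(x, sol)
  }
  sol
}

.h2_growth_id <- function(x) {
  m <- .h2_model(x)
  if (inherits(x, "expanded_model")) {
    x$mapping$orig_id[x$mapping$expanded_id == m$objective_id][1]
  } else {
    m$objective_id
  }
}

#' H2 x O2 robustness surface
#'
#' Growth optimum over a grid of fixed H2 and O2 exchange fluxes for one
#' cell of a two-cell (optionally regulated) model; the objective stays
#' the vegetative biomass. Rows index the H2 grid, columns the O2 grid;
#' infeasible cells are `NA`.
#'
#' @param x a `two_cell_model` or `regulated_model`.
#' @param exp an [h2_experiment()].
#' @param h2_grid forced H2 secretion fluxes (>= 0).
#' @param o2_grid fixed O2 exchange fluxes (negative = uptake).
#' @return numeric matrix of growth values.
#' @export
h2_o2_surface <- function(x, exp, h2_grid, o2_grid) {
  stopifnot(inherits(exp, "h2_experiment"),
            all(is.finite(h2_grid)), all(is.finite(o2_grid)))
  out <- matrix(NA_real_, length(h2_grid), length(o2_grid),
                dimnames = list(format(h2_grid, trim = TRUE),
                                format(o2_grid, trim = TRUE)))
  for (i in seq_along(h2_grid)) {
    xi <- fix_net_flux(x, exp$h2_exchange_id, h2_grid[i])
    for (j in seq_along(o2_grid)) {
      xij <- fix_net_flux(xi, exp$o2_exchange_id, o2_grid[j])
      s <- .h2_solve(xij)
      if (s$status == "optimal") out[i, j] <- s$objective_value
    }
  }
  out
}

#' Maximal and minimal H2 secretion at suboptimal growth
#'
#' Fixes growth to `growth_fraction` times the model's optimal growth rate
#' and minimises, then maximises, the H2 secretion flux of the studied
#' cell. Each extreme flux distribution is reported as the L1-minimal
#' (Manhattan-norm-minimal) flux vector at its respective growth and H2
#' fixing, to remove the degeneracy of alternate optima.
#'
#' @param x a `two_cell_model` or `regulated_model`.
#' @param exp an [h2_experiment()].
#' @return list with `h2_min`, `h2_max`, `sol_min`, `sol_max`,
#'   `growth_fixed` (the pinned growth value).
#' @export
h2_range_at_suboptimal_growth <- function(x, exp) {
  stopifnot(inherits(exp, "h2_experiment"))
  base <- .h2_solve(x)
  if (base$status != "optimal") stop("base model is ", base$status)
  gid <- .h2_growth_id(x)
  gfix <- exp$growth_fraction * base$objective_value
  xg <- fix_net_flux(x, gid, gfix)
  h2c <- .net_coefs(xg, exp$h2_exchange_id)
  lo <- .h2_solve(xg, objective_coefs = h2c, maximize = FALSE)
  hi <- .h2_solve(xg, objective_coefs = h2c, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal") {
    stop("growth fixing at fraction ", exp$growth_fraction, " is infeasible")
  }
  sol_min <- .h2_l1(fix_net_flux(xg, exp$h2_exchange_id, lo$objective_value))
  sol_max <- .h2_l1(fix_net_flux(xg, exp$h2_exchange_id, hi$objective_value))
  list(h2_min = lo$objective_value, h2_max = hi$objective_value,
       sol_min = sol_min, sol_max = sol_max, growth_fixed = gfix)
}

#' Differential flux report between minimal- and maximal-H2 states
#'
#' Classifies every (original) reaction as up-regulated, down-regulated or
#' unchanged between the L1-minimal flux distributions of the minimal- and
#' maximal-H2 states, and computes the fraction of the maximal-state H2
#' production catalysed by the bidirectional Hox hydrogenase.
#'
#' @param x the model the solutions came from.
#' @param sol_min,sol_max `flux_solution`s from
#'   [h2_range_at_suboptimal_growth()].
#' @param exp the [h2_experiment()].
#' @return list with data.frames `up` and `down` (`reaction_id`,
#'   `flux_min`, `flux_max`), `unchanged` (count), and `hox_fraction_max`.
#' @export
differential_flux <- function(x, sol_min, sol_max, exp) {
  fmin <- if (!is.null(sol_min$mapped_fluxes)) sol_min$mapped_fluxes else
    sol_min$fluxes
  fmax <- if (!is.null(sol_max$mapped_fluxes)) sol_max$mapped_fluxes else
    sol_max$fluxes
  ids <- intersect(.h2_orig_ids(x), names(fmin))
  if (!setequal(ids, intersect(.h2_orig_ids(x), names(fmax)))) {
    stop("solutions come from different models")
  }
  delta <- fmax[ids] - fmin[ids]
  thr <- exp$flux_change_threshold
  mk <- function(sel) data.frame(reaction_id = ids[sel],
                                 flux_min = unname(fmin[ids[sel]]),
                                 flux_max = unname(fmax[ids[sel]]),
                                 stringsAsFactors = FALSE)
  list(up = mk(delta > thr), down = mk(delta < -thr),
       unchanged = sum(abs(delta) <= thr),
       hox_fraction_max = hox_fraction(x, sol_max, exp))
}

#' Fraction of H2 production catalysed by the Hox hydrogenase
#'
#' In the given solution, total production of the studied cell's
#' cytoplasmic H2 is `sum_i max(0, S_h2,i * v_i)`; the Hox fraction is the
#' share contributed by the `hox_ids` reactions.
#'
#' @param x the model; `solution` a `flux_solution`; `exp` the experiment.
#' @param solution a `flux_solution` of `x`.
#' @param exp an [h2_experiment()].
#' @return number in `[0, 1]` (0 when nothing produces H2).
#' @export
hox_fraction <- function(x, solution, exp) {
  m <- .h2_model(x)
  h2_met <- paste0(exp$cell, "_h2_c")
  if (!h2_met %in% m$metabolites$id) stop("no metabolite ", h2_met)
  orig_of <- if (inherits(x, "expanded_model")) {
    stats::setNames(x$mapping$orig_id, x$mapping$expanded_id)
  } else {
    stats::setNames(m$reactions$id, m$reactions$id)
  }
  tot <- 0; hox <- 0
  for (k in seq_len(n_reactions(m))) {
    st <- m$stoich[[k]]
    if (!h2_met %in% names(st)) next
    rid <- m$reactions$id[k]
    prod <- max(0, st[[h2_met]] * solution$fluxes[[rid]])
    tot <- tot + prod
    if (orig_of[[rid]] %in% exp$hox_ids) hox <- hox + prod
  }
  if (tot <= 1e-12) 0 else hox / tot
}

#' Knock out reactions and recompute maximal H2
#'
#' Deletes the listed (original) reactions, then recomputes the maximal H2
#' secretion at `growth_fraction` of the knockout model's own optimal
#' growth rate (the growth reference moves with the knockout, as the
#' engineered strain grows at its own optimum).
#'
#' @param x a `two_cell_model` or `regulated_model`.
#' @param exp an [h2_experiment()].
#' @param knockout_ids original reaction ids to delete.
#' @return list `h2_max_wt`, `h2_max_ko`.
#' @export
knockout_h2 <- function(x, exp, knockout_ids) {
  wt <- h2_range_at_suboptimal_growth(x, exp)
  ko <- knockout_reactions(x, knockout_ids)
  kr <- h2_range_at_suboptimal_growth(ko, exp)
  list(h2_max_wt = wt$h2_max, h2_max_ko = kr$h2_max)
}

#' @rdname knockout_h2
#' @export
knockout_reactions <- function(x, knockout_ids) {
  if (inherits(x, "expanded_model")) {
    ids <- x$mapping$expanded_id[x$mapping$orig_id %in% knockout_ids]
    miss <- setdiff(knockout_ids, x$mapping$orig_id)
    if (length(miss)) stop("unknown reaction: ", miss[1])
    x$model <- remove_reactions(x$model, ids)
    x$mapping <- x$mapping[!x$mapping$expanded_id %in% ids, , drop = FALSE]
    x$K <- lapply(x$K, setdiff, y = ids)
    x
  } else {
    remove_reactions(x, knockout_ids)
  }
}
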