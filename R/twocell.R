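#' Cell and shuttle specifications for the two-cell model
#'
#' `cell_spec()` names one cell copy: its id prefix, the reactions deleted
#' from that cell (deletion removes the reaction column; metabolite balance
#' rows are kept), and optional per-exchange uptake caps applied after
#' composition. `shuttle_spec()` lists the periplasmic metabolites shared
#' between the two cells (sucrose, glutamate and glutamine by default),
#' each linked by one reversible unconstrained transfer reaction.
#'
#' @param prefix `"Vegetative"` or `"Heterocyst"`.
#' @param removed_reactions reaction ids (in the base model) absent from
#'   this cell type.
#' @param allowed_uptakes named numeric: exchange id -> maximum uptake
#'   (mmol/gDCW/h), applied as lower bound `-value`.
#' @export
cell_spec <- function(prefix = c("Vegetative", "Heterocyst"),
                      removed_reactions = character(),
                      allowed_uptakes = numeric()) {
  prefix <- match.arg(prefix)
  structure(list(prefix = prefix, removed_reactions = removed_reactions,
                 allowed_uptakes = allowed_uptakes), class = "cell_spec")
}

#' @rdname cell_spec
#' @param shuttle_metabolites periplasmic metabolite ids (base model)
#'   exchanged between the cells.
#' @param bound magnitude of the (unconstrained) shuttle bounds.
#' @export
shuttle_spec <- function(shuttle_metabolites = c("suc_p", "glu_p", "gln_p"),
                         bound = 1000) {
  structure(list(shuttle_metabolites = shuttle_metabolites, bound = bound),
            class = "shuttle_spec")
}

#' Compose a two-cell (vegetative + heterocyst) model
#'
#' Builds one merged model containing a prefixed copy of the base model per
#' cell type (with cell-specific deletions), three reversible intercellular
#' shuttle reactions through the shared periplasm, a photon-budget row
#' `photon_V + photon_H + slack = photon_max` (slack >= 0), and a biomass
#' coupling row `growth_H = f * growth_V` with heterocyst fraction
#' `f = 0.1`. Bicarbonate uptake is enabled only in the vegetative cell and
#' dinitrogen uptake only in the heterocyst. The objective is the
#' vegetative biomass reaction; reported total growth is
#' `total_growth_factor * growth_V` (see [total_growth()]).
#'
#' @param base a single-cell `metabolic_model`.
#' @param veg,het [cell_spec()]s for the two copies.
#' @param shuttle a [shuttle_spec()].
#' @param photon_max shared maximum photon uptake, mmol/gDCW/h.
#' @param heterocyst_fraction ratio of heterocyst to vegetative growth.
#' @param total_growth_factor factor applied to vegetative growth when
#'   reporting filament growth.
#' @param hco3_exchange,n2_exchange,photon_exchange exchange reaction ids
#'   in the base model.
#' @return a `two_cell_model` (also a `metabolic_model`).
#' @export
compose_two_cell <- function(base,
                             veg = cell_spec("Vegetative", "NIT"),
                             het = cell_spec("Heterocyst",
                                             c("PSII", "RBPC", "HCO3E",
                                               "GOGAT", "NO3R")),
                             shuttle = shuttle_spec(),
                             photon_max = 20,
                             heterocyst_fraction = 0.10,
                             total_growth_factor = 1.1,
                             hco3_exchange = "EX_hco3",
                             n2_exchange = "EX_n2",
                             photon_exchange = "EX_photon") {
  stopifnot(inherits(veg, "cell_spec"), inherits(het, "cell_spec"))
  if (veg$prefix == het$prefix) stop("cell prefixes must be distinct")
  for (spec in list(veg, het)) {
    miss <- setdiff(spec$removed_reactions, base$reactions$id)
    if (length(miss)) stop("removed reaction not in base model: ", miss[1])
  }
  if (!photon_exchange %in% base$reactions$id) {
    stop("photon exchange not in base model: ", photon_exchange)
  }
  if (is.na(base$objective_id)) stop("base model needs an objective reaction")
  if (base$objective_id %in% c(veg$removed_reactions, het$removed_reactions)) {
    stop("cannot remove the objective reaction from a cell copy")
  }

  copies <- lapply(list(veg, het), function(spec) {
    m <- base
    if (length(spec$removed_reactions)) {
      m <- remove_reactions(m, spec$removed_reactions)
    }
    prefix_model(m, spec$prefix)
  })
  vm <- copies[[1]]; hm <- copies[[2]]

  mets <- rbind(vm$metabolites, hm$metabolites)
  rxns <- rbind(vm$reactions, hm$reactions)
  stoich <- c(vm$stoich, hm$stoich)

  shuttle_ids <- character(0)
  for (met in shuttle$shuttle_metabolites) {
    a <- paste0(veg$prefix, "_", met); b <- paste0(het$prefix, "_", met)
    if (!a %in% mets$id || !b %in% mets$id) {
      stop("shuttle metabolite absent from a cell copy: ", met)
    }
    sid <- paste0("SHUTTLE_", met)
    shuttle_ids <- c(shuttle_ids, sid)
    rxns <- rbind(rxns, data.frame(
      id = sid, lower_bound = -shuttle$bound, upper_bound = shuttle$bound,
      gpr = "", subsystem = "Intercellular exchange",
      stringsAsFactors = FALSE))
    stoich[[sid]] <- stats::setNames(c(-1, 1), c(a, b))
  }

  pvar <- "photon_slack"
  vex <- paste0(veg$prefix, "_", photon_exchange)
  hex <- paste0(het$prefix, "_", photon_exchange)
  vg <- paste0(veg$prefix, "_", base$objective_id)
  hg <- paste0(het$prefix, "_", base$objective_id)
  extra_vars <- data.frame(id = pvar, lower_bound = 0,
                           upper_bound = photon_max,
                           stringsAsFactors = FALSE)
  extra_constraints <- list(
    list(name = "photon_budget",
         coefs = stats::setNames(c(-1, -1, 1), c(vex, hex, pvar)),
         rhs = photon_max),
    list(name = "biomass_coupling",
         coefs = stats::setNames(c(1, -heterocyst_fraction), c(hg, vg)),
         rhs = 0))

  tc <- new_metabolic_model(
    id = paste0(base$id, "_twocell"),
    metabolites = mets, reactions = rxns, stoich = stoich,
    objective_id = vg,
    extra_vars = extra_vars, extra_constraints = extra_constraints)

  # uptake wiring: photon limited by the shared budget; HCO3 vegetative
  # only; N2 heterocyst only
  tc <- set_bounds(tc, c(vex, hex), lb = -photon_max)
  hco3_v <- paste0(veg$prefix, "_", hco3_exchange)
  hco3_h <- paste0(het$prefix, "_", hco3_exchange)
  n2_v <- paste0(veg$prefix, "_", n2_exchange)
  n2_h <- paste0(het$prefix, "_", n2_exchange)
  if (hco3_h %in% tc$reactions$id) tc <- set_bounds(tc, hco3_h, lb = 0)
  if (n2_v %in% tc$reactions$id) tc <- set_bounds(tc, n2_v, lb = 0)
  if (n2_h %in% tc$reactions$id) tc <- set_bounds(tc, n2_h, lb = -1000)
  for (spec in list(veg, het)) {
    for (ex in names(spec$allowed_uptakes)) {
      tc <- set_bounds(tc, paste0(spec$prefix, "_", ex),
                       lb = -spec$allowed_uptakes[[ex]])
    }
  }

  tc$veg_prefix <- veg$prefix
  tc$het_prefix <- het$prefix
  tc$heterocyst_fraction <- heterocyst_fraction
  tc$total_growth_factor <- total_growth_factor
  tc$photon_max <- photon_max
  tc$shuttle_ids <- shuttle_ids
  tc$photon_exchange <- photon_exchange
  tc$base_exchanges <- base$reactions$id[is_exchange_reaction(base)]
  class(tc) <- c("two_cell_model", class(tc))
  tc
}

#' Apply a growth-condition preset to a two-cell model
#'
#' * `diazotrophic_auto`: nitrate uptake closed in both cells, dinitrogen
#'   open for the heterocyst, bicarbonate open for the vegetative cell,
#'   photon budget active.
#' * `nitrate_auto`: as diazotrophic, plus nitrate uptake open (a strict
#'   relaxation, so optimal growth can only increase).
#' * `heterotrophic`: fructose (up to `fructose_uptake`) replaces
#'   bicarbonate and photon as the vegetative carbon and energy source;
#'   photon and bicarbonate uptakes are closed.
#'
#' @param tc a `two_cell_model`.
#' @param condition preset name.
#' @param hco3_uptake vegetative bicarbonate cap, mmol/gDCW/h.
#' @param no3_uptake nitrate cap used by `nitrate_auto`.
#' @param fructose_uptake vegetative fructose cap for `heterotrophic`.
#' @return the modified `two_cell_model`.
#' @export
set_condition <- function(tc, condition = c("diazotrophic_auto",
                                            "nitrate_auto", "heterotrophic"),
                          hco3_uptake = 10, no3_uptake = 10,
                          fructose_uptake = 1) {
  condition <- match.arg(condition)
  vp <- tc$veg_prefix; hp <- tc$het_prefix
  vex <- function(x) paste0(vp, "_", x)
  hex <- function(x) paste0(hp, "_", x)
  set_if <- function(m, id, lb) {
    if (id %in% m$reactions$id) set_bounds(m, id, lb = lb) else m
  }
  tc <- set_if(tc, vex("EX_no3"), 0)
  tc <- set_if(tc, hex("EX_no3"), 0)
  if (condition == "nitrate_auto") {
    tc <- set_if(tc, vex("EX_no3"), -no3_uptake)
    tc <- set_if(tc, hex("EX_no3"), -no3_uptake)
  }
  if (condition %in% c("diazotrophic_auto", "nitrate_auto")) {
    tc <- set_if(tc, vex("EX_hco3"), -hco3_uptake)
    tc <- set_if(tc, vex("EX_frc"), 0)
    tc <- set_if(tc, hex("EX_frc"), 0)
  } else {
    # heterotrophic: no light, no inorganic carbon; fructose feeds the
    # vegetative cell
    tc <- set_if(tc, vex("EX_hco3"), 0)
    tc <- set_if(tc, hex("EX_hco3"), 0)
    tc <- set_if(tc, vex(tc$photon_exchange), 0)
    tc <- set_if(tc, hex(tc$photon_exchange), 0)
    tc <- set_if(tc, vex("EX_frc"), -fructose_uptake)
  }
  tc$condition <- condition
  tc
}

#' Total filament growth rate
#'
#' @param solution an optimal `flux_solution` of a two-cell model.
#' @param tc the `two_cell_model` it solves.
#' @return `total_growth_factor * v_growth_vegetative` (1/h).
#' @export
total_growth <- function(solution, tc) {
  if (solution$status != "optimal") stop("solution is not optimal")
  tc$total_growth_factor * unname(solution$fluxes[tc$objective_id])
}

#' Dimensions of a two-cell model
#'
#' `model_dimensions()` counts the decision variables (reaction fluxes of
#' both cells, shuttle reactions, photon slack, plus any gene-expression
#' slacks) and equality rows (metabolite balances of both cells, photon
#' budget, biomass coupling, plus gene rows) of a composed model.
#' `two_cell_dimensions()` is the closed-form count for composing an
#' unreduced base model with n reactions and m metabolites:
#' `2n + 3 + 1` variables and `2m + 2` equations.
#'
#' @param tc a `two_cell_model`.
#' @return integer vector `c(n_variables, n_equations)`.
#' @export
model_dimensions <- function(tc) {
  nv <- nrow(tc$reactions) +
    (if (is.null(tc$extra_vars)) 0L else nrow(tc$extra_vars))
  ne <- nrow(tc$metabolites) + length(tc$extra_constraints)
  c(n_variables = nv, n_equations = ne)
}

#' @rdname model_dimensions
#' @param n_reactions,n_metabolites base (single-cell) model dimensions.
#' @param n_shuttles number of intercellular transfer reactions.
#' @export
two_cell_dimensions <- function(n_reactions, n_metabolites, n_shuttles = 3L) {
  c(n_variables = 2L * as.integer(n_reactions) + as.integer(n_shuttles) + 1L,
    n_equations = 2L * as.integer(n_metabolites) + 2L)
}

#' Mixotrophic growth relative to autotrophic growth on bicarbonate
#'
#' Computes the FBA growth optimum with a supplementary carbon source
#' opened (mixotrophic: photon + bicarbonate + carbon source) divided by
#' the optimum on bicarbonate alone.
#'
#' @param model a single-cell `metabolic_model`.
#' @param carbon_source exchange reaction id of the extra carbon source.
#' @param uptake maximum uptake of the carbon source, mmol/gDCW/h.
#' @param reference bicarbonate exchange id.
#' @return the relative growth ratio (dimensionless).
#' @export
relative_growth <- function(model, carbon_source, uptake = 1,
                            reference = "EX_hco3") {
  for (id in c(carbon_source, reference)) {
    if (!id %in% model$reactions$id) stop("unknown exchange: ", id)
  }
  auto <- fba(set_bounds(model, carbon_source, lb = 0))
  if (auto$status != "optimal" || auto$objective_value <= 1e-12) {
    stop("autotrophic reference growth is zero or infeasible")
  }
  mixo <- fba(set_bounds(model, carbon_source, lb = -uptake))
  mixo$objective_value / auto$objective_value
}
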