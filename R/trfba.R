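#' Irreversible, OR-free model expansion
#'
#' Transcription-regulated FBA caps sums of gene-supported fluxes, which
#' requires (i) every flux to be non-negative and (ii) every reaction to be
#' supported by a single AND-conjunction of genes. `to_irreversible_no_or()`
#' therefore splits each reversible reaction into a forward and a reversed
#' copy (`<id>_rev`, negated stoichiometry, bounds `[0, -lb]`) and
#' duplicates each reaction whose GPR contains OR into one copy per
#' OR-alternative (`<id>_iso<k>`, the alternatives being the disjunctive
#' normal form of the rule). Bounds, extra constraint rows (photon budget,
#' biomass coupling) and the objective are remapped so the expanded model's
#' flux space projects exactly onto the original one; in particular the FBA
#' optimum is unchanged.
#'
#' @param model a `metabolic_model` (typically a composed two-cell model).
#' @return an `expanded_model`: list with `model` (the expanded
#'   `metabolic_model`), `mapping` (data.frame `expanded_id`, `orig_id`,
#'   `dir` in `{+1,-1}`, `iso`), and `K` (named list: gene id -> expanded
#'   reaction ids it supports).
#' @export
to_irreversible_no_or <- function(model) {
  rxn <- model$reactions
  exp_rows <- list(); exp_stoich <- list(); map_rows <- list()
  K <- list()
  for (k in seq_len(nrow(rxn))) {
    id <- rxn$id[k]; lb <- rxn$lower_bound[k]; ub <- rxn$upper_bound[k]
    st <- model$stoich[[k]]
    dnf <- gpr_dnf(parse_gpr(rxn$gpr[k]))
    n_alt <- max(1L, length(dnf))
    if (n_alt > 1L && lb > 0) {
      # a strictly positive lower bound cannot be attributed to one isozyme
      lb <- 0
      warning("reaction ", id, ": positive lower bound relaxed to 0 on ",
              "isozyme expansion")
    }
    for (a in seq_len(n_alt)) {
      conj <- if (length(dnf)) dnf[[a]] else character()
      gpr_a <- paste(conj, collapse = " and ")
      suffix <- if (n_alt > 1L) paste0("_iso", a) else ""
      fid <- paste0(id, suffix)
      exp_rows[[fid]] <- data.frame(
        id = fid, lower_bound = max(lb, 0), upper_bound = max(ub, 0),
        gpr = gpr_a, subsystem = rxn$subsystem[k], stringsAsFactors = FALSE)
      exp_stoich[[fid]] <- st
      map_rows[[fid]] <- data.frame(expanded_id = fid, orig_id = id,
                                    dir = 1, iso = a,
                                    stringsAsFactors = FALSE)
      for (g in conj) K[[g]] <- c(K[[g]], fid)
      if (lb < 0) {
        rid <- paste0(id, "_rev", suffix)
        exp_rows[[rid]] <- data.frame(
          id = rid, lower_bound = 0, upper_bound = -lb,
          gpr = gpr_a, subsystem = rxn$subsystem[k], stringsAsFactors = FALSE)
        exp_stoich[[rid]] <- -st
        map_rows[[rid]] <- data.frame(expanded_id = rid, orig_id = id,
                                      dir = -1, iso = a,
                                      stringsAsFactors = FALSE)
        for (g in conj) K[[g]] <- c(K[[g]], rid)
      }
    }
  }
  reactions <- do.call(rbind, exp_rows)
  rownames(reactions) <- NULL
  mapping <- do.call(rbind, map_rows)
  rownames(mapping) <- NULL

  # remap extra rows (coefficient c on an original flux becomes c on every
  # forward copy and -c on every reversed copy)
  extra <- lapply(model$extra_constraints, function(con) {
    coefs <- numeric(0)
    for (nm in names(con$coefs)) {
      hits <- mapping[mapping$orig_id == nm, , drop = FALSE]
      if (nrow(hits)) {
        coefs <- c(coefs, stats::setNames(con$coefs[[nm]] * hits$dir,
                                          hits$expanded_id))
      } else {
        coefs <- c(coefs, con$coefs[nm])  # extra variable (e.g. slack)
      }
    }
    list(name = con$name, coefs = coefs, rhs = con$rhs)
  })

  obj <- model$objective_id
  if (!is.na(obj) && !obj %in% reactions$id) {
    obj <- mapping$expanded_id[mapping$orig_id == obj & mapping$dir == 1][1]
  }
  em_model <- new_metabolic_model(
    id = paste0(model$id, "_irrev"),
    metabolites = model$metabolites, reactions = reactions,
    stoich = exp_stoich, objective_id = obj,
    extra_vars = model$extra_vars, extra_constraints = extra,
    b = model$b)
  for (f in c("veg_prefix", "het_prefix", "heterocyst_fraction",
              "total_growth_factor", "photon_max", "shuttle_ids",
              "photon_exchange", "condition")) {
    em_model[[f]] <- model[[f]]
  }
  if (inherits(model, "two_cell_model")) {
    class(em_model) <- c("two_cell_model", class(em_model))
  }
  structure(list(model = em_model, mapping = mapping,
                 K = lapply(K, unique)),
            class = "expanded_model")
}

#' Project expanded fluxes back onto original reactions
#'
#' @param em an `expanded_model` (or `regulated_model`).
#' @param solution a `flux_solution` of the expanded model.
#' @return named numeric vector of net fluxes per original reaction id.
#' @export
map_fluxes <- function(em, solution) {
  v <- solution$fluxes[em$mapping$expanded_id] * em$mapping$dir
  out <- tapply(v, em$mapping$orig_id, sum)
  stats::setNames(as.numeric(out), names(out))[unique(em$mapping$orig_id)]
}

#' Add per-gene expression constraints (transcription-regulated FBA)
#'
#' For every measured metabolic gene j of each cell copy, adds the equality
#' row `sum_{i in K_j} v_i + a_j = E_j * C` with slack `a_j >= 0`, where
#' `K_j` are the expanded reactions the gene supports in that cell, `E_j`
#' the expression level in that cell type, and `C` (mmol/gDCW/h) the flux
#' capacity supported by one expression unit. Rows are named
#' `<prefix>_<gene>`; genes with measured expression but no supported
#' reaction in a cell copy are skipped with a warning.
#'
#' @param em an `expanded_model` of a two-cell model.
#' @param expr expression data.frame with columns `gene_id`, `E_veg`,
#'   `E_het` (expression levels >= 0, arbitrary units) over base
#'   (unprefixed) gene ids.
#' @param C positive capacity conversion constant, mmol/gDCW/h.
#' @return a `regulated_model`: the `expanded_model` fields plus `C`,
#'   `expression`, `gene_rows` (data.frame `row`, `cell`, `gene`,
#'   `slack_id`, `E`), and counts `n_added_vars` / `n_added_rows`.
#' @export
add_expression_constraints <- function(em, expr, C) {
  stopifnot(inherits(em, "expanded_model"), C > 0)
  stopifnot(all(c("gene_id", "E_veg", "E_het") %in% names(expr)))
  if (any(expr$E_veg < 0) || any(expr$E_het < 0)) {
    stop("expression levels must be non-negative")
  }
  model <- em$model
  prefixes <- c(model$veg_prefix, model$het_prefix)
  ecols <- c("E_veg", "E_het")
  rows <- list()
  skipped <- character(0)
  for (ci in 1:2) {
    for (j in seq_len(nrow(expr))) {
      gene <- paste0(prefixes[ci], "_", expr$gene_id[j])
      Kj <- em$K[[gene]]
      if (is.null(Kj) || !length(Kj)) {
        skipped <- c(skipped, gene)
        next
      }
      E <- expr[[ecols[ci]]][j]
      slack <- paste0("a_", gene)
      rows[[gene]] <- list(
        row = gene, cell = prefixes[ci], gene = expr$gene_id[j],
        slack_id = slack, E = E,
        con = list(name = gene,
                   coefs = stats::setNames(c(rep(1, length(Kj)), 1),
                                           c(Kj, slack)),
                   rhs = E * C))
    }
  }
  if (length(skipped)) {
    warning(length(skipped), " gene(s) with no supported reaction skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  }
  gene_rows <- do.call(rbind, lapply(rows, function(r) {
    data.frame(row = r$row, cell = r$cell, gene = r$gene,
               slack_id = r$slack_id, E = r$E, stringsAsFactors = FALSE)
  }))
  add_vars <- data.frame(id = gene_rows$slack_id, lower_bound = 0,
                         upper_bound = Inf, stringsAsFactors = FALSE)
  model$extra_vars <- rbind(model$extra_vars, add_vars)
  model$extra_constraints <- c(model$extra_constraints,
                               lapply(rows, `[[`, "con"))
  rm <- list(model = model, mapping = em$mapping, K = em$K, C = C,
             expression = expr, gene_rows = gene_rows,
             n_added_vars = nrow(gene_rows), n_added_rows = nrow(gene_rows))
  class(rm) <- c("regulated_model", "expanded_model")
  rm
}

#' FBA on a regulated model
#'
#' Solves the expanded, gene-constrained LP and attaches net fluxes mapped
#' back to the original reaction ids (`$mapped_fluxes`).
#'
#' @param rm a `regulated_model` (or `expanded_model`).
#' @param objective_id objective reaction (expanded or original id).
#' @return a `flux_solution` with an extra `mapped_fluxes` element.
#' @export
regulated_fba <- function(rm, objective_id = rm$model$objective_id) {
  if (!objective_id %in% rm$model$reactions$id &&
      objective_id %in% rm$mapping$orig_id) {
    objective_id <- rm$mapping$expanded_id[rm$mapping$orig_id == objective_id &
                                             rm$mapping$dir == 1][1]
  }
  sol <- fba(rm$model, objective_id)
  if (sol$status == "optimal") sol$mapped_fluxes <- map_fluxes(rm, sol)
  sol
}

#' Calibrate the expression-capacity constant C by sensitivity analysis
#'
#' Sweeps a grid of C values, computes the regulated growth prediction for
#' each, and returns the C minimising the relative error against an
#' observed growth rate (ties broken towards the smallest C). Predicted
#' growth is reported as total filament growth when the model carries a
#' `total_growth_factor`.
#'
#' @param em an `expanded_model` of the two-cell model.
#' @param expr expression table (see [add_expression_constraints()]).
#' @param objective_id objective reaction id.
#' @param c_grid positive C values; default log-spaced `1e-4 ... 1`.
#' @param observed_growth measured growth rate (1/h), must be positive.
#' @return list with `C_opt` and `curve` (data.frame `C`, `predicted`,
#'   `rel_error`).
#' @export
scan_C <- function(em, expr, objective_id = em$model$objective_id,
                   c_grid = 10^seq(-4, 0, length.out = 25),
                   observed_growth) {
  stopifnot(length(c_grid) > 0, all(c_grid > 0))
  if (missing(observed_growth) || observed_growth <= 0) {
    stop("observed_growth must be positive")
  }
  fac <- if (is.null(em$model$total_growth_factor)) 1 else
    em$model$total_growth_factor
  c_grid <- sort(c_grid)
  pred <- vapply(c_grid, function(C) {
    rm <- suppressWarnings(add_expression_constraints(em, expr, C))
    sol <- regulated_fba(rm, objective_id)
    if (sol$status != "optimal") return(NA_real_)
    fac * sol$objective_value
  }, numeric(1))
  rel_error <- abs(pred - observed_growth) / observed_growth
  best <- which(rel_error == min(rel_error, na.rm = TRUE))[1]
  list(C_opt = c_grid[best],
       curve = data.frame(C = c_grid, predicted = pred,
                          rel_error = rel_error))
}

#' Gene-level shadow prices
#'
#' The shadow price of gene j in one cell is the dual value of its
#' expression row, i.e. the sensitivity of the objective to the row's
#' right-hand side `E_j * C`. Multiplying by C gives the effect of one
#' unit of expression on the predicted growth rate; both scales are
#' reported. By complementary slackness a gene whose slack `a_j` is
#' positive (expression not limiting) has shadow price zero.
#'
#' @param rm a `regulated_model`.
#' @param solution an optimal `flux_solution` of `rm` with duals.
#' @return data.frame `cell`, `gene`, `dual` (per rhs unit),
#'   `per_expression_unit` (`dual * C`), `slack`.
#' @export
gene_shadow_prices <- function(rm, solution) {
  stopifnot(inherits(rm, "regulated_model"))
  if (solution$status != "optimal" || is.null(solution$duals)) {
    stop("solution must be optimal with dual values")
  }
  gr <- rm$gene_rows
  duals <- solution$duals[gr$row]
  slacks <- solution$fluxes[gr$slack_id]
  data.frame(cell = gr$cell, gene = gr$gene,
             dual = unname(duals),
             per_expression_unit = unname(duals) * rm$C,
             slack = unname(slacks),
             stringsAsFactors = FALSE)
}

#' Fix the net flux of an original reaction
#'
#' On a plain model this pins the reaction bounds. On an expanded or
#' regulated model the original flux is spread over forward/reverse (and
#' isozyme) copies, so the fixing is added as an equality row
#' `sum_i dir_i v_i = t` with a new bounded variable `t in [lo, hi]`.
#'
#' @param x a `metabolic_model`, `expanded_model` or `regulated_model`.
#' @param id original reaction id.
#' @param lo,hi fixed value (`hi` defaults to `lo`) or interval.
#' @return object of the same class with the fixing applied.
#' @export
fix_net_flux <- function(x, id, lo, hi = lo) {
  UseMethod("fix_net_flux")
}

#' @export
fix_net_flux.metabolic_model <- function(x, id, lo, hi = lo) {
  set_bounds(x, id, lb = lo, ub = hi)
}

#' @export
fix_net_flux.expanded_model <- function(x, id, lo, hi = lo) {
  hits <- x$mapping[x$mapping$orig_id == id, , drop = FALSE]
  if (!nrow(hits)) stop("unknown original reaction: ", id)
  tid <- paste0("fix_", id)
  i <- 1L
  while (tid %in% c(x$model$extra_vars$id, x$model$reactions$id)) {
    tid <- paste0("fix_", id, "_", i); i <- i + 1L
  }
  x$model$extra_vars <- rbind(
    x$model$extra_vars,
    data.frame(id = tid, lower_bound = lo, upper_bound = hi,
               stringsAsFactors = FALSE))
  x$model$extra_constraints <- c(x$model$extra_constraints, list(list(
    name = paste0("fixrow_", tid),
    coefs = stats::setNames(c(hits$dir, -1), c(hits$expanded_id, tid)),
    rhs = 0)))
  x
}
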