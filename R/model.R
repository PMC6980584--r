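#' Constraint-based metabolic model container
#'
#' A `metabolic_model` bundles the metabolites, reactions (with flux bounds
#' and GPR rules), implicit stoichiometric matrix S, and the objective
#' reaction of a stoichiometric model. Steady state `S v = b` (with `b = 0`
#' unless stated otherwise) applies to every metabolite row.
#'
#' Extra linear equality constraints beyond the metabolite balances (photon
#' budgets, biomass coupling, per-gene expression caps) are carried in
#' `extra_constraints`, each a `list(name, coefs, rhs)` whose `coefs` is a
#' named numeric vector over reaction and/or extra-variable ids. Non-flux
#' decision variables (slacks) live in `extra_vars`.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (one of cytoplasm, thylakoid, periplasm, extracellular) and optional
#'   `formula` (elemental composition, pseudo-elements allowed).
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `gpr`, `subsystem` (bounds in mmol/gDCW/h).
#' @param stoich named list, one entry per reaction id: a named numeric
#'   vector of signed stoichiometric coefficients over metabolite ids.
#' @param objective_id id of the objective (biomass) reaction, or `NA`.
#' @param extra_vars optional data.frame (`id`, `lower_bound`, `upper_bound`).
#' @param extra_constraints optional list of extra equality rows (see above).
#' @param b optional named right-hand-side vector over metabolite ids
#'   (defaults to zero for every metabolite).
#' @return an object of class `metabolic_model`.
#' @export
new_metabolic_model <- function(id, metabolites, reactions, stoich,
                                objective_id = NA_character_,
                                extra_vars = NULL, extra_constraints = list(),
                                b = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  m <- structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    stoich = stoich[reactions$id],
    objective_id = objective_id,
    extra_vars = extra_vars,
    extra_constraints = extra_constraints,
    b = b
  ), class = "metabolic_model")
  validate_model(m)
}

#' @rdname new_metabolic_model
#' @param model a `metabolic_model`.
#' @export
validate_model <- function(model) {
  met <- model$metabolites; rxn <- model$reactions
  if (nrow(met) == 0L || nrow(rxn) == 0L) stop("model must contain metabolites and reactions")
  if (anyDuplicated(met$id)) stop("duplicate metabolite id: ",
                                  met$id[duplicated(met$id)][1])
  if (anyDuplicated(rxn$id)) stop("duplicate reaction id: ",
                                  rxn$id[duplicated(rxn$id)][1])
  ok_comp <- c("cytoplasm", "thylakoid", "periplasm", "extracellular")
  if (!all(met$compartment %in% ok_comp)) {
    stop("unknown compartment: ",
         setdiff(unique(met$compartment), ok_comp)[1])
  }
  if (!setequal(names(model$stoich), rxn$id)) {
    stop("stoichiometry list must have one entry per reaction")
  }
  refs <- unique(unlist(lapply(model$stoich, names)))
  miss <- setdiff(refs, met$id)
  if (length(miss)) stop("reaction references unknown metabolite: ", miss[1])
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    stop("lower_bound > upper_bound for reaction ",
         rxn$id[rxn$lower_bound > rxn$upper_bound][1])
  }
  if (!is.na(model$objective_id) && !model$objective_id %in% rxn$id) {
    stop("objective reaction not in model: ", model$objective_id)
  }
  for (g in rxn$gpr) parse_gpr(g)  # errors on malformed rules
  model
}

#' Stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return sparse `Matrix` (metabolites x reactions) with dimnames.
#' @export
stoich_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rxn_ids)) {
    st <- model$stoich[[k]]
    if (!length(st)) next
    i <- c(i, match(names(st), met_ids))
    j <- c(j, rep.int(k, length(st)))
    x <- c(x, unname(st))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' @rdname stoich_matrix
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname stoich_matrix
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' @rdname stoich_matrix
#' @return `model_genes()`: sorted vector of gene ids appearing in GPR rules.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$reactions$gpr,
                            function(g) gpr_genes(parse_gpr(g))))))
}

#' @rdname stoich_matrix
#' @return `is_exchange_reaction()`: logical vector, `TRUE` for reactions
#'   involving exactly one metabolite (boundary exchanges).
#' @export
is_exchange_reaction <- function(model) {
  vapply(model$stoich, function(s) length(s) == 1L, logical(1))
}

#' Edit helpers
#'
#' `set_bounds()` updates flux bounds; `remove_reactions()` deletes reaction
#' columns (metabolite rows are kept, matching the two-cell convention that
#' cell-specific deletions do not change the balance count);
#' `add_reaction()` appends a reaction; `prefix_model()` prefixes every
#' metabolite, reaction and gene id (used for cell copies).
#'
#' @param model a `metabolic_model`.
#' @param id,ids reaction id(s).
#' @param lb,ub new bounds (either may be `NULL` to keep).
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  k <- match(id, model$reactions$id)
  if (anyNA(k)) stop("unknown reaction: ", id[is.na(k)][1])
  if (!is.null(lb)) model$reactions$lower_bound[k] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[k] <- ub
  bad <- model$reactions$lower_bound[k] > model$reactions$upper_bound[k]
  if (any(bad)) stop("lower bound above upper bound for ", id[bad][1])
  model
}

#' @rdname set_bounds
#' @export
remove_reactions <- function(model, ids) {
  miss <- setdiff(ids, model$reactions$id)
  if (length(miss)) stop("cannot remove unknown reaction: ", miss[1])
  if (!is.na(model$objective_id) && model$objective_id %in% ids) {
    stop("cannot remove the objective reaction")
  }
  keep <- !model$reactions$id %in% ids
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$stoich <- model$stoich[model$reactions$id]
  if (length(model$extra_constraints)) {
    # deleted columns disappear from any extra rows referencing them
    model$extra_constraints <- lapply(model$extra_constraints, function(con) {
      con$coefs <- con$coefs[!names(con$coefs) %in% ids]
      con
    })
  }
  model
}

#' @rdname set_bounds
#' @param stoich named numeric stoichiometry of the new reaction.
#' @param gpr,subsystem reaction annotation.
#' @export
add_reaction <- function(model, id, stoich, lb, ub, gpr = "", subsystem = "") {
  if (id %in% model$reactions$id) stop("duplicate reaction id: ", id)
  model$reactions <- rbind(model$reactions, data.frame(
    id = id, lower_bound = lb, upper_bound = ub,
    gpr = gpr, subsystem = subsystem, stringsAsFactors = FALSE))
  model$stoich[[id]] <- stoich
  validate_model(model)
}

#' @rdname set_bounds
#' @param prefix string prepended (with `_`) to all ids.
#' @export
prefix_model <- function(model, prefix) {
  p <- function(x) paste0(prefix, "_", x)
  met_map <- stats::setNames(p(model$metabolites$id), model$metabolites$id)
  model$metabolites$id <- unname(met_map)
  model$reactions$id <- p(model$reactions$id)
  model$reactions$gpr <- vapply(model$reactions$gpr, function(g) {
    tree <- parse_gpr(g)
    if (is.null(tree)) return("")
    deparse_gpr(.gpr_rename(tree, p))
  }, character(1))
  model$stoich <- lapply(model$stoich, function(s) {
    stats::setNames(unname(s), unname(met_map[names(s)]))
  })
  names(model$stoich) <- model$reactions$id
  if (!is.na(model$objective_id)) model$objective_id <- p(model$objective_id)
  if (!is.null(model$b)) names(model$b) <- unname(met_map[names(model$b)])
  model
}

.gpr_rename <- function(tree, f) {
  if (is.character(tree)) return(f(tree))
  tree$args <- lapply(tree$args, .gpr_rename, f = f)
  tree
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model '%s': %d metabolites x %d reactions, %d genes\n",
              x$id, n_metabolites(x), n_reactions(x), length(model_genes(x))))
  if (!is.na(x$objective_id)) cat("  objective:", x$objective_id, "\n")
  if (length(x$extra_constraints)) {
    cat(sprintf("  + %d extra constraint row(s), %d extra variable(s)\n",
                length(x$extra_constraints),
                if (is.null(x$extra_vars)) 0L else nrow(x$extra_vars)))
  }
  invisible(x)
}
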