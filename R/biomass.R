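#' Biomass composition
#'
#' Macromolecular composition of the cell in dry-weight percent, a monomer
#' table per macromolecule, and ATP maintenance demands. The default weight
#' percents are the measured composition of *Anabaena variabilis*
#' (protein 48.3, carbohydrate 24.53, lipid 11.6, RNA 9.1, DNA 2.27,
#' ash 4.2 % gDCW).
#'
#' @param weight_percent named numeric, percentages by macromolecule; must
#'   sum to 100 within 0.5. `ash` carries no monomers.
#' @param monomer_table named list (one entry per non-ash macromolecule):
#'   data.frame with columns `metabolite`, `mole_fraction`, `mw`
#'   (g/mmol); mole fractions sum to 1 per macromolecule.
#' @param gam_atp growth-associated maintenance, mmol ATP/gDCW.
#' @param ngam_atp non-growth-associated maintenance, mmol ATP/gDCW/h.
#' @return object of class `biomass_composition`.
#' @export
biomass_composition <- function(weight_percent = c(protein = 48.3,
                                                   carbohydrate = 24.53,
                                                   lipid = 11.6, RNA = 9.1,
                                                   DNA = 2.27, ash = 4.2),
                                monomer_table, gam_atp = 50, ngam_atp = 0.13) {
  if (any(weight_percent < 0)) stop("weight percents must be non-negative")
  if (abs(sum(weight_percent) - 100) > 0.5) {
    stop("weight percents must sum to 100 within 0.5, got ",
         format(sum(weight_percent)))
  }
  macro <- setdiff(names(weight_percent)[weight_percent > 0], "ash")
  miss <- setdiff(macro, names(monomer_table))
  if (length(miss)) stop("monomer table missing for: ", miss[1])
  for (M in macro) {
    tb <- monomer_table[[M]]
    stopifnot(all(c("metabolite", "mole_fraction", "mw") %in% names(tb)))
    if (any(tb$mw <= 0)) stop("monomer with non-positive molecular weight in ", M)
    if (abs(sum(tb$mole_fraction) - 1) > 1e-6) {
      stop("mole fractions for ", M, " must sum to 1")
    }
  }
  structure(list(weight_percent = weight_percent,
                 monomer_table = monomer_table,
                 gam_atp = gam_atp, ngam_atp = ngam_atp),
            class = "biomass_composition")
}

#' Assemble a biomass reaction from a macromolecular composition
#'
#' For monomer k of macromolecule M with weight percent `wp_M`, mole
#' fraction `f_k` and molecular weight `MW_k` (g/mmol), the drain
#' coefficient is
#' `(wp_M / 100) * f_k / sum_k(f_k * MW_k)`  mmol/gDCW,
#' so that the dry weight of all consumed monomers equals
#' `(100 - ash%) / 100` g per g biomass. Growth-associated maintenance adds
#' `gam_atp` ATP + H2O -> ADP + Pi to the reaction.
#'
#' @param comp a [biomass_composition()].
#' @param id reaction id for the biomass drain.
#' @param atp,h2o,adp,pi_ metabolite ids of the maintenance currency.
#' @return a reaction description `list(id, stoich, lower_bound,
#'   upper_bound, gpr, subsystem)` suitable for [add_reaction()].
#' @export
build_biomass_reaction <- function(comp, id = "BIOMASS",
                                   atp = "atp_c", h2o = "h2o_c",
                                   adp = "adp_c", pi_ = "pi_c") {
  stopifnot(inherits(comp, "biomass_composition"))
  macro <- setdiff(names(comp$weight_percent)[comp$weight_percent > 0], "ash")
  stoich <- numeric(0)
  for (M in macro) {
    tb <- comp$monomer_table[[M]]
    denom <- sum(tb$mole_fraction * tb$mw)
    coefs <- (comp$weight_percent[[M]] / 100) * tb$mole_fraction / denom
    add <- stats::setNames(-coefs, tb$metabolite)
    for (j in seq_along(add)) {
      stoich[names(add)[j]] <- (if (names(add)[j] %in% names(stoich))
        stoich[[names(add)[j]]] else 0) + add[[j]]
    }
  }
  if (comp$gam_atp > 0) {
    gam <- stats::setNames(c(-1, -1, 1, 1) * comp$gam_atp,
                           c(atp, h2o, adp, pi_))
    for (j in seq_along(gam)) {
      stoich[names(gam)[j]] <- (if (names(gam)[j] %in% names(stoich))
        stoich[[names(gam)[j]]] else 0) + gam[[j]]
    }
  }
  list(id = id, stoich = stoich, lower_bound = 0, upper_bound = 1000,
       gpr = "", subsystem = "Biomass and maintenance")
}
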