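#' Deterministic toy cyanobacterial network
#'
#' A small (about 50 reactions) photoautotrophic, diazotrophy-capable metabolic
#' network used to exercise every stage of the two-cell pipeline without
#' external data. It contains lumped photosystems (PSII with the `psbJ_toy`
#' gene, PSI, NDH, ATP synthase, cytochrome oxidase), a minimal Calvin
#' cycle (RuBisCO `rbpc_toy`, bicarbonate equilibration `hco3e_toy`), an
#' oxidative pentose phosphate branch (`g6pdh2_toy`), sucrose synthesis and
#' alkaline-invertase cleavage, nitrate reduction, GS/Fd-GOGAT nitrogen
#' assimilation, nitrogenase (16 ATP + 8 Fd(red) per N2, evolving 1 H2;
#' gene `nif_toy`), uptake hydrogenase (`hup_toy`) and the bidirectional
#' NAD(P)H-linked Hox hydrogenase (`hox_toy`), plus a biomass reaction
#' assembled by [build_biomass_reaction()] from four pseudo-monomers
#' (glutamate for protein, a glycogen unit for carbohydrate, a C16 lipid
#' unit, and a nucleic-acid unit).
#'
#' Metabolite formulas use the pseudo-elements C, N, O, P (hydrogen and
#' charge are not tracked); every internal reaction except the biomass
#' drain is balanced in these elements.
#'
#' Generation is fully deterministic (no randomness).
#'
#' @return a validated `metabolic_model` with objective `BIOMASS`.
#' @export
make_toy_model <- function() {
  r <- function(id, eq, gene = "", sub = "", lb = NA, ub = NA) {
    data.frame(id = id, equation = eq, gpr = gene, subsystem = sub,
               lb = lb, ub = ub, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    # boundary exchanges (single metabolite; bounds set by the policy below)
    r("EX_photon", "photon[c] <->", sub = "Exchange"),
    r("EX_hco3",   "hco3[c] <->",   sub = "Exchange"),
    r("EX_no3",    "no3[c] <->",    sub = "Exchange"),
    r("EX_n2",     "n2[c] <->",     sub = "Exchange"),
    r("EX_o2",     "o2[c] <->",     sub = "Exchange"),
    r("EX_h2",     "h2[c] <->",     sub = "Exchange"),
    r("EX_frc",    "frc[c] <->",    sub = "Exchange"),
    r("EX_h2o",    "h2o[c] <->",    sub = "Exchange"),
    r("EX_pi",     "pi[c] <->",     sub = "Exchange"),
    r("EX_co2",    "co2[c] <->",    sub = "Exchange"),
    r("EX_for",    "for[c] <->",    sub = "Exchange"),
    r("EX_nh4",    "nh4[c] <->",    sub = "Exchange"),
    # periplasmic transfers for the intercellular shuttle metabolites
    r("SUCt", "suc[c] <-> suc[p]", "suct_toy", "Transport"),
    r("GLUt", "glu[c] <-> glu[p]", "glut_toy", "Transport"),
    r("GLNt", "gln[c] <-> gln[p]", "glnt_toy", "Transport"),
    # photosynthetic electron transport and energy metabolism
    r("PSII", "2 photon[c] + h2o[c] -> 0.5 o2[c] + 2 eq[c] + 2 pmf[c]",
      "psbJ_toy", "Photosynthesis"),
    r("PSI",  "photon[c] + eq[c] + fdox[c] -> fdred[c] + pmf[c]",
      "psaA_toy", "Photosynthesis"),
    r("NDH",  "nadh[c] -> nad[c] + 2 eq[c] + pmf[c]", "ndh_toy",
      "Respiratory electron transport"),
    r("FNR",  "2 fdred[c] + nadp[c] -> 2 fdox[c] + nadph[c]", "fnr_toy",
      "Photosynthesis"),
    r("ATPS", "3 pmf[c] + adp[c] + pi[c] -> atp[c] + h2o[c]", "atps_toy",
      "Oxidative phosphorylation"),
    r("COX",  "nadh[c] + 0.5 o2[c] -> nad[c] + 2 pmf[c] + h2o[c]", "cox_toy",
      "Respiratory electron transport"),
    # carbon fixation (Calvin cycle, lumped)
    r("HCO3E", "hco3[c] -> co2[c] + h2o[c]", "hco3e_toy", "Carbon fixation"),
    r("RBPC",  "rubp[c] + co2[c] + h2o[c] -> 2 pg3[c]", "rbpc_toy",
      "Carbon fixation"),
    r("CBBR",  "pg3[c] + atp[c] + nadph[c] -> g3p[c] + adp[c] + pi[c] + nadp[c]",
      "cbbr_toy", "Carbon fixation"),
    r("GAPD",  "g3p[c] + adp[c] + pi[c] + nad[c] -> pg3[c] + atp[c] + nadh[c]",
      "gapd_toy", "Glycolysis"),
    r("TKTL",  "3 ru5p[c] <-> 2 f6p[c] + g3p[c]", "tktl_toy",
      "Pentose phosphate pathway"),
    r("PRK",   "ru5p[c] + atp[c] -> rubp[c] + adp[c]", "prk_toy",
      "Carbon fixation"),
    # sugar metabolism
    r("FBP",  "2 g3p[c] + h2o[c] -> f6p[c] + pi[c]", "fbp_toy", "Glycolysis"),
    r("PFK",  "f6p[c] + atp[c] -> 2 g3p[c] + adp[c]", "pfk_toy", "Glycolysis"),
    r("PGI",  "g6p[c] <-> f6p[c]", "pgi_toy", "Glycolysis"),
    r("G6PDH2", "g6p[c] + 2 nadp[c] + h2o[c] -> ru5p[c] + 2 nadph[c] + co2[c]",
      "g6pdh2_toy", "Pentose phosphate pathway"),
    r("GALU", "g6p[c] + udp[c] -> udpg[c] + pi[c]", "galu_toy",
      "Sucrose metabolism"),
    r("SPS",  "f6p[c] + udpg[c] + h2o[c] -> suc[c] + udp[c] + pi[c]",
      "sps_toy", "Sucrose metabolism"),
    r("INV",  "suc[c] + h2o[c] -> 2 frc[c]", "inv_toy", "Sucrose metabolism"),
    r("FRK",  "frc[c] + atp[c] -> f6p[c] + adp[c]", "frk_toy",
      "Sucrose metabolism"),
    r("GLYS", "udpg[c] -> glyco[c] + udp[c]", "glgA_toy",
      "Carbohydrate storage"),
    # lower glycolysis and the formate branch
    r("PYK",  "pg3[c] + adp[c] -> pyr[c] + atp[c] + h2o[c]", "pyk_toy",
      "Glycolysis"),
    r("PFL",  "pyr[c] -> for[c] + ac2[c]", "pfl_toy", "Fermentation"),
    r("PFOR", "pyr[c] + 2 fdox[c] -> ac2[c] + co2[c] + 2 fdred[c]",
      "pfor_toy", "Fermentation"),
    r("AKGS", "2 pyr[c] + h2o[c] + nad[c] -> akg[c] + co2[c] + nadh[c]",
      "akgs_toy", "TCA (incomplete)"),
    # nitrogen metabolism
    r("NO3R", "no3[c] + 8 fdred[c] -> nh4[c] + 3 h2o[c] + 8 fdox[c]",
      "nar_toy", "Nitrogen metabolism"),
    r("GLNS", "glu[c] + nh4[c] + atp[c] -> gln[c] + adp[c] + pi[c]",
      "glns_toy", "Nitrogen metabolism"),
    r("GOGAT", "gln[c] + akg[c] + 2 fdred[c] -> 2 glu[c] + 2 fdox[c]",
      "gogat_toy", "Nitrogen metabolism"),
    r("NIT", paste0("n2[c] + 16 atp[c] + 8 fdred[c] + 16 h2o[c] -> ",
                    "2 nh4[c] + h2[c] + 16 adp[c] + 16 pi[c] + 8 fdox[c]"),
      "nif_toy", "Nitrogen fixation"),
    # hydrogen metabolism
    r("HUP",  "h2[c] + 2 fdox[c] -> 2 fdred[c]", "hup_toy",
      "Hydrogen metabolism"),
    r("HOXN", "nadh[c] <-> nad[c] + h2[c]", "hox_toy", "Hydrogen metabolism"),
    r("HOXP", "nadph[c] <-> nadp[c] + h2[c]", "hox_toy", "Hydrogen metabolism"),
    # biomass precursor assembly and maintenance
    r("LIPS", paste0("8 ac2[c] + 14 nadph[c] + 7 atp[c] + 7 h2o[c] -> ",
                     "lipid[c] + 14 nadp[c] + 7 adp[c] + 7 pi[c]"),
      "lips_toy", "Lipid synthesis"),
    r("RNAS", paste0("ru5p[c] + gln[c] + 2 atp[c] + 2 h2o[c] -> ",
                     "rna[c] + glu[c] + 2 adp[c] + 2 pi[c]"),
      "rnas_toy", "Nucleotide synthesis"),
    r("NGAM", "atp[c] + h2o[c] -> adp[c] + pi[c]", "",
      "Biomass and maintenance")
  )
  parsed <- Map(parse_equation, tab$equation, tab$id)
  mets <- unique(do.call(rbind, lapply(parsed, `[[`, "metabolites")))
  rownames(mets) <- NULL
  mets$formula <- unname(.toy_formulas[mets$name])
  rxns <- data.frame(id = tab$id,
                     lower_bound = ifelse(vapply(parsed, `[[`, logical(1),
                                                 "reversible"), -1000, 0),
                     upper_bound = 1000,
                     gpr = tab$gpr, subsystem = tab$subsystem,
                     stringsAsFactors = FALSE)
  model <- new_metabolic_model(
    id = "toy_anabaena",
    metabolites = mets, reactions = rxns,
    stoich = stats::setNames(lapply(parsed, `[[`, "stoich"), tab$id))
  model <- apply_bound_policy(model, toy_bound_policy())
  # non-growth-associated maintenance is a hard demand
  comp <- toy_biomass_composition()
  model <- set_bounds(model, "NGAM", lb = comp$ngam_atp)
  bm <- build_biomass_reaction(comp)
  model <- add_reaction(model, bm$id, bm$stoich, bm$lower_bound,
                        bm$upper_bound, bm$gpr, bm$subsystem)
  model$objective_id <- "BIOMASS"
  validate_model(model)
}

# pseudo-element formulas (C, N, O, P; hydrogen untracked)
.toy_formulas <- c(
  photon = "", hco3 = "CO3", no3 = "NO3", n2 = "N2", o2 = "O2", h2 = "",
  frc = "C6O6", h2o = "O", pi = "O4P", co2 = "CO2", "for" = "CO2",
  nh4 = "N", eq = "", pmf = "", fdred = "", fdox = "",
  nad = "C21N7O14P2", nadh = "C21N7O14P2",
  nadp = "C21N7O17P3", nadph = "C21N7O17P3",
  atp = "C10N5O13P3", adp = "C10N5O10P2",
  rubp = "C5O11P2", pg3 = "C3O7P", g3p = "C3O6P", ru5p = "C5O8P",
  f6p = "C6O9P", g6p = "C6O9P", udpg = "C6O5", udp = "",
  suc = "C12O11", pyr = "C3O3", ac2 = "C2O", akg = "C5O5",
  glu = "C5NO4", gln = "C5N2O3", glyco = "C6O5", lipid = "C16O8",
  rna = "C5NO7P")

#' @rdname make_toy_model
#' @export
toy_bound_policy <- function() {
  bound_policy(
    free_exchange_ids = c("EX_h2o", "EX_pi", "EX_o2"),
    limited_exchange = c(EX_hco3 = -10, EX_no3 = -10, EX_photon = -10))
}

#' @rdname make_toy_model
#' @export
toy_biomass_composition <- function() {
  # A. variabilis macromolecular weight percents; the DNA pool is merged
  # into the nucleic-acid pseudo-monomer so the toy uses four monomers.
  # Monomer weights follow the pseudo-element formulas (g/mmol).
  biomass_composition(
    weight_percent = c(protein = 48.3, carbohydrate = 24.53, lipid = 11.6,
                       nucleic_acid = 11.37, ash = 4.2),
    monomer_table = list(
      protein = data.frame(metabolite = "glu_c", mole_fraction = 1,
                           mw = 0.138),
      carbohydrate = data.frame(metabolite = "glyco_c", mole_fraction = 1,
                                mw = 0.152),
      lipid = data.frame(metabolite = "lipid_c", mole_fraction = 1,
                         mw = 0.320),
      nucleic_acid = data.frame(metabolite = "rna_c", mole_fraction = 1,
                                mw = 0.217)),
    gam_atp = 50, ngam_atp = 0.13)
}

#' Parse an elemental composition string
#'
#' @param formula e.g. `"C6O9P"`; empty/NA gives an empty vector.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(stats::setNames(numeric(0), character(0)))
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9.]*)", formula))[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  ct <- sub("^[A-Z][a-z]?", "", toks)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  tapply(ct, el, sum)
}

#' Elemental imbalance of every reaction
#'
#' @param model a `metabolic_model` with metabolite formulas.
#' @param elements elements to check.
#' @return matrix (reactions x elements) of net element production;
#'   zero rows are balanced. Exchange reactions and the biomass drain are
#'   unbalanced by construction and are best excluded by the caller.
#' @export
element_balance <- function(model, elements = c("C", "N", "O", "P")) {
  fmat <- matrix(0, nrow = n_metabolites(model), ncol = length(elements),
                 dimnames = list(model$metabolites$id, elements))
  for (i in seq_len(n_metabolites(model))) {
    f <- parse_formula(model$metabolites$formula[i])
    common <- intersect(names(f), elements)
    fmat[i, common] <- f[common]
  }
  out <- t(vapply(model$stoich, function(st) {
    drop(st %*% fmat[names(st), , drop = FALSE])
  }, numeric(length(elements))))
  colnames(out) <- elements
  out
}

#' Toy expression scenarios
#'
#' `toy_scenario()` describes a deterministic two-cell expression profile;
#' `make_expression()` realises it for a model's genes. Expression units
#' are microarray-like and arbitrary: only the product `E * C` enters the
#' regulated model. Scenarios:
#'
#' * `baseline`: every gene at `expression_default` in both cell types.
#' * `psii_bottleneck`: as the differentiated profile below, but the PSII
#'   gene (`bottleneck_gene`, default `psbJ_toy`) is measured at
#'   `bottleneck_level` (default 56, well below the default level) in the
#'   vegetative cells, making PSII the growth-limiting capacity.
#' * `hup_knockout`: differentiated profile with the uptake-hydrogenase
#'   gene at zero in both cells.
#' * `heterotrophic`: the differentiated profile itself (conditions differ
#'   through uptake bounds, not expression).
#'
#' The differentiated heterocyst profile sets the genes of the
#' vegetative-only functions (PSII, RuBisCO, bicarbonate equilibration,
#' Fd-GOGAT, nitrate reduction) to zero and the nitrogenase/hydrogenase
#' genes (`nif_toy`, `hox_toy`, `hup_toy`) to twice the default level.
#'
#' @param name scenario name.
#' @param expression_default expression level of unremarkable genes.
#' @param bottleneck_gene gene limited under `psii_bottleneck`.
#' @param bottleneck_level its vegetative expression level (must be below
#'   `expression_default`).
#' @return `toy_scenario()`: a `toy_scenario` object; `make_expression()`:
#'   a data.frame with columns `gene_id`, `E_veg`, `E_het`.
#' @export
toy_scenario <- function(name = c("baseline", "psii_bottleneck",
                                  "hup_knockout", "heterotrophic"),
                         expression_default = 500,
                         bottleneck_gene = "psbJ_toy",
                         bottleneck_level = 56) {
  name <- match.arg(name)
  if (name == "psii_bottleneck" && bottleneck_level >= expression_default) {
    stop("bottleneck_level must be below expression_default")
  }
  structure(list(name = name, expression_default = expression_default,
                 bottleneck_gene = bottleneck_gene,
                 bottleneck_level = bottleneck_level),
            class = "toy_scenario")
}

#' @rdname toy_scenario
#' @param model the (single-cell) model whose genes are profiled.
#' @param scenario a `toy_scenario`.
#' @export
make_expression <- function(model, scenario = toy_scenario()) {
  stopifnot(inherits(scenario, "toy_scenario"))
  genes <- model_genes(model)
  if (scenario$name == "psii_bottleneck" &&
      !scenario$bottleneck_gene %in% genes) {
    stop("bottleneck gene absent from model: ", scenario$bottleneck_gene)
  }
  d <- scenario$expression_default
  out <- data.frame(gene_id = genes, E_veg = d, E_het = d,
                    stringsAsFactors = FALSE)
  if (scenario$name == "baseline") return(out)
  veg_only <- c("psbJ_toy", "rbpc_toy", "hco3e_toy", "gogat_toy", "nar_toy")
  het_high <- c("nif_toy", "hox_toy", "hup_toy")
  out$E_het[out$gene_id %in% veg_only] <- 0
  out$E_het[out$gene_id %in% het_high] <- 2 * d
  if (scenario$name == "psii_bottleneck") {
    out$E_veg[out$gene_id == scenario$bottleneck_gene] <-
      scenario$bottleneck_level
  }
  if (scenario$name == "hup_knockout") {
    out$E_veg[out$gene_id == "hup_toy"] <- 0
    out$E_het[out$gene_id == "hup_toy"] <- 0
  }
  out
}

#' Expression table input/output
#'
#' TSV with columns `gene_id`, `E_veg`, `E_het`.
#'
#' @param expr expression data.frame.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(all(c("gene_id", "E_veg", "E_het") %in% names(expr)))
  utils::write.table(expr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  expr <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "E_veg", "E_het"), names(expr))
  if (length(miss)) stop("expression table lacks column(s): ",
                         paste(miss, collapse = ", "))
  expr
}
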