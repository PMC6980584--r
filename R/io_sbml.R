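#' SBML Level 3 (FBC) input/output
#'
#' Writes and reads the SBML subset used by constraint-based models:
#' compartments, species (with optional chemical formula), reactions with
#' stoichiometries, FBC flux bounds (as shared parameters), FBC gene-product
#' associations (nested and/or trees) and the active FBC objective.
#' `write_sbml()` / `read_sbml()` round-trip all `metabolic_model` fields;
#' extra constraint rows (photon budget, gene rows) are not part of SBML and
#' are not serialized.
#'
#' @param model a `metabolic_model`.
#' @param path file path of the SBML document.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
  fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root("sbml",
    "xmlns" = sbml_ns, "xmlns:fbc" = fbc_ns,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = .sbml_sid(model$id),
                             "fbc:strict" = "true")

  tags <- names(.compartment_tags)[match(unique(model$metabolites$compartment),
                                         .compartment_tags)]
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (tg in tags) {
    xml2::xml_add_child(loc, "compartment", id = tg,
                        name = .compartment_tags[[tg]], constant = "true")
  }

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  met <- model$metabolites
  met_tag <- names(.compartment_tags)[match(met$compartment, .compartment_tags)]
  for (i in seq_len(nrow(met))) {
    sp <- xml2::xml_add_child(los, "species",
      id = paste0("M_", .sbml_sid(met$id[i])), name = met$name[i],
      compartment = met_tag[i], hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    if (!is.na(met$formula[i]) && nzchar(met$formula[i])) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", met$formula[i])
    }
  }

  rxn <- model$reactions
  bnd_vals <- sort(unique(c(rxn$lower_bound, rxn$upper_bound)))
  bnd_ids <- stats::setNames(sprintf("bnd_%d", seq_along(bnd_vals)),
                             sprintf("%.17g", bnd_vals))
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(bnd_vals)) {
    xml2::xml_add_child(lop, "parameter", id = bnd_ids[[i]],
                        value = sprintf("%.17g", bnd_vals[i]),
                        constant = "true")
  }

  genes <- model_genes(model)
  if (length(genes)) {
    log_ <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(log_, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", .sbml_sid(g)),
                          "fbc:label" = g)
    }
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_len(nrow(rxn))) {
    nd <- xml2::xml_add_child(lor, "reaction",
      id = paste0("R_", .sbml_sid(rxn$id[k])),
      reversible = tolower(rxn$lower_bound[k] < 0), fast = "false",
      "fbc:lowerFluxBound" = bnd_ids[[sprintf("%.17g", rxn$lower_bound[k])]],
      "fbc:upperFluxBound" = bnd_ids[[sprintf("%.17g", rxn$upper_bound[k])]])
    st <- model$stoich[[k]]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lr <- xml2::xml_add_child(nd, "listOfReactants")
      for (j in seq_along(subs)) {
        xml2::xml_add_child(lr, "speciesReference",
          species = paste0("M_", .sbml_sid(names(subs)[j])),
          stoichiometry = sprintf("%.17g", -subs[[j]]), constant = "true")
      }
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(nd, "listOfProducts")
      for (j in seq_along(prods)) {
        xml2::xml_add_child(lp, "speciesReference",
          species = paste0("M_", .sbml_sid(names(prods)[j])),
          stoichiometry = sprintf("%.17g", prods[[j]]), constant = "true")
      }
    }
    tree <- parse_gpr(rxn$gpr[k])
    if (!is.null(tree)) {
      gpa <- xml2::xml_add_child(nd, "fbc:geneProductAssociation")
      .sbml_write_gpr(gpa, tree)
    }
    if (nzchar(rxn$subsystem[k])) {
      nt <- xml2::xml_add_child(nd, "notes")
      bd <- xml2::xml_add_child(nt, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(bd, "p", paste0("SUBSYSTEM: ", rxn$subsystem[k]))
    }
  }

  if (!is.na(model$objective_id)) {
    loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
      "fbc:reaction" = paste0("R_", .sbml_sid(model$objective_id)),
      "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.sbml_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

.sbml_write_gpr <- function(parent, tree) {
  if (is.character(tree)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", .sbml_sid(tree)))
    return(invisible(NULL))
  }
  nd <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
  for (a in tree$args) .sbml_write_gpr(nd, a)
  invisible(NULL)
}

#' @rdname write_sbml
#' @return [read_sbml()]: a validated `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)

  comp_nodes <- xml2::xml_find_all(mdl, ".//listOfCompartments/compartment")
  comp_name <- stats::setNames(
    xml2::xml_attr(comp_nodes, "name"), xml2::xml_attr(comp_nodes, "id"))
  comp_name[is.na(comp_name)] <- .compartment_tags[names(comp_name)[is.na(comp_name)]]

  sp_nodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  sid <- sub("^M_", "", xml2::xml_attr(sp_nodes, "id"))
  mets <- data.frame(
    id = sid,
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")), sid,
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = unname(comp_name[xml2::xml_attr(sp_nodes, "compartment")]),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula"),
    stringsAsFactors = FALSE)

  par_nodes <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  rid <- sub("^R_", "", xml2::xml_attr(rx_nodes, "id"))
  if (!length(rx_nodes)) stop("SBML model has no reactions")
  lb <- ub <- numeric(length(rx_nodes))
  gprs <- subsys <- character(length(rx_nodes))
  stoich <- vector("list", length(rx_nodes))
  for (k in seq_along(rx_nodes)) {
    nd <- rx_nodes[[k]]
    lb[k] <- .sbml_bound(nd, "lowerFluxBound", par_val, -1000)
    ub[k] <- .sbml_bound(nd, "upperFluxBound", par_val, 1000)
    refs <- function(xp, sign) {
      rr <- xml2::xml_find_all(nd, xp)
      if (!length(rr)) return(numeric(0))
      stats::setNames(sign * as.numeric(xml2::xml_attr(rr, "stoichiometry")),
                      sub("^M_", "", xml2::xml_attr(rr, "species")))
    }
    st <- c(refs(".//listOfReactants/speciesReference", -1),
            refs(".//listOfProducts/speciesReference", +1))
    agg <- tapply(unname(st), names(st), sum)
    stoich[[k]] <- stats::setNames(as.numeric(agg),
                                   names(agg))[unique(names(st))]
    gpa <- xml2::xml_find_first(nd, ".//*[local-name()='geneProductAssociation']/*")
    gprs[k] <- if (inherits(gpa, "xml_missing")) "" else {
      deparse_gpr(.sbml_read_gpr(gpa))
    }
    note <- xml2::xml_find_first(nd, ".//notes//p")
    subsys[k] <- if (inherits(note, "xml_missing")) "" else {
      sub("^\\s*SUBSYSTEM:\\s*", "", xml2::xml_text(note))
    }
  }

  obj_node <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  obj <- if (inherits(obj_node, "xml_missing")) NA_character_ else {
    sub("^R_", "", xml2::xml_attr(obj_node, "reaction"))
  }

  new_metabolic_model(
    id = xml2::xml_attr(mdl, "id"),
    metabolites = mets,
    reactions = data.frame(id = rid, lower_bound = lb, upper_bound = ub,
                           gpr = gprs, subsystem = subsys,
                           stringsAsFactors = FALSE),
    stoich = stats::setNames(stoich, rid),
    objective_id = obj)
}

.sbml_bound <- function(nd, attr, par_val, default) {
  ref <- xml2::xml_attr(nd, attr)
  if (is.na(ref)) return(default)
  if (ref %in% names(par_val)) return(par_val[[ref]])
  suppressWarnings(v <- as.numeric(ref))
  if (is.na(v)) stop("unresolvable flux bound parameter: ", ref)
  v
}

.sbml_read_gpr <- function(node) {
  nm <- sub("^.*:", "", xml2::xml_name(node))
  if (nm == "geneProductRef") {
    return(sub("^G_", "", xml2::xml_attr(node, "geneProduct")))
  }
  if (!nm %in% c("and", "or")) stop("unsupported GPR element: ", nm)
  list(op = nm, args = lapply(xml2::xml_children(node), .sbml_read_gpr))
}
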