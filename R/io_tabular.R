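#' Read and write stoichiometric models
#'
#' Two on-disk formats are supported. `format = "tabular"` is a strict TSV
#' dialect with columns `reaction_id`, `equation`, `lower_bound`,
#' `upper_bound`, `gpr`, `subsystem` and an optional logical `objective`
#' column; reaction equations follow the grammar
#' `"coef met[comp] + ... -> ..."` (or `<->`), with compartment tags
#' `[c]`ytoplasm, `[t]`hylakoid, `[p]`eriplasm, `[e]`xtracellular, and one
#' side may be empty for boundary exchanges. `format = "sbml"` is SBML
#' Level 3 with the FBC package (see [write_sbml()]).
#'
#' @param path file path.
#' @param format `"tabular"` or `"sbml"`.
#' @return [load_model()]: a validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         tabular = .load_model_tabular(path),
         sbml = read_sbml(path))
}

#' @rdname load_model
#' @param model a `metabolic_model`.
#' @export
write_model <- function(model, path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  switch(format,
         tabular = .write_model_tabular(model, path),
         sbml = write_sbml(model, path))
  invisible(path)
}

.compartment_tags <- c(c = "cytoplasm", t = "thylakoid",
                       p = "periplasm", e = "extracellular")

.met_id <- function(name, tag) paste0(name, "_", tag)

#' Parse a reaction equation string
#'
#' @param eq equation string, e.g. `"2 h_c + 0.5 o2_c"`-style
#'   `"2 H[c] + 0.5 O2[c] -> H2O[c]"`.
#' @param rxn reaction id used in error messages.
#' @return list with `stoich` (named coefficients over metabolite ids),
#'   `metabolites` (data.frame id/name/compartment), `reversible`.
#' @export
parse_equation <- function(eq, rxn = "?") {
  err <- function(...) stop("reaction '", rxn, "': ", ..., call. = FALSE)
  eq <- trimws(eq)
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (rev) "<->" else "->", fixed = TRUE)[[1]]
  if (!grepl("->", eq, fixed = TRUE) || length(sides) > 2L) {
    err("malformed equation '", eq, "'")
  }
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(NULL)
    terms <- strsplit(side, "\\s*\\+\\s+")[[1]]
    out <- lapply(terms, function(tm) {
      tm <- trimws(tm)
      mm <- regmatches(tm, regexec(
        "^(?:([0-9.eE+-]+)\\s+)?([A-Za-z0-9_.-]+)\\[([a-z])\\]$", tm))[[1]]
      if (!length(mm)) err("malformed term '", tm, "'")
      coef <- if (nzchar(mm[2])) suppressWarnings(as.numeric(mm[2])) else 1
      if (is.na(coef)) err("bad coefficient in term '", tm, "'")
      if (!mm[4] %in% names(.compartment_tags)) {
        err("unknown compartment suffix '[", mm[4], "]'")
      }
      list(name = mm[3], tag = mm[4], coef = sign * coef)
    })
    out
  }
  terms <- c(parse_side(sides[1], -1), parse_side(sides[2], +1))
  if (!length(terms)) err("empty equation")
  ids <- vapply(terms, function(t) .met_id(t$name, t$tag), character(1))
  stoich <- tapply(vapply(terms, `[[`, numeric(1), "coef"), ids, sum)
  stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  stoich <- stoich[stoich != 0]
  mets <- unique(data.frame(
    id = ids,
    name = vapply(terms, `[[`, character(1), "name"),
    compartment = unname(.compartment_tags[vapply(terms, `[[`, character(1), "tag")]),
    stringsAsFactors = FALSE))
  list(stoich = stoich, metabolites = mets, reversible = rev)
}

.deparse_equation <- function(stoich, met_tab, reversible) {
  tag_of <- stats::setNames(names(.compartment_tags)[match(met_tab$compartment,
                                                           .compartment_tags)],
                            met_tab$id)
  name_of <- stats::setNames(met_tab$name, met_tab$id)
  fmt <- function(ids, coefs) {
    if (!length(ids)) return("")
    paste(vapply(seq_along(ids), function(i) {
      cf <- abs(coefs[i])
      tok <- paste0(name_of[[ids[i]]], "[", tag_of[[ids[i]]], "]")
      if (cf == 1) tok else paste(format(cf, digits = 15, scientific = FALSE), tok)
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt(names(stoich)[stoich < 0], stoich[stoich < 0])
  rhs <- fmt(names(stoich)[stoich > 0], stoich[stoich > 0])
  trimws(paste(lhs, if (reversible) "<->" else "->", rhs))
}

.load_model_tabular <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("reaction_id", "equation", "lower_bound", "upper_bound",
            "gpr", "subsystem")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("tabular model lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$reaction_id)) {
    stop("duplicate reaction id: ", tab$reaction_id[duplicated(tab$reaction_id)][1])
  }
  tab$gpr[is.na(tab$gpr)] <- ""
  tab$subsystem[is.na(tab$subsystem)] <- ""
  parsed <- Map(parse_equation, tab$equation, tab$reaction_id)
  mets <- unique(do.call(rbind, lapply(parsed, `[[`, "metabolites")))
  rownames(mets) <- NULL
  obj <- NA_character_
  if ("objective" %in% names(tab)) {
    flag <- as.logical(tab$objective) %in% TRUE
    if (sum(flag) > 1L) stop("more than one objective reaction flagged")
    if (any(flag)) obj <- tab$reaction_id[flag]
  }
  new_metabolic_model(
    id = sub("\\.[a-zA-Z]+$", "", basename(path)),
    metabolites = mets,
    reactions = data.frame(id = tab$reaction_id,
                           lower_bound = as.numeric(tab$lower_bound),
                           upper_bound = as.numeric(tab$upper_bound),
                           gpr = tab$gpr, subsystem = tab$subsystem,
                           stringsAsFactors = FALSE),
    stoich = stats::setNames(lapply(parsed, `[[`, "stoich"), tab$reaction_id),
    objective_id = obj)
}

.write_model_tabular <- function(model, path) {
  rxn <- model$reactions
  eqs <- vapply(seq_len(nrow(rxn)), function(k) {
    .deparse_equation(model$stoich[[k]], model$metabolites,
                      reversible = rxn$lower_bound[k] < 0)
  }, character(1))
  out <- data.frame(reaction_id = rxn$id, equation = eqs,
                    lower_bound = rxn$lower_bound,
                    upper_bound = rxn$upper_bound,
                    gpr = rxn$gpr, subsystem = rxn$subsystem,
                    objective = rxn$id %in% model$objective_id,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
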