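#' Gene-protein-reaction (GPR) rule handling
#'
#' GPR rules are boolean AND/OR expressions over gene identifiers, e.g.
#' `"(g1 and g2) or g3"`. They are parsed to a tree, can be normalised to
#' disjunctive normal form (a list of AND-conjunctions, one per isozyme
#' alternative), and deparsed back to a canonical string.
#'
#' @param rule GPR rule string; `""`/`NA` denote a reaction with no gene.
#' @return `parse_gpr()`: a tree (`NULL`, a gene id string, or
#'   `list(op = "and"|"or", args = list(...))`).
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- .gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- .gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule: trailing input in '", rule, "'")
  }
  tree
}

.gpr_tokenize <- function(rule) {
  rule <- gsub("&&?", " and ", rule)
  rule <- gsub("\\|\\|?", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  bad <- grepl("[^A-Za-z0-9_.()-]", toks)
  if (any(bad)) stop("malformed GPR rule: bad token '", toks[bad][1], "'")
  toks
}

.gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

.gpr_parse_or <- function(st) {
  args <- list(.gpr_parse_and(st))
  while (!is.na(.gpr_peek(st)) && tolower(.gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

.gpr_parse_and <- function(st) {
  args <- list(.gpr_parse_atom(st))
  while (!is.na(.gpr_peek(st)) && tolower(.gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

.gpr_parse_atom <- function(st) {
  tok <- .gpr_peek(st)
  if (is.na(tok)) stop("malformed GPR rule: unexpected end of input")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- .gpr_parse_or(st)
    if (is.na(.gpr_peek(st)) || .gpr_peek(st) != ")") {
      stop("malformed GPR rule: missing ')'")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok %in% c(")", "and", "or", "AND", "OR")) {
    stop("malformed GPR rule: unexpected token '", tok, "'")
  }
  st$pos <- st$pos + 1L
  tok
}

#' @rdname parse_gpr
#' @param tree a parsed GPR tree.
#' @return `gpr_genes()`: character vector of gene ids in the rule.
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' @rdname parse_gpr
#' @return `gpr_dnf()`: list of character vectors; each vector is one
#'   OR-alternative (an AND-conjunction of gene ids).
#' @export
gpr_dnf <- function(tree) {
  if (is.null(tree)) return(list())
  if (is.character(tree)) return(list(tree))
  alts <- lapply(tree$args, gpr_dnf)
  if (tree$op == "or") {
    out <- do.call(c, alts)
  } else {
    # cartesian product of conjunctions
    out <- list(character())
    for (a in alts) {
      out <- unlist(lapply(out, function(pre) {
        lapply(a, function(conj) c(pre, conj))
      }), recursive = FALSE)
    }
  }
  unique(lapply(out, function(x) sort(unique(x))))
}

#' @rdname parse_gpr
#' @return `deparse_gpr()`: canonical rule string.
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (!is.character(a) && a$op != tree$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
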