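#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers in which `and`
#' joins subunits of an enzyme complex and `or` joins isozymes. `and` binds
#' tighter than `or`, keywords are matched case-insensitively, and any
#' maximal run of non-space, non-parenthesis characters other than the two
#' keywords is taken as a gene identifier. Associative chains are flattened,
#' so `a or b or c` becomes one three-child `or` node.
#'
#' @param rule A GPR string, e.g. `"(A and (B or (C and D))) or E"`. An
#'   empty or `NA` rule yields `NULL` (no gene association).
#' @return A GPR tree: nested lists with fields `kind` (`"gene"`, `"and"`
#'   or `"or"`), `gene` (leaf nodes) and `children` (operator nodes, always
#'   at least two after normalization), or `NULL` for an empty rule.
#' @seealso [gpr_factors()], [gpr_to_string()]
#' @examples
#' tree <- parse_gpr("(A and (B or (C and D))) or E")
#' gpr_to_string(tree)
#' gpr_factors(tree)
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)

  m <- gregexpr("[()]|[^()[:space:]]+", rule)[[1L]]
  toks <- regmatches(rule, gregexpr("[()]|[^()[:space:]]+", rule))[[1L]]
  pos <- as.integer(m)
  n <- length(toks)
  i <- 0L # index of last consumed token

  peek <- function() if (i < n) toks[[i + 1L]] else NA_character_
  advance <- function() {
    i <<- i + 1L
    toks[[i]]
  }
  fail <- function(msg, at = if (i < n) pos[[i + 1L]] else nchar(rule) + 1L) {
    rlang::abort(
      sprintf("GPR parse error at position %d: %s (rule: %s)", at, msg, rule),
      class = "regflux_gpr_error"
    )
  }

  parse_primary <- function() {
    tok <- peek()
    if (is.na(tok)) fail("unexpected end of rule")
    if (tok == ")") fail("unbalanced parentheses: unexpected ')'")
    if (tok == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) fail("unbalanced parentheses: missing ')'")
      advance()
      return(node)
    }
    if (tolower(tok) %in% c("and", "or")) {
      fail(sprintf("operand expected, found '%s'", tok))
    }
    advance()
    gpr_gene(tok)
  }

  parse_and <- function() {
    nodes <- list(parse_primary())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      nodes <- c(nodes, list(parse_primary()))
    }
    gpr_op("and", nodes)
  }

  parse_or <- function() {
    nodes <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      nodes <- c(nodes, list(parse_and()))
    }
    gpr_op("or", nodes)
  }

  tree <- parse_or()
  if (i < n) fail(sprintf("trailing input '%s'", peek()))
  tree
}

gpr_gene <- function(id) {
  structure(list(kind = "gene", gene = id), class = "gpr_tree")
}

# n-ary operator node; flattens same-kind children and collapses singletons
gpr_op <- function(kind, children) {
  if (length(children) == 1L) return(children[[1L]])
  flat <- list()
  for (ch in children) {
    if (identical(ch$kind, kind)) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  structure(list(kind = kind, children = flat), class = "gpr_tree")
}

#' Canonical string form of a GPR tree
#'
#' Output uses lower-case `and`/`or` and is fully parenthesized, so
#' `parse_gpr(gpr_to_string(tree))` reproduces `tree` exactly.
#'
#' @param tree A GPR tree from [parse_gpr()], or `NULL`.
#' @return A string, or `NA_character_` for `NULL`.
#' @export
gpr_to_string <- function(tree) {
  if (is.null(tree)) return(NA_character_)
  if (tree$kind == "gene") return(tree$gene)
  inner <- vapply(tree$children, gpr_to_string, character(1L))
  paste0("(", paste(inner, collapse = paste0(" ", tree$kind, " ")), ")")
}

#' Genes referenced by a GPR tree
#'
#' @param tree A GPR tree or `NULL`.
#' @return Character vector of unique gene ids (possibly empty).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0L))
  if (tree$kind == "gene") return(tree$gene)
  unique(unlist(lapply(tree$children, gpr_genes)))
}

#' GPR subunit factors
#'
#' Distributes the weight of a reaction over its genes. The root of the
#' rule carries factor 1; an `or` node (isozymes) passes its factor
#' unchanged to every child, because any single branch can form a fully
#' functional enzyme; an `and` node with `c` children (complex subunits)
#' passes `factor * c` to each child, because each subunit constitutes a
#' 1/c share of the complex. A gene's factor is the value arriving at its
#' leaf; if a gene occurs in several leaves, the minimum (its strongest
#' stoichiometric contribution) is kept.
#'
#' @param tree A non-empty GPR tree from [parse_gpr()].
#' @return Named numeric vector of factors (all >= 1), sorted by gene id.
#' @examples
#' gpr_factors(parse_gpr("(A and (B or (C and D))) or E"))
#' # A = B = 2, C = D = 4, E = 1
#' @export
gpr_factors <- function(tree) {
  if (is.null(tree)) {
    rlang::abort("cannot compute GPR factors of an empty tree",
                 class = "regflux_gpr_error")
  }
  acc <- new.env(parent = emptyenv())
  walk <- function(node, f) {
    if (node$kind == "gene") {
      prev <- if (exists(node$gene, envir = acc)) get(node$gene, envir = acc) else Inf
      assign(node$gene, min(prev, f), envir = acc)
    } else if (node$kind == "or") {
      for (ch in node$children) walk(ch, f)
    } else { # and
      f2 <- f * length(node$children)
      for (ch in node$children) walk(ch, f2)
    }
    invisible(NULL)
  }
  walk(tree, 1)
  out <- unlist(as.list(acc))
  out[order(names(out))]
}

#' @export
print.gpr_tree <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}
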