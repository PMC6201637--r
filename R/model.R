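#' Construct a constraint-based metabolic model
#'
#' The container behind all flux computations: a reaction table with flux
#' bounds and GPR rules, plus the stoichiometry in long (tidy) form. The
#' stoichiometric matrix is materialised on demand by [stoich_matrix()].
#'
#' @param reactions Tibble/data frame with columns `id`, `lower_bound`,
#'   `upper_bound` (mmol/gDW/h) and `gpr` (GPR rule string, `NA` for
#'   reactions with no gene association).
#' @param stoichiometry Tibble with columns `reaction`, `metabolite`,
#'   `coefficient` (signed, negative = consumed).
#' @param biomass_id,target_id Reaction ids of the biomass reaction and the
#'   product (target) exchange; must name reactions in `reactions`.
#' @param metabolites,genes Optional id universes; defaults are derived
#'   from `stoichiometry` and the GPR rules.
#' @return A `metabolic_model` object (S3): list with elements `reactions`
#'   (tibble, with a derived `reversible = lower_bound < 0` column),
#'   `stoichiometry`, `metabolites`, `genes`, `biomass_id`, `target_id`
#'   and pre-parsed `gpr_trees` (named list).
#' @export
metabolic_model <- function(reactions, stoichiometry, biomass_id, target_id,
                            metabolites = NULL, genes = NULL) {
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)
  req <- c("id", "lower_bound", "upper_bound")
  if (!all(req %in% names(reactions))) {
    rlang::abort("`reactions` needs columns id, lower_bound, upper_bound",
                 class = "regflux_config_error")
  }
  if (!"gpr" %in% names(reactions)) reactions$gpr <- NA_character_
  if (anyDuplicated(reactions$id)) {
    rlang::abort("duplicated reaction ids", class = "regflux_config_error")
  }
  bad <- reactions$lower_bound > reactions$upper_bound
  if (any(bad)) {
    rlang::abort(sprintf("lower_bound > upper_bound for reaction(s): %s",
                         paste(reactions$id[bad], collapse = ", ")),
                 class = "regflux_config_error")
  }
  if (!all(stoichiometry$reaction %in% reactions$id)) {
    rlang::abort("stoichiometry references undeclared reactions",
                 class = "regflux_config_error")
  }
  mets <- sort(unique(stoichiometry$metabolite))
  if (is.null(metabolites)) {
    metabolites <- mets
  } else if (!all(mets %in% metabolites)) {
    rlang::abort("stoichiometry references undeclared metabolites",
                 class = "regflux_config_error")
  }
  for (rid in c(biomass_id, target_id)) {
    if (!rid %in% reactions$id) {
      rlang::abort(sprintf("reaction '%s' not present in the model", rid),
                   class = "regflux_config_error")
    }
  }

  trees <- vector("list", nrow(reactions))
  names(trees) <- reactions$id
  for (k in seq_len(nrow(reactions))) {
    trees[k] <- list(tryCatch(
      parse_gpr(reactions$gpr[[k]]),
      regflux_gpr_error = function(e) {
        rlang::abort(sprintf("unparsable GPR for reaction '%s': %s",
                             reactions$id[[k]], conditionMessage(e)),
                     class = "regflux_gpr_error")
      }
    ))
  }
  used_genes <- sort(unique(unlist(lapply(trees, gpr_genes))))
  if (is.null(genes)) {
    genes <- used_genes
  } else if (!all(used_genes %in% genes)) {
    rlang::abort("GPR rules reference undeclared genes",
                 class = "regflux_config_error")
  }
  reactions$reversible <- reactions$lower_bound < 0

  structure(
    list(reactions = reactions, stoichiometry = stoichiometry,
         metabolites = metabolites, genes = genes,
         biomass_id = biomass_id, target_id = target_id,
         gpr_trees = trees),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "<metabolic_model> %d reactions, %d metabolites, %d genes\n  biomass: %s   target: %s\n",
    nrow(x$reactions), length(x$metabolites), length(x$genes),
    x$biomass_id, x$target_id))
  invisible(x)
}

#' Dense stoichiometric matrix (metabolites x reactions)
#'
#' @param model A [metabolic_model()].
#' @return Numeric matrix with metabolite row names and reaction column names.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, length(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites, model$reactions$id))
  st <- model$stoichiometry
  S[cbind(match(st$metabolite, model$metabolites),
          match(st$reaction, model$reactions$id))] <- st$coefficient
  S
}

#' Reactions with a gene association
#'
#' @param model A [metabolic_model()].
#' @return Character vector of reaction ids whose GPR is non-empty.
#' @export
gene_associated_reactions <- function(model) {
  model$reactions$id[!vapply(model$gpr_trees, is.null, logical(1L))]
}

# exchange/demand/sink reactions: stoichiometry touches a single metabolite
exchange_reactions <- function(model) {
  tab <- table(model$stoichiometry$reaction)
  intersect(model$reactions$id, names(tab)[tab == 1L])
}

#' Per-gene GPR factors for every gene-associated reaction
#'
#' @param model A [metabolic_model()].
#' @return Tibble with columns `reaction`, `gene`, `gprf` (see
#'   [gpr_factors()]); reactions without GPR are omitted.
#' @export
gpr_factor_table <- function(model) {
  rids <- gene_associated_reactions(model)
  purrr::map_dfr(rids, function(rid) {
    f <- gpr_factors(model$gpr_trees[[rid]])
    tibble::tibble(reaction = rid, gene = names(f), gprf = unname(f))
  })
}

# zero out the bounds of `ids` (in-silico knockout)
model_knockout <- function(model, ids) {
  hit <- model$reactions$id %in% ids
  model$reactions$lower_bound[hit] <- 0
  model$reactions$upper_bound[hit] <- 0
  model
}

## ---- SBML I/O -------------------------------------------------------------

# attribute lookup tolerant of namespace prefixes (document is ns-stripped,
# but attribute names may keep their prefix)
sbml_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
  v
}

#' Read a constraint-based model from SBML
#'
#' Supports SBML Level 3 with the `fbc` package (flux bounds as global
#' parameters, GPRs as `geneProductAssociation` trees) and falls back to
#' Level 2 conventions (`kineticLaw` LOWER_BOUND/UPPER_BOUND parameters,
#' `GENE_ASSOCIATION:` strings in reaction notes). Boundary-condition
#' species are excluded from the stoichiometry.
#'
#' @param path Path to an SBML document.
#' @param biomass_id,target_id Ids of the biomass reaction and the product
#'   exchange reaction; both must exist in the document.
#' @return A [metabolic_model()].
#' @export
read_sbml_model <- function(path, biomass_id, target_id) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("SBML file not found: %s", path),
                 class = "regflux_io_error")
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  # global flux-bound parameters (L3 fbc)
  pars <- xml2::xml_find_all(doc, "./model/listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  # gene products (L3 fbc): id -> label
  gps <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGeneProducts']/*")
  gp_label <- stats::setNames(
    ifelse(is.na(sbml_attr_all(gps, "label")), sbml_attr_all(gps, "id"),
           sbml_attr_all(gps, "label")),
    sbml_attr_all(gps, "id"))

  sp <- xml2::xml_find_all(doc, "./model/listOfSpecies/species")
  boundary <- xml2::xml_attr(sp, "id")[xml2::xml_attr(sp, "boundaryCondition") %in% "true"]

  rxn_nodes <- xml2::xml_find_all(doc, "./model/listOfReactions/reaction")
  if (length(rxn_nodes) == 0L) {
    rlang::abort("SBML document contains no reactions", class = "regflux_io_error")
  }

  rows <- vector("list", length(rxn_nodes))
  st <- vector("list", length(rxn_nodes))
  for (k in seq_along(rxn_nodes)) {
    nd <- rxn_nodes[[k]]
    rid <- xml2::xml_attr(nd, "id")
    bounds <- sbml_bounds(nd, par_val)
    gpr <- sbml_gpr(nd, gp_label)
    rows[[k]] <- tibble::tibble(id = rid, lower_bound = bounds[[1L]],
                                upper_bound = bounds[[2L]], gpr = gpr)
    st[[k]] <- sbml_stoich(nd, rid, boundary)
  }
  reactions <- dplyr::bind_rows(rows)
  stoichiometry <- dplyr::bind_rows(st)

  for (rid in c(biomass_id, target_id)) {
    if (!rid %in% reactions$id) {
      rlang::abort(sprintf("reaction '%s' not found in %s", rid, path),
                   class = "regflux_config_error")
    }
  }
  metabolic_model(reactions, stoichiometry,
                  biomass_id = biomass_id, target_id = target_id)
}

sbml_attr_all <- function(nodes, name) {
  v <- xml2::xml_attr(nodes, name)
  v2 <- xml2::xml_attr(nodes, paste0("fbc:", name))
  ifelse(is.na(v), v2, v)
}

sbml_bounds <- function(nd, par_val) {
  lo_ref <- sbml_attr(nd, "lowerFluxBound")
  up_ref <- sbml_attr(nd, "upperFluxBound")
  if (!is.na(lo_ref) && !is.na(up_ref)) {
    return(c(par_val[[lo_ref]], par_val[[up_ref]]))
  }
  # L2: kineticLaw parameters
  kl <- xml2::xml_find_all(nd, ".//kineticLaw//parameter")
  if (length(kl) > 0L) {
    ids <- xml2::xml_attr(kl, "id")
    vals <- as.numeric(xml2::xml_attr(kl, "value"))
    lo <- vals[match("LOWER_BOUND", ids)]
    up <- vals[match("UPPER_BOUND", ids)]
    if (!is.na(lo) && !is.na(up)) return(c(lo, up))
  }
  rev <- xml2::xml_attr(nd, "reversible")
  if (identical(rev, "false")) c(0, 1000) else c(-1000, 1000)
}

sbml_stoich <- function(nd, rid, boundary) {
  refs <- function(xp, sign) {
    sr <- xml2::xml_find_all(nd, xp)
    if (length(sr) == 0L) return(NULL)
    coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    coef[is.na(coef)] <- 1
    tibble::tibble(reaction = rid, metabolite = xml2::xml_attr(sr, "species"),
                   coefficient = sign * coef)
  }
  out <- dplyr::bind_rows(refs("./listOfReactants/speciesReference", -1),
                          refs("./listOfProducts/speciesReference", 1))
  if (is.null(out) || nrow(out) == 0L) return(NULL)
  dplyr::filter(out, !.data$metabolite %in% boundary)
}

sbml_gpr <- function(nd, gp_label) {
  assoc <- xml2::xml_find_first(nd, "./*[local-name()='geneProductAssociation']")
  if (!inherits(assoc, "xml_missing")) {
    kids <- xml2::xml_children(assoc)
    if (length(kids) == 0L) return(NA_character_)
    return(fbc_assoc_string(kids[[1L]], gp_label))
  }
  # L2 notes fallback
  notes <- xml2::xml_find_first(nd, "./notes")
  if (!inherits(notes, "xml_missing")) {
    txt <- xml2::xml_text(notes)
    m <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^\n<]*", txt))
    if (length(m) == 1L) {
      rule <- trimws(sub("^GENE_ASSOCIATION:", "", m))
      if (nzchar(rule)) return(rule)
    }
  }
  NA_character_
}

fbc_assoc_string <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- sbml_attr(node, "geneProduct")
    lab <- if (ref %in% names(gp_label)) gp_label[[ref]] else ref
    return(lab)
  }
  op <- tolower(nm) # "and" / "or"
  if (!op %in% c("and", "or")) {
    rlang::abort(sprintf("unsupported geneProductAssociation node '%s'", nm),
                 class = "regflux_io_error")
  }
  inner <- vapply(xml2::xml_children(node), fbc_assoc_string, character(1L),
                  gp_label = gp_label)
  paste0("(", paste(inner, collapse = paste0(" ", op, " ")), ")")
}

#' Write a model as SBML Level 3 + fbc
#'
#' Emits a deterministic document (stable ordering, fixed formatting) so
#' identical models produce byte-identical files. GPRs are written as
#' `fbc:geneProductAssociation` trees in canonical form.
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  rx <- model$reactions
  num <- function(x) formatC(x, format = "g", digits = 15)
  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (m in model$metabolites) {
    L <- c(L, sprintf('      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>', m))
  }
  L <- c(L, '    </listOfSpecies>', '    <listOfParameters>')
  for (k in seq_len(nrow(rx))) {
    L <- c(L,
      sprintf('      <parameter id="lb_%s" value="%s" constant="true"/>', rx$id[[k]], num(rx$lower_bound[[k]])),
      sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>', rx$id[[k]], num(rx$upper_bound[[k]])))
  }
  L <- c(L, '    </listOfParameters>', '    <fbc:listOfGeneProducts>')
  for (g in model$genes) {
    L <- c(L, sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>', g, g))
  }
  L <- c(L, '    </fbc:listOfGeneProducts>', '    <listOfReactions>')
  st <- model$stoichiometry
  for (k in seq_len(nrow(rx))) {
    rid <- rx$id[[k]]
    L <- c(L, sprintf('      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">',
                      rid, tolower(as.character(rx$lower_bound[[k]] < 0)), rid, rid))
    sub <- st[st$reaction == rid, ]
    sub <- sub[order(sub$metabolite), ]
    rea <- sub[sub$coefficient < 0, ]
    pro <- sub[sub$coefficient > 0, ]
    if (nrow(rea) > 0L) {
      L <- c(L, '        <listOfReactants>',
             sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                     rea$metabolite, num(-rea$coefficient)),
             '        </listOfReactants>')
    }
    if (nrow(pro) > 0L) {
      L <- c(L, '        <listOfProducts>',
             sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                     pro$metabolite, num(pro$coefficient)),
             '        </listOfProducts>')
    }
    tree <- model$gpr_trees[[rid]]
    if (!is.null(tree)) {
      L <- c(L, '        <fbc:geneProductAssociation>',
             fbc_assoc_xml(tree, indent = "          "),
             '        </fbc:geneProductAssociation>')
    }
    L <- c(L, '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(L, path)
  invisible(path)
}

fbc_assoc_xml <- function(tree, indent) {
  if (tree$kind == "gene") {
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>', indent, tree$gene))
  }
  tag <- paste0("fbc:", tree$kind)
  c(sprintf("%s<%s>", indent, tag),
    unlist(lapply(tree$children, fbc_assoc_xml, indent = paste0(indent, "  "))),
    sprintf("%s</%s>", indent, tag))
}
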