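TRE_ZERO_TOL <- 1e-9 # |TRE| below this is treated as zero by the filter

#' Build the TR hierarchy from TR-TR interactions
#'
#' Self-regulation and feedback loops are excluded before leveling: the
#' net effect of a negative feedback loop is zero and that of a positive
#' feedback loop diverges, so keeping such edges would give downstream
#' propagation unrealistically large (or infinite) scores. Concretely,
#' self-loops are dropped, every edge internal to a nontrivial strongly
#' connected component is excluded (the component's TRs stay as nodes),
#' and levels are assigned on the remaining DAG by longest path from the
#' roots, so every retained edge points strictly downward.
#'
#' @param interactions Tibble of TR-to-TR edges (columns `regulator`,
#'   `target`, optionally `nrs`).
#' @param trs Optional full TR universe; TRs without retained edges become
#'   level-1 roots.
#' @return A `tr_hierarchy` object: list with `levels` (tibble `tr`,
#'   `level`), `h` (number of levels, 0 for an empty hierarchy), `edges`
#'   (retained edges with `nrs`), `excluded` (edges with `reason`
#'   `"self_loop"` or `"cycle"`).
#' @export
build_hierarchy <- function(interactions, trs = NULL) {
  edges <- tibble::as_tibble(interactions)
  if (!"nrs" %in% names(edges)) edges$nrs <- NA_real_
  edges <- dplyr::select(edges, "regulator", "target", "nrs")
  trs <- sort(unique(c(trs, edges$regulator, edges$target)))

  if (length(trs) == 0L) {
    return(structure(list(levels = tibble::tibble(tr = character(), level = integer()),
                          h = 0L, edges = edges[0, ],
                          excluded = dplyr::mutate(edges[0, ], reason = character())),
                     class = "tr_hierarchy"))
  }

  self <- edges$regulator == edges$target
  excluded <- dplyr::mutate(edges[self, ], reason = "self_loop")
  edges <- edges[!self, ]

  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = trs))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership[trs]
  in_cycle <- comp$csize[memb[edges$regulator]] > 1L &
    memb[edges$regulator] == memb[edges$target]
  excluded <- dplyr::bind_rows(excluded,
                               dplyr::mutate(edges[in_cycle, ], reason = "cycle"))
  edges <- edges[!in_cycle, ]

  # longest-path leveling on the pruned DAG
  dag <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = trs))
  ord <- names(igraph::topo_sort(dag, mode = "out"))
  level <- stats::setNames(rep(1L, length(trs)), trs)
  for (v in ord) {
    parents <- edges$regulator[edges$target == v]
    if (length(parents) > 0L) level[[v]] <- 1L + max(level[parents])
  }

  structure(
    list(levels = tibble::tibble(tr = trs, level = unname(level[trs])),
         h = max(level), edges = edges, excluded = excluded),
    class = "tr_hierarchy")
}

#' @export
print.tr_hierarchy <- function(x, ...) {
  cat(sprintf("<tr_hierarchy> %d TRs in %d level(s); %d retained edge(s), %d excluded\n",
              nrow(x$levels), x$h, nrow(x$edges), nrow(x$excluded)))
  invisible(x)
}

#' TR effect on product flux (TRE)
#'
#' `TRE_i = sum over regulated metabolic genes j and their reactions r of
#' nRS_ij * nGAP_jr` — the regulon-weighted sum of gene-level product-flux
#' scores. TRs regulating no measured metabolic gene score 0.
#'
#' @param gap Tibble from [compute_ngap()].
#' @param interactions Filtered TR-to-gene interactions with `nrs` (from
#'   [filter_sign_consistency()]).
#' @param trs Optional TR universe for the output (default: regulators
#'   present in `interactions`).
#' @return Tibble `(tr, tre)`.
#' @export
compute_tre <- function(gap, interactions, trs = NULL) {
  if (is.null(trs)) trs <- sort(unique(interactions$regulator))
  contrib <- interactions %>%
    dplyr::filter(!is.na(.data$nrs)) %>%
    dplyr::inner_join(gap, by = c(target = "gene"), relationship = "many-to-many") %>%
    dplyr::group_by(.data$regulator) %>%
    dplyr::summarise(tre = sum(.data$nrs * .data$ngap), .groups = "drop")
  tibble::tibble(tr = trs) %>%
    dplyr::left_join(contrib, by = c(tr = "regulator")) %>%
    dplyr::mutate(tre = dplyr::coalesce(.data$tre, 0))
}

#' Randomization significance filter for TRE scores
#'
#' Screens TRE scores against the chance that a random assignment of
#' reaction slopes reproduces them: in each draw every scored reaction
#' receives an nRAP sampled uniformly from the global range of observed
#' nRAP values, nGAP and TRE are recomputed, and `q` is the fraction of
#' draws whose randomized TRE falls within `window * |TRE|` of the actual
#' score. A TR is significant when `q < alpha`. TRs with near-zero TRE are
#' marked not significant outright (`q = 1`), since a relative window
#' around zero has vanishing measure.
#'
#' @param gap Tibble from [compute_ngap()].
#' @param rap Tibble from [compute_nrap()] (defines the observed nRAP
#'   range).
#' @param interactions Filtered TR-to-gene interactions with `nrs`.
#' @param tre Tibble `(tr, tre)` from [compute_tre()].
#' @param n_draws Number of random draws (default 1000).
#' @param window Relative window around the actual TRE (default 0.10).
#' @param alpha Significance threshold on `q` (default 0.05).
#' @param seed RNG seed; draws are consumed in sorted reaction-id order,
#'   so runs are bit-reproducible.
#' @return Tibble `(tr, tre, q, significant)`.
#' @export
significance_filter <- function(gap, rap, interactions, tre,
                                n_draws = 1000L, window = 0.10, alpha = 0.05,
                                seed = 1L) {
  if (!is.numeric(n_draws) || n_draws < 1) {
    rlang::abort("`n_draws` must be >= 1", class = "regflux_config_error")
  }
  rxns <- sort(unique(rap$reaction[!rap$flagged]))
  rng <- range(rap$nrap[!rap$flagged])

  # TRE is linear in the nRAP vector: TRE = A %*% nrap with
  # A[i, r] = sum over regulated genes j carried by r of nRS_ij / GPRf_jr
  coefs <- interactions %>%
    dplyr::filter(!is.na(.data$nrs)) %>%
    dplyr::inner_join(gap, by = c(target = "gene"), relationship = "many-to-many") %>%
    dplyr::group_by(.data$regulator, .data$reaction) %>%
    dplyr::summarise(w = sum(.data$nrs / .data$gprf), .groups = "drop")
  A <- matrix(0, nrow(tre), length(rxns), dimnames = list(tre$tr, rxns))
  keep <- coefs$regulator %in% tre$tr & coefs$reaction %in% rxns
  A[cbind(match(coefs$regulator[keep], tre$tr),
          match(coefs$reaction[keep], rxns))] <- coefs$w[keep]

  set.seed(seed)
  R <- matrix(stats::runif(length(rxns) * n_draws, rng[1L], rng[2L]),
              nrow = length(rxns))
  trand <- A %*% R
  q <- rowMeans(abs(trand - tre$tre) <= window * abs(tre$tre))
  q[abs(tre$tre) < TRE_ZERO_TOL] <- 1
  tibble::tibble(tr = tre$tr, tre = tre$tre, q = unname(q),
                 significant = unname(q) < alpha)
}

#' Global TR effects (gTRE) by bottom-up propagation
#'
#' Processes the hierarchy from the bottom level `h` up to level 1:
#' `gTRE_i = TRE_i + sum over retained TR-TR edges (i -> c) of
#' nRS_ic * gTRE_c`. The sum is empty for TRs that regulate no other TR
#' (their gTRE equals their TRE). TRs failing the significance filter
#' contribute `TRE = 0` but by default still act as conduits, passing
#' their children's scores upward; with `strict = TRUE` they are removed
#' from the hierarchy entirely (dropped as nodes, with their edges).
#'
#' @param hierarchy A [build_hierarchy()] result whose retained edges
#'   carry nRS values.
#' @param tre Tibble `(tr, tre)`.
#' @param significance Optional tibble `(tr, significant)` (from
#'   [significance_filter()]); `NULL` treats every TR as significant.
#' @param strict Remove non-significant TRs as nodes (default `FALSE`).
#' @return Tibble `(tr, level, tre, gtre)`.
#' @export
compute_gtre <- function(hierarchy, tre, significance = NULL, strict = FALSE) {
  stopifnot(inherits(hierarchy, "tr_hierarchy"))
  scores <- hierarchy$levels %>%
    dplyr::left_join(tre, by = "tr") %>%
    dplyr::mutate(tre = dplyr::coalesce(.data$tre, 0))
  if (is.null(significance)) {
    sig <- rep(TRUE, nrow(scores))
  } else {
    sig <- dplyr::coalesce(
      significance$significant[match(scores$tr, significance$tr)], FALSE)
  }
  edges <- hierarchy$edges
  if (strict) {
    keep_tr <- scores$tr[sig]
    edges <- edges[edges$regulator %in% keep_tr & edges$target %in% keep_tr, ]
    scores <- scores[sig, ]
    sig <- rep(TRUE, nrow(scores))
  }

  lv <- stats::setNames(scores$level, scores$tr)
  if (nrow(edges) > 0L && any(lv[edges$target] <= lv[edges$regulator])) {
    rlang::abort("hierarchy contract violated: non-downward edge",
                 class = "regflux_internal_error")
  }

  eff <- ifelse(sig, scores$tre, 0)
  gtre <- stats::setNames(eff, scores$tr)
  for (p in sort(unique(scores$level), decreasing = TRUE)) {
    for (v in scores$tr[scores$level == p]) {
      kid <- edges[edges$regulator == v, ]
      if (nrow(kid) > 0L) {
        gtre[[v]] <- gtre[[v]] + sum(kid$nrs * gtre[kid$target])
      }
    }
  }
  dplyr::mutate(scores, gtre = unname(gtre[scores$tr]))
}

#' Rank TRs as overexpression / downregulation targets
#'
#' Sorts by gTRE descending; positive scores are upregulation
#' (overexpression) candidates, negative scores downregulation candidates.
#' Ties are broken by |TRE| (descending) then lexicographic id.
#'
#' @param scores Tibble with columns `tr`, `tre`, `gtre` (e.g. from
#'   [compute_gtre()], optionally joined with significance columns).
#' @param zero_tol Scores within `zero_tol` of 0 are labelled `"neutral"`.
#' @return `scores` sorted, with added `rank` and `direction` columns.
#' @export
rank_targets <- function(scores, zero_tol = TRE_ZERO_TOL) {
  scores %>%
    dplyr::arrange(dplyr::desc(.data$gtre), dplyr::desc(abs(.data$tre)), .data$tr) %>%
    dplyr::mutate(
      rank = dplyr::row_number(),
      direction = dplyr::case_when(
        .data$gtre > zero_tol ~ "upregulate",
        .data$gtre < -zero_tol ~ "downregulate",
        TRUE ~ "neutral"))
}
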