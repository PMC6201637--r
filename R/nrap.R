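NRAP_ZERO_TOL <- 1e-6 # slopes below this magnitude are snapped to zero

#' Per-reaction product-flux slopes (nRAP)
#'
#' For each reaction `r` with feasible range `[v_min, v_max]` (from
#' [flux_variability()] under the same growth fraction), the reaction flux
#' is fixed at `v_min + k * (v_max - v_min)` for `k = 0, 0.1, ..., 1`, the
#' product (target) flux is maximised at each point subject to steady
#' state, bounds and the growth constraint, and the slope of the 11
#' `(k, v_target)` pairs is estimated by ordinary least squares. Positive
#' slopes mark product-favouring reactions, negative slopes
#' product-competing ones; zero-width ranges score 0. The fractional sweep
#' position `k` is used instead of absolute flux so that reactions carrying
#' small fluxes do not receive inflated slopes.
#'
#' @param model A [metabolic_model()].
#' @param ranges Output of [flux_variability()] computed under
#'   `growth_fraction`.
#' @param growth_fraction Growth constraint fraction; must match `ranges`
#'   (taken from its attribute when omitted).
#' @param k_step Sweep step (default 0.1, i.e. 11 points).
#' @return Tibble (`reaction`, `v_min`, `v_max`, `nrap`, `provenance`,
#'   `flagged`, `sweep`), where `sweep` is a list-column of
#'   `(k, v_target)` tibbles and `provenance` is `"primary"` here (see
#'   [extend_alternate_routes()]). Sweep points that stay infeasible after
#'   an epsilon bound relaxation flag the reaction instead of scoring it.
#' @export
compute_nrap <- function(model, ranges, growth_fraction = NULL, k_step = 0.1) {
  if (is.null(growth_fraction)) {
    growth_fraction <- attr(ranges, "growth_fraction")
    if (is.null(growth_fraction)) growth_fraction <- 0.5
  } else if (!is.null(attr(ranges, "growth_fraction")) &&
             abs(growth_fraction - attr(ranges, "growth_fraction")) > 1e-12) {
    rlang::abort("`ranges` were computed under a different growth_fraction",
                 class = "regflux_config_error")
  }
  gc_ <- growth_constraint(model, growth_fraction)
  ks <- seq(0, 1, by = k_step)

  out <- purrr::map_dfr(seq_len(nrow(ranges)), function(i) {
    rid <- ranges$reaction[[i]]
    lo <- ranges$v_min[[i]]
    hi <- ranges$v_max[[i]]
    if (isTRUE(ranges$flagged[[i]])) {
      return(tibble::tibble(reaction = rid, v_min = lo, v_max = hi,
                            nrap = NA_real_, provenance = "primary",
                            flagged = TRUE, sweep = list(NULL)))
    }
    vt <- vapply(ks, function(k) {
      sweep_point(model, rid, lo + k * (hi - lo), gc_$lb_override)
    }, numeric(1L))
    if (anyNA(vt)) {
      return(tibble::tibble(reaction = rid, v_min = lo, v_max = hi,
                            nrap = NA_real_, provenance = "primary",
                            flagged = TRUE,
                            sweep = list(tibble::tibble(k = ks, v_target = vt))))
    }
    slope <- ols_slope(ks, vt)
    if (abs(slope) < NRAP_ZERO_TOL) slope <- 0
    tibble::tibble(reaction = rid, v_min = lo, v_max = hi, nrap = slope,
                   provenance = "primary", flagged = FALSE,
                   sweep = list(tibble::tibble(k = ks, v_target = vt)))
  })
  attr(out, "growth_fraction") <- growth_fraction
  attr(out, "vbm_max") <- gc_$vbm_max
  out
}

# maximize v_target with reaction rid fixed at `value`; retries with a small
# box relaxation if the pinned LP is numerically infeasible
sweep_point <- function(model, rid, value, lb_growth) {
  fix_lb <- c(lb_growth, stats::setNames(value, rid))
  fix_ub <- stats::setNames(value, rid)
  sol <- fba(model, model$target_id, maximize = TRUE,
             lb_override = fix_lb, ub_override = fix_ub)
  if (sol$status == "optimal") return(sol$value)
  eps <- 1e-6 * max(1, abs(value))
  sol <- fba(model, model$target_id, maximize = TRUE,
             lb_override = c(lb_growth, stats::setNames(value - eps, rid)),
             ub_override = stats::setNames(value + eps, rid))
  if (sol$status == "optimal") sol$value else NA_real_
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc * xc)
}

#' Extend nRAP scores to alternative product routes
#'
#' Reactions on alternative (non-optimal) routes to the product can score 0
#' in the primary sweep because a parallel optimal route compensates for
#' any flux forced through them. This optional extension disables, one per
#' round, a reaction of the product-optimal flux support — preferring the
#' highest-|nRAP| member whose knockout neither abolishes product
#' formation nor breaks the growth demand — and re-sweeps the reactions
#' still scored 0 with that single knockout in place. Newly nonzero slopes
#' are recorded with provenance `"alternate"`; primary scores are never
#' overwritten. Across rounds the candidate pool is taken from the product
#' optimum of the model with all previously tried knockouts applied, so
#' successive rounds walk through successive parallel routes, while each
#' re-sweep applies only its own knockout (so a route disabled in an
#' earlier round can itself be scored later). The procedure is a heuristic
#' stand-in for exhaustive alternative-pathway enumeration and its results
#' are flagged as such.
#'
#' @param model A [metabolic_model()].
#' @param rap Output of [compute_nrap()].
#' @param growth_fraction Growth constraint fraction (default: from `rap`).
#' @param max_rounds Maximum knockout rounds (>= 1).
#' @return `rap` with alternate-route rows rescored.
#' @export
extend_alternate_routes <- function(model, rap, growth_fraction = NULL,
                                    max_rounds = 1L) {
  if (!is.numeric(max_rounds) || max_rounds < 1) {
    rlang::abort("`max_rounds` must be >= 1", class = "regflux_config_error")
  }
  if (is.null(growth_fraction)) {
    growth_fraction <- attr(rap, "growth_fraction")
    if (is.null(growth_fraction)) growth_fraction <- 0.5
  }
  vbm_req <- growth_fraction * growth_constraint(model, growth_fraction)$vbm_max
  tried <- character(0L)
  for (round in seq_len(max_rounds)) {
    zero_ids <- rap$reaction[!rap$flagged & rap$nrap == 0 &
                               rap$provenance == "primary"]
    if (length(zero_ids) == 0L) break
    pick <- alternate_knockout_candidate(model, rap, tried, growth_fraction,
                                         vbm_req)
    if (is.null(pick)) break
    tried <- c(tried, pick)
    mod_k <- model_knockout(model, pick)

    resweep <- setdiff(zero_ids, pick)
    if (length(resweep) == 0L) next
    ranges2 <- tryCatch(
      flux_variability(mod_k, reactions = resweep,
                       growth_fraction = growth_fraction),
      regflux_solver_error = function(e) NULL
    )
    if (is.null(ranges2)) next
    rap2 <- compute_nrap(mod_k, ranges2, growth_fraction = growth_fraction)
    gained <- rap2$reaction[!rap2$flagged & rap2$nrap != 0]
    if (length(gained) == 0L) next
    idx <- match(gained, rap$reaction)
    rap$nrap[idx] <- rap2$nrap[match(gained, rap2$reaction)]
    rap$provenance[idx] <- "alternate"
    rap$sweep[idx] <- rap2$sweep[match(gained, rap2$reaction)]
  }
  rap
}

# Pick the next knockout: from the product-optimal support of the model
# with all `tried` knockouts applied, prefer high |nRAP| (ties broken by
# id), and require that the single knockout alone keeps the product
# reachable and the original growth demand satisfiable.
alternate_knockout_candidate <- function(model, rap, tried, growth_fraction,
                                         vbm_req) {
  pool_model <- model_knockout(model, tried)
  gc_ <- tryCatch(growth_constraint(pool_model, growth_fraction),
                  regflux_solver_error = function(e) NULL)
  if (is.null(gc_)) return(NULL)
  sol <- fba(pool_model, model$target_id, maximize = TRUE,
             lb_override = gc_$lb_override)
  if (sol$status != "optimal" || sol$value < 1e-6) return(NULL)
  support <- names(sol$fluxes)[abs(sol$fluxes) > 1e-6]
  support <- setdiff(support, c(tried, model$target_id, model$biomass_id))
  if (length(support) == 0L) return(NULL)
  score <- abs(rap$nrap[match(support, rap$reaction)])
  score[is.na(score)] <- 0
  support <- support[order(-score, support)]
  for (cand in support) {
    m2 <- model_knockout(model, cand)
    bm <- fba(m2, m2$biomass_id, maximize = TRUE)
    if (bm$status != "optimal" || bm$value < vbm_req - 1e-6) next
    s2 <- fba(m2, m2$target_id, maximize = TRUE,
              lb_override = stats::setNames(vbm_req, m2$biomass_id))
    if (s2$status == "optimal" && s2$value > 1e-6) return(cand)
  }
  NULL
}

#' Per-gene product-flux scores (nGAP)
#'
#' Distributes each reaction's nRAP over its genes:
#' `nGAP = nRAP / GPRf`, one row per (gene, reaction) pair. Reactions
#' without a GPR, and reactions flagged during the sweep, are omitted.
#'
#' @param rap Output of [compute_nrap()] (possibly extended).
#' @param factors Tibble `(reaction, gene, gprf)` from
#'   [gpr_factor_table()].
#' @return Tibble with columns `gene`, `reaction`, `gprf`, `nrap`, `ngap`.
#' @export
compute_ngap <- function(rap, factors) {
  if (any(factors$gprf <= 0)) {
    rlang::abort("GPR factors must be positive", class = "regflux_internal_error")
  }
  rap %>%
    dplyr::filter(!.data$flagged) %>%
    dplyr::select("reaction", "nrap") %>%
    dplyr::inner_join(factors, by = "reaction") %>%
    dplyr::mutate(ngap = .data$nrap / .data$gprf) %>%
    dplyr::select("gene", "reaction", "gprf", "nrap", "ngap")
}
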