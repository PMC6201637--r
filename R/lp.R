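# Linear-programming backend.
#
# All flux LPs in the package funnel through lp_solve(): maximize/minimize
# obj'v subject to S v = 0 and lb <= v <= ub. boot::simplex() works on
# non-negative variables with non-negative right-hand sides, so variables
# are shifted by their lower bounds and equality rows are sign-normalised
# before the call.

LP_BIG <- 1e6      # stand-in for infinite bounds
LP_EPS <- 1e-9     # simplex feasibility/optimality tolerance

lp_solve <- function(obj, S, lb, ub, maximize = TRUE) {
  n <- length(obj)
  infeasible <- list(status = "infeasible", value = NA_real_,
                     fluxes = rep(NA_real_, n))
  lb2 <- pmax(unname(lb), -LP_BIG)
  ub2 <- pmin(unname(ub), LP_BIG)
  if (any(lb2 > ub2 + 1e-12)) return(infeasible)
  ub2 <- pmax(ub2, lb2)

  # shift x = v - lb >= 0; fold fixed variables (zero-width boxes) into the
  # right-hand side — degenerate columns trip the simplex pivoting
  d <- ub2 - lb2
  free <- d > 1e-12
  b3 <- as.numeric(-S %*% lb2)
  Sf <- S[, free, drop = FALSE]

  # equality rows with no free variable must already be satisfied
  vacuous <- rowSums(abs(Sf)) == 0
  if (any(abs(b3[vacuous]) > 1e-7)) return(infeasible)
  A3 <- Sf[!vacuous, , drop = FALSE]
  b3 <- b3[!vacuous]

  if (!any(free)) {
    v <- lb2
    return(list(status = "optimal", value = sum(obj * v), fluxes = v))
  }

  # drop linearly dependent equality rows (simplex mishandles them);
  # consistency of the full system is re-checked on the solution below
  if (nrow(A3) > 1L) {
    qa <- qr(t(A3))
    keep <- sort(qa$pivot[seq_len(qa$rank)])
    A3 <- A3[keep, , drop = FALSE]
    b3 <- b3[keep]
  }

  b3[abs(b3) < 1e-12] <- 0
  neg <- b3 < 0
  if (any(neg)) {
    A3[neg, ] <- -A3[neg, , drop = FALSE]
    b3[neg] <- -b3[neg]
  }

  nf <- sum(free)
  args <- list(a = obj[free], A1 = diag(nf), b1 = d[free],
               maxi = maximize, n.iter = 200L + 20L * (nf + nrow(A3)),
               eps = LP_EPS)
  if (nrow(A3) > 0L) {
    args$A3 <- A3
    args$b3 <- b3
  }
  res <- tryCatch(do.call(boot::simplex, args), error = function(e) NULL)
  if (is.null(res) || res$solved != 1L) {
    if (!is.null(res) && res$solved == -1L) return(infeasible)
    return(list(status = "failed", value = NA_real_, fluxes = rep(NA_real_, n)))
  }
  v <- lb2
  v[free] <- as.numeric(res$soln) + lb2[free]
  if (max(abs(S %*% v)) > 1e-6) return(infeasible)
  list(status = "optimal", value = sum(obj * v), fluxes = v)
}

#' Flux balance analysis
#'
#' Optimizes the flux of one reaction subject to steady state and the
#' model's flux bounds, optionally with per-reaction bound overrides (used
#' internally for growth constraints, flux fixing and knockouts).
#'
#' @param model A [metabolic_model()].
#' @param objective_id Reaction id to optimize; defaults to the biomass
#'   reaction.
#' @param maximize Maximize (default) or minimize.
#' @param lb_override,ub_override Named numeric vectors of bound overrides.
#' @return List with `status` (`"optimal"`, `"infeasible"` or `"failed"`),
#'   `value` (optimal flux of `objective_id`) and `fluxes` (named vector,
#'   one feasible optimum).
#' @export
fba <- function(model, objective_id = model$biomass_id, maximize = TRUE,
                lb_override = NULL, ub_override = NULL) {
  rx <- model$reactions
  lb <- rx$lower_bound
  ub <- rx$upper_bound
  names(lb) <- names(ub) <- rx$id
  if (length(lb_override)) lb[names(lb_override)] <- lb_override
  if (length(ub_override)) ub[names(ub_override)] <- ub_override
  obj <- as.numeric(rx$id == objective_id)
  if (!any(obj == 1)) {
    rlang::abort(sprintf("objective reaction '%s' not in model", objective_id),
                 class = "regflux_config_error")
  }
  out <- lp_solve(obj, stoich_matrix(model), lb, ub, maximize = maximize)
  names(out$fluxes) <- rx$id
  out
}

# lower-bound override enforcing v_biomass >= fraction * v_biomass_max;
# returns list(lb_override, vbm_max)
growth_constraint <- function(model, growth_fraction) {
  stopifnot(growth_fraction >= 0, growth_fraction <= 1)
  sol <- fba(model, model$biomass_id, maximize = TRUE)
  if (sol$status != "optimal") {
    rlang::abort("model infeasible: biomass FBA did not solve",
                 class = "regflux_solver_error")
  }
  vbm_max <- sol$value
  cur_lb <- model$reactions$lower_bound[model$reactions$id == model$biomass_id]
  lb_override <- stats::setNames(max(cur_lb, growth_fraction * vbm_max),
                                 model$biomass_id)
  list(lb_override = lb_override, vbm_max = vbm_max)
}
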