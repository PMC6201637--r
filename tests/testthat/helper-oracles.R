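# Independent oracles, deliberately implemented on a different solver
# backend (pracma::linprog) and with different estimators (stats::lm for
# slopes, explicit path enumeration for gTRE, a per-draw loop for the
# randomization filter) than the package internals.

# LP oracle: optimize obj'v s.t. S v = 0, lb <= v <= ub
oracle_lp <- function(obj, S, lb, ub, maximize = TRUE) {
  n <- length(obj)
  beq <- as.numeric(-S %*% lb)
  Aeq <- S
  flip <- beq < 0
  Aeq[flip, ] <- -Aeq[flip, , drop = FALSE]
  beq[flip] <- -beq[flip]
  p <- tryCatch(
    pracma::linprog(cc = obj, A = diag(n), b = ub - lb, Aeq = Aeq, beq = beq,
                    maximize = maximize, maxiter = 2000),
    error = function(e) NULL)
  if (is.null(p) || p$errno != 1) return(NULL)
  v <- p$x + lb
  list(value = sum(obj * v), fluxes = v)
}

# model pieces as plain vectors/matrix for the oracle
oracle_pieces <- function(model) {
  list(S = stoich_matrix(model),
       lb = stats::setNames(model$reactions$lower_bound, model$reactions$id),
       ub = stats::setNames(model$reactions$upper_bound, model$reactions$id),
       ids = model$reactions$id)
}

oracle_opt <- function(pieces, rid, maximize = TRUE, lb = pieces$lb,
                       ub = pieces$ub) {
  obj <- as.numeric(pieces$ids == rid)
  oracle_lp(obj, pieces$S, lb, ub, maximize = maximize)
}

# full nRAP oracle: FVA + 11-point sweep + lm() slope, growth constraint
# at `fraction` of maximal biomass
oracle_nrap <- function(model, reactions, fraction = 0.5) {
  pc <- oracle_pieces(model)
  vbm <- oracle_opt(pc, model$biomass_id, TRUE)$value
  lb <- pc$lb
  lb[model$biomass_id] <- max(lb[model$biomass_id], fraction * vbm)
  vapply(reactions, function(rid) {
    lo <- oracle_opt(pc, rid, FALSE, lb = lb)$value
    hi <- oracle_opt(pc, rid, TRUE, lb = lb)$value
    ks <- seq(0, 1, 0.1)
    vt <- vapply(ks, function(k) {
      lb2 <- lb; ub2 <- pc$ub
      lb2[rid] <- ub2[rid] <- lo + k * (hi - lo)
      oracle_opt(pc, model$target_id, TRUE, lb = lb2, ub = ub2)$value
    }, numeric(1L))
    unname(stats::coef(stats::lm(vt ~ ks))[2L])
  }, numeric(1L))
}

# gTRE oracle: TRE(i) plus the sum over every directed path i -> ... -> c
# of the product of edge nRS times TRE(c), by explicit path enumeration
oracle_gtre <- function(edges, tre) {
  vapply(names(tre), function(v) {
    total <- tre[[v]]
    rec <- function(u, prodv) {
      out <- edges[edges$regulator == u, , drop = FALSE]
      for (k in seq_len(nrow(out))) {
        w <- out$target[[k]]
        pw <- prodv * out$nrs[[k]]
        total <<- total + pw * tre[[w]]
        rec(w, pw)
      }
    }
    rec(v, 1)
    total
  }, numeric(1L))
}

# second implementation of the randomization filter: per-draw loop,
# explicit per-row recomputation of nGAP and TRE
oracle_significance_q <- function(gap, rap, interactions, tre,
                                  n_draws, window, seed) {
  rxns <- sort(unique(rap$reaction[!rap$flagged]))
  rng <- range(rap$nrap[!rap$flagged])
  inter <- interactions[!is.na(interactions$nrs), ]
  set.seed(seed)
  hits <- stats::setNames(numeric(nrow(tre)), tre$tr)
  for (d in seq_len(n_draws)) {
    r <- stats::runif(length(rxns), rng[1L], rng[2L])
    names(r) <- rxns
    g2 <- gap
    g2$ngap <- r[g2$reaction] / g2$gprf
    for (i in seq_len(nrow(tre))) {
      rows <- inter[inter$regulator == tre$tr[[i]], ]
      tr_rand <- 0
      for (k in seq_len(nrow(rows))) {
        sub <- g2[g2$gene == rows$target[[k]], ]
        tr_rand <- tr_rand + sum(rows$nrs[[k]] * sub$ngap)
      }
      if (abs(tr_rand - tre$tre[[i]]) <= window * abs(tre$tre[[i]])) {
        hits[[i]] <- hits[[i]] + 1
      }
    }
  }
  hits / n_draws
}

# random DAG hierarchy over n TRs with edge probability p (upper-triangular
# so acyclicity is guaranteed by construction)
random_dag_edges <- function(n, p = 0.35) {
  trs <- sprintf("t%02d", seq_len(n))
  out <- expand.grid(regulator = trs, target = trs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[match(out$regulator, trs) < match(out$target, trs), ]
  out <- out[stats::runif(nrow(out)) < p, ]
  out$nrs <- round(stats::runif(nrow(out), -2, 2), 2)
  tibble::as_tibble(out)
}
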