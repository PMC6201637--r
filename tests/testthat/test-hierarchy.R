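edge_tbl <- function(...) {
  x <- tibble::tribble(...)
  if (!"nrs" %in% names(x)) x$nrs <- 1
  x
}

test_that("hierarchy leveling follows longest paths", {
  # single TR, no edges
  h0 <- build_hierarchy(tibble::tibble(regulator = character(),
                                       target = character()), trs = "t1")
  expect_equal(h0$levels$level, 1L)
  expect_equal(h0$h, 1L)

  # chain
  h1 <- build_hierarchy(edge_tbl(~regulator, ~target,
                                 "t1", "t2", "t2", "t3"))
  expect_equal(h1$levels$level[match(c("t1", "t2", "t3"), h1$levels$tr)],
               c(1L, 2L, 3L))
  expect_equal(h1$h, 3L)

  # longest path dominates when a shortcut exists
  h2 <- build_hierarchy(edge_tbl(~regulator, ~target,
                                 "a", "b", "b", "c", "a", "c"))
  expect_equal(h2$levels$level[h2$levels$tr == "c"], 3L)

  # empty hierarchy is valid
  he <- build_hierarchy(tibble::tibble(regulator = character(),
                                       target = character()))
  expect_equal(he$h, 0L)
  expect_equal(nrow(he$levels), 0L)
})

test_that("cycles and self-loops are excluded edge-wise, keeping the TRs", {
  h <- build_hierarchy(edge_tbl(~regulator, ~target,
                                "t1", "t2", "t2", "t1", "t1", "t3"))
  expect_setequal(h$excluded$reason, "cycle")
  expect_equal(nrow(h$excluded), 2L)
  lv <- stats::setNames(h$levels$level, h$levels$tr)
  # both cycle members stay as nodes at level 1; t3 hangs below t1
  expect_equal(unname(lv[c("t1", "t2", "t3")]), c(1L, 1L, 2L))
  expect_equal(h$h, 2L)

  hs <- build_hierarchy(edge_tbl(~regulator, ~target, "t1", "t1"))
  expect_equal(hs$excluded$reason, "self_loop")
  expect_equal(hs$levels$level, 1L)

  # a larger strongly connected component loses all internal edges
  h3 <- build_hierarchy(edge_tbl(~regulator, ~target,
                                 "a", "b", "b", "c", "c", "a", "c", "d"))
  expect_equal(sum(h3$excluded$reason == "cycle"), 3L)
  expect_equal(nrow(h3$edges), 1L)
})

test_that("TRE sums nRS-weighted gene scores over the regulon", {
  gap <- tibble::tibble(gene = c("g1", "g2", "g2"),
                        reaction = c("r1", "r1", "r2"),
                        gprf = c(2, 1, 1), nrap = c(1, 1, -2),
                        ngap = c(0.5, 1, -2))
  inter <- tibble::tibble(regulator = c("tA", "tA", "tB"),
                          target = c("g1", "g2", "g9"),
                          effect = 1, nrs = c(2, 1, 5))
  tre <- compute_tre(gap, inter)
  # tA: 2*0.5 + 1*(1 - 2); tB regulates nothing measured
  expect_equal(tre$tre[tre$tr == "tA"], 0)
  expect_equal(tre$tre[tre$tr == "tB"], 0)

  inter2 <- tibble::tibble(regulator = "tC", target = "g1", effect = 1,
                           nrs = 2)
  gap2 <- gap[1, ]
  expect_equal(compute_tre(gap2, inter2)$tre, 1)
})

test_that("gTRE propagates bottom-up through the hierarchy", {
  # leaf: gTRE = TRE; one edge: parent inherits child's score
  h <- build_hierarchy(edge_tbl(~regulator, ~target, ~nrs, "t1", "t2", 1))
  tre <- tibble::tibble(tr = c("t1", "t2"), tre = c(0, 5))
  g <- compute_gtre(h, tre)
  expect_equal(g$gtre[g$tr == "t2"], 5)
  expect_equal(g$gtre[g$tr == "t1"], 5)

  # three-level worked example
  h2 <- build_hierarchy(edge_tbl(~regulator, ~target, ~nrs,
                                 "t1", "t2", 0.5,
                                 "t1", "t3", -1,
                                 "t2", "t4", 2))
  tre2 <- tibble::tibble(tr = c("t1", "t2", "t3", "t4"), tre = 1:4)
  g2 <- compute_gtre(h2, tre2)
  want <- c(t4 = 4, t2 = 2 + 2 * 4, t3 = 3, t1 = 1 + 0.5 * 10 + (-1) * 3)
  expect_equal(stats::setNames(g2$gtre, g2$tr)[names(want)], want)
})

test_that("gTRE equals the path-enumeration oracle on random DAGs", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(4:12, 1L)
    edges <- random_dag_edges(n)
    trs <- sprintf("t%02d", seq_len(n))
    tre_v <- stats::setNames(round(stats::runif(n, -5, 5), 2), trs)
    h <- build_hierarchy(edges, trs = trs)
    g <- compute_gtre(h, tibble::tibble(tr = trs, tre = unname(tre_v)))
    oracle <- oracle_gtre(h$edges, tre_v)
    expect_equal(stats::setNames(g$gtre, g$tr)[trs], oracle[trs],
                 tolerance = 1e-10)
    expect_true(all(is.finite(g$gtre)))
  }
})

test_that("zero-strength TR-TR edges conserve TRE", {
  set.seed(7)
  edges <- random_dag_edges(8)
  edges$nrs <- 0
  trs <- sprintf("t%02d", 1:8)
  tre <- tibble::tibble(tr = trs, tre = stats::runif(8, -3, 3))
  g <- compute_gtre(build_hierarchy(edges, trs = trs), tre)
  expect_equal(g$gtre, tre$tre[match(g$tr, tre$tr)])
})

test_that("cycle pruning keeps every score finite even for amplifying loops", {
  # a positive 2-cycle would blow up an iterative evaluation; exclusion
  # keeps the computation finite
  edges <- edge_tbl(~regulator, ~target, ~nrs,
                    "a", "b", 2, "b", "a", 2, "a", "c", 1)
  h <- build_hierarchy(edges)
  tre <- tibble::tibble(tr = c("a", "b", "c"), tre = c(1, 1, 1))
  g <- compute_gtre(h, tre)
  expect_true(all(is.finite(g$gtre)))
  expect_equal(g$gtre[g$tr == "a"], 2) # own TRE + 1 * TRE(c)
})

test_that("non-significant TRs stop contributing but still conduct", {
  h <- build_hierarchy(edge_tbl(~regulator, ~target, ~nrs,
                                "t1", "t2", 1, "t2", "t3", 1))
  tre <- tibble::tibble(tr = c("t1", "t2", "t3"), tre = c(1, 10, 2))
  sig <- tibble::tibble(tr = c("t1", "t2", "t3"),
                        significant = c(TRUE, FALSE, TRUE))
  g <- compute_gtre(h, tre, sig)
  # t2's own effect is zeroed but t3's score flows through it
  expect_equal(g$gtre[g$tr == "t2"], 2)
  expect_equal(g$gtre[g$tr == "t1"], 1 + 2)

  strict <- compute_gtre(h, tre, sig, strict = TRUE)
  expect_false("t2" %in% strict$tr)
  # with the conduit removed, t1 no longer sees t3
  expect_equal(strict$gtre[strict$tr == "t1"], 1)
})

test_that("the randomization filter is reproducible and sane", {
  m <- toy_model()
  rap <- compute_nrap(m, flux_variability(m))
  gap <- compute_ngap(rap, gpr_factor_table(m))
  inst <- toy_instance(1)
  trn <- inst$trn[inst$trn$regulator != inst$trn$target, ]
  trn$effect <- ifelse(trn$effect == "+", 1, -1)
  nrs <- compute_nrs(trn, inst$expression)
  gene_edges <- nrs[!nrs$target %in% unique(nrs$regulator), ]
  tre <- compute_tre(gap, gene_edges)

  s1 <- significance_filter(gap, rap, gene_edges, tre, n_draws = 400,
                            seed = 42)
  s2 <- significance_filter(gap, rap, gene_edges, tre, n_draws = 400,
                            seed = 42)
  expect_identical(s1, s2)

  # exact agreement with an independently coded sampler
  q_oracle <- oracle_significance_q(gap, rap, gene_edges, tre,
                                    n_draws = 200, window = 0.10, seed = 9)
  s3 <- significance_filter(gap, rap, gene_edges, tre, n_draws = 200,
                            seed = 9)
  nonzero <- abs(s3$tre) > 1e-9
  expect_equal(s3$q[nonzero], unname(q_oracle[s3$tr])[nonzero])

  # q estimates are stable in n_draws within binomial error
  s_small <- significance_filter(gap, rap, gene_edges, tre,
                                 n_draws = 1000, seed = 1)
  s_big <- significance_filter(gap, rap, gene_edges, tre,
                               n_draws = 10000, seed = 2)
  for (i in which(nonzero)) {
    se <- sqrt(s_big$q[i] * (1 - s_big$q[i]) / 1000) + 1e-3
    expect_lt(abs(s_small$q[i] - s_big$q[i]), 3 * se + 0.02)
  }

  # zero TRE is never significant
  expect_true(all(s1$q[abs(s1$tre) < 1e-9] == 1))
  expect_false(any(s1$significant[abs(s1$tre) < 1e-9]))

  # degenerate zero-width nRAP range: every draw reproduces the actual TRE
  rap_const <- rap
  rap_const$nrap <- 3
  gap_const <- compute_ngap(rap_const, gpr_factor_table(m))
  tre_const <- compute_tre(gap_const, gene_edges)
  s_const <- significance_filter(gap_const, rap_const, gene_edges, tre_const,
                                 n_draws = 100, seed = 5)
  expect_true(all(s_const$q == 1))
  expect_false(any(s_const$significant))

  expect_error(significance_filter(gap, rap, gene_edges, tre, n_draws = 0),
               class = "regflux_config_error")
})

test_that("rank_targets orders by gTRE with |TRE| then id tie-breaks", {
  sc <- tibble::tibble(tr = c("a", "b", "c"), level = 1L,
                       tre = c(1, -1, 0), gtre = c(3, -2, 0))
  rk <- rank_targets(sc)
  expect_identical(rk$tr, c("a", "c", "b"))
  expect_identical(rk$direction, c("upregulate", "neutral", "downregulate"))
  expect_identical(rk$rank, 1:3)

  tied <- tibble::tibble(tr = c("b", "a", "c"), level = 1L,
                         tre = c(0, 0, 0), gtre = c(1, 1, 1))
  expect_identical(rank_targets(tied)$tr, c("a", "b", "c"))

  tied2 <- tibble::tibble(tr = c("a", "b"), level = 1L,
                          tre = c(1, 5), gtre = c(2, 2))
  expect_identical(rank_targets(tied2)$tr, c("b", "a"))
})
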