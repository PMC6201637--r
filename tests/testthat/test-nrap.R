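test_that("sweeping the target reaction itself gives slope v_max - v_min", {
  m <- toy_model()
  r <- flux_variability(m, reactions = "EX_P", growth_fraction = 0.5)
  rap <- compute_nrap(m, r)
  expect_equal(rap$nrap, r$v_max - r$v_min, tolerance = 1e-8)
})

test_that("a zero-width range scores exactly zero", {
  m <- toy_model()
  m$reactions$lower_bound[m$reactions$id == "R_drain"] <- 2
  m$reactions$upper_bound[m$reactions$id == "R_drain"] <- 2
  r <- flux_variability(m, reactions = "R_drain")
  rap <- compute_nrap(m, r)
  expect_identical(rap$nrap, 0)
  expect_equal(nrow(rap$sweep[[1L]]), 11L)
})

test_that("toy nRAP values match the independent brute-force oracle", {
  skip_if_not_installed("pracma")
  m <- toy_model()
  rxns <- gene_associated_reactions(m)
  rap <- compute_nrap(m, flux_variability(m))
  expect_equal(nrow(rap), length(rxns))
  expect_true(all(vapply(rap$sweep, nrow, integer(1L)) == 11L))
  oracle <- oracle_nrap(m, rxns)
  for (rid in rxns) {
    got <- rap$nrap[rap$reaction == rid]
    want <- oracle[[rid]]
    expect_equal(got, want, tolerance = 1e-6, info = rid)
  }
  # drain and biomass-precursor steps compete with the product
  expect_lt(rap$nrap[rap$reaction == "R_drain"], 0)
  expect_lt(rap$nrap[rap$reaction == "R_b1"], 0)
  # committed product-path steps favour it
  expect_gt(rap$nrap[rap$reaction == "R_p1"], 0)
  expect_gt(rap$nrap[rap$reaction == "R_p2"], 0)
})

test_that("nRAP signs predict the effect of forcing the reaction", {
  m <- toy_model()
  gc_lb <- c(R_bio = 5)
  base <- fba(m, "EX_P", lb_override = gc_lb)$value
  rap <- compute_nrap(m, flux_variability(m))
  for (i in seq_len(nrow(rap))) {
    rid <- rap$reaction[[i]]
    if (rap$nrap[[i]] > 0) {
      # knocking a product-favouring reaction to zero cannot help
      v <- fba(m, "EX_P", lb_override = gc_lb,
               ub_override = stats::setNames(0, rid))
      val <- if (v$status == "optimal") v$value else 0
      expect_lte(val, base + 1e-7, label = rid)
    } else if (rap$nrap[[i]] < 0) {
      # forcing a competing reaction to its maximum cannot help
      v <- fba(m, "EX_P",
               lb_override = c(gc_lb, stats::setNames(rap$v_max[[i]], rid)))
      val <- if (v$status == "optimal") v$value else 0
      expect_lte(val, base + 1e-7, label = rid)
    }
  }
})

test_that("scaling all bounds by c scales every nRAP by c", {
  m <- toy_model()
  rap1 <- compute_nrap(m, flux_variability(m))
  cc <- 2.5
  m2 <- scale_model_bounds(m, cc)
  rap2 <- compute_nrap(m2, flux_variability(m2))
  expect_equal(rap2$nrap, cc * rap1$nrap, tolerance = 1e-6)
})

test_that("alternate-route extension scores parallel branches", {
  mb <- branched_toy_model()
  rap <- compute_nrap(mb, flux_variability(mb))
  # parallel routes hide each other in the primary sweep
  zeroed <- rap$reaction[rap$nrap == 0]
  expect_true(all(c("R_alt1", "R_alt2") %in% zeroed))

  ext <- extend_alternate_routes(mb, rap, max_rounds = 4)
  alt <- ext[ext$reaction %in% c("R_alt1", "R_alt2"), ]
  expect_true(all(alt$nrap > 0))
  expect_true(all(alt$provenance == "alternate"))
  # primary scores are never overwritten
  prim <- ext[ext$provenance == "primary" & ext$reaction %in%
                rap$reaction[rap$nrap != 0], ]
  expect_equal(prim$nrap,
               rap$nrap[match(prim$reaction, rap$reaction)])

  skip_if_not_installed("pracma")
  # oracle: with the compensating primary step disabled, the branch slope
  # is the brute-force sweep of the knocked-out model
  m_k <- mb
  m_k$reactions$upper_bound[m_k$reactions$id == "R_p2"] <- 0
  oracle <- oracle_nrap(m_k, c("R_alt1", "R_alt2"))
  expect_equal(alt$nrap[alt$reaction == "R_alt1"], oracle[["R_alt1"]],
               tolerance = 1e-6)
  expect_equal(alt$nrap[alt$reaction == "R_alt2"], oracle[["R_alt2"]],
               tolerance = 1e-6)
})

test_that("the unbranched toy is a fixpoint of the extension", {
  m <- toy_model()
  rap <- compute_nrap(m, flux_variability(m))
  ext <- extend_alternate_routes(m, rap, max_rounds = 1)
  expect_equal(dplyr::select(ext, -sweep), dplyr::select(rap, -sweep))
  expect_error(extend_alternate_routes(m, rap, max_rounds = 0),
               class = "regflux_config_error")
})

test_that("nGAP divides slopes by the GPR factors", {
  m <- toy_model()
  rap <- compute_nrap(m, flux_variability(m))
  gap <- compute_ngap(rap, gpr_factor_table(m))
  expect_equal(gap$ngap, gap$nrap / gap$gprf)
  expect_true(all(abs(gap$ngap) <= abs(gap$nrap) + 1e-12))
  # the isozyme branch gB3 carries the full slope, the complex halves it
  r2 <- rap$nrap[rap$reaction == "R_p2"]
  expect_equal(gap$ngap[gap$gene == "gB3"], r2)
  expect_equal(gap$ngap[gap$gene == "gB1"], r2 / 2)
  # reactions without GPR never appear
  expect_false(any(c("R_upt", "R_bio", "EX_P") %in% gap$reaction))

  # direct arithmetic on a hand-built table
  rap2 <- tibble::tibble(reaction = c("r1", "r2"), v_min = 0, v_max = 1,
                         nrap = c(4, 0), provenance = "primary",
                         flagged = FALSE, sweep = list(NULL, NULL))
  fac <- tibble::tibble(reaction = c("r1", "r2"), gene = c("C", "C"),
                        gprf = c(4, 2))
  gap2 <- compute_ngap(rap2, fac)
  expect_equal(gap2$ngap, c(1, 0))
  fac$gprf[1] <- -1
  expect_error(compute_ngap(rap2, fac), "positive")
})

test_that("a gene in two reactions keeps one row per reaction", {
  rap <- tibble::tibble(reaction = c("r1", "r2"), v_min = 0, v_max = 1,
                        nrap = c(2, -3), provenance = "primary",
                        flagged = FALSE, sweep = list(NULL, NULL))
  fac <- tibble::tibble(reaction = c("r1", "r2"), gene = "g",
                        gprf = c(1, 2))
  gap <- compute_ngap(rap, fac)
  expect_equal(nrow(gap), 2L)
  expect_equal(sort(gap$ngap), c(-1.5, 2))
})
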