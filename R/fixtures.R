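#' A nine-reaction toy production model
#'
#' Minimal but complete test bed for the whole pipeline: a carbon uptake
#' (`R_upt`), a three-step product pathway `A -> B -> C -> P`
#' (`R_p1`, `R_p2`, `R_p3`), a two-step biomass-precursor pathway
#' `A -> M1 -> M2` (`R_b1`, `R_b2`), a drain diverting the pathway
#' intermediate B away from the product (`R_drain`), the biomass reaction
#' (`R_bio`, consuming M2) and the product exchange (`EX_P`). All six
#' internal conversions carry GPRs, including one isozyme/complex rule on
#' `R_p2`, so nGAP distribution is exercised.
#'
#' Under the default 50% growth constraint the product-path reactions have
#' positive nRAP, while the drain and both biomass-precursor steps compete
#' with the product and have negative nRAP.
#'
#' @param uptake Maximum carbon uptake flux (default 10 mmol/gDW/h).
#' @return A [metabolic_model()].
#' @export
toy_model <- function(uptake = 10) {
  reactions <- tibble::tribble(
    ~id,       ~lower_bound, ~upper_bound, ~gpr,
    "R_upt",   0,            uptake,       NA_character_,
    "R_p1",    0,            1000,         "gA1",
    "R_p2",    0,            1000,         "((gB1 and gB2) or gB3)",
    "R_p3",    0,            1000,         "gC3",
    "R_b1",    0,            1000,         "gM1",
    "R_b2",    0,            1000,         "gM2",
    "R_drain", 0,            1000,         "gD1",
    "R_bio",   0,            1000,         NA_character_,
    "EX_P",    0,            1000,         NA_character_)
  stoichiometry <- tibble::tribble(
    ~reaction, ~metabolite, ~coefficient,
    "R_upt",   "A",  1,
    "R_p1",    "A", -1, "R_p1", "B",  1,
    "R_p2",    "B", -1, "R_p2", "C",  1,
    "R_p3",    "C", -1, "R_p3", "P",  1,
    "R_b1",    "A", -1, "R_b1", "M1", 1,
    "R_b2",    "M1", -1, "R_b2", "M2", 1,
    "R_drain", "B", -1,
    "R_bio",   "M2", -1,
    "EX_P",    "P", -1)
  metabolic_model(reactions, stoichiometry,
                  biomass_id = "R_bio", target_id = "EX_P")
}

# Planted relative expression changes (producer vs non-producer). An edge's
# nRS equals rel(target) / rel(regulator), so signs and magnitudes of every
# regulatory strength are fixed by this table regardless of the seed.
toy_rel_changes <- function() {
  c(tG = 4, tM = 2, tA = 1, tD = -0.5, tR = 1, tC1 = 2, tC2 = 0.5,
    gA1 = 1, gB1 = 1, gB2 = 1, gB3 = -0.5, gC3 = 1,
    gD1 = -0.5, gM1 = -0.5, gM2 = -0.5)
}

#' The toy TRN
#'
#' Thirteen signed interactions over seven TRs: a three-level chain
#' (`tG -> tM -> {tA, tD}`), the product-pathway activator `tA` (regulon:
#' `gB1`, `gB2`, `gC3`), the drain/biomass activator `tD` (regulon: `gD1`,
#' `gM1`; carries a self-loop), the product-gene repressor `tR`, and a
#' planted two-TR feedback cycle `tC1 <-> tC2` (with `tC1` also repressing
#' `gM2`), exercising the self-loop and cycle exclusion rules.
#'
#' @return Tibble `(regulator, target, effect)` with symbolic effects
#'   (`"+"`/`"-"`), including the self-loop row.
#' @export
toy_trn <- function() {
  tibble::tribble(
    ~regulator, ~target, ~effect,
    "tG",  "tM",  "+",
    "tM",  "tA",  "+",
    "tM",  "tD",  "-",
    "tA",  "gB1", "+",
    "tA",  "gB2", "+",
    "tA",  "gC3", "+",
    "tD",  "gD1", "+",
    "tD",  "gM1", "+",
    "tD",  "tD",  "+",
    "tR",  "gB3", "-",
    "tC1", "tC2", "+",
    "tC2", "tC1", "+",
    "tC1", "gM2", "-")
}

#' Generate the self-contained toy instance
#'
#' Builds the toy metabolic model, TRN and a consistent synthetic
#' expression table with planted ground truth. Non-producer intensities
#' are seeded random integers (multiples of 4 in \[12, 996\]) and producer
#' intensities follow the planted relative changes exactly, so expression
#' magnitudes vary with the seed while every nRS value — and hence the
#' ground-truth ranking — is seed-invariant. Intensities are integers so
#' the regulatory-strength arithmetic is exactly representable.
#'
#' @param seed Integer RNG seed.
#' @return A `toy_instance`: list with `model`, `trn`, `expression` and
#'   `ground_truth` (expected nRAP signs, hierarchy levels, `h`, and the
#'   planted top/bottom TRs).
#' @export
toy_instance <- function(seed = 1L) {
  rel <- toy_rel_changes()
  set.seed(seed)
  nonprod <- 4L * sample(3:249, length(rel), replace = TRUE)
  expression <- tibble::tibble(
    id = names(rel),
    producer = nonprod * (1 + rel),
    nonproducer = as.numeric(nonprod))
  structure(
    list(
      model = toy_model(),
      trn = toy_trn(),
      expression = expression,
      ground_truth = list(
        nrap_sign = c(R_p1 = 1, R_p2 = 1, R_p3 = 1,
                      R_drain = -1, R_b1 = -1, R_b2 = -1),
        levels = c(tG = 1L, tM = 2L, tA = 3L, tD = 3L,
                   tR = 1L, tC1 = 1L, tC2 = 1L),
        h = 3L,
        top_tr = "tA", bottom_tr = "tD")),
    class = "toy_instance")
}

#' Write a toy instance to disk
#'
#' Writes `model.xml` (SBML L3 + fbc), `trn.tsv` and `expression.tsv` in
#' the dialects the package readers consume. Output is byte-deterministic
#' for a given seed.
#'
#' @param instance A [toy_instance()] (or an integer seed).
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`model`, `trn`, `expression`),
#'   invisibly.
#' @export
write_toy_instance <- function(instance, dir) {
  if (is.numeric(instance)) instance <- toy_instance(instance)
  stopifnot(inherits(instance, "toy_instance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(model = file.path(dir, "model.xml"),
                trn = file.path(dir, "trn.tsv"),
                expression = file.path(dir, "expression.tsv"))
  write_sbml_model(instance$model, paths$model)
  readr::write_tsv(instance$trn, paths$trn)
  expr_out <- tibble::tibble(id = instance$expression$id,
                             producer_1 = instance$expression$producer,
                             nonproducer_1 = instance$expression$nonproducer)
  readr::write_tsv(expr_out, paths$expression)
  invisible(paths)
}

#' Binary-classification metrics from TP/FP/FN counts
#'
#' Computes the derived measures used to evaluate target predictions
#' against literature evidence: sensitivity (TPR), precision (PPV), false
#' negative rate, false discovery rate, F1 score and the FP/FN ratio.
#' True negatives are not involved (they are rarely knowable from
#' literature mining). Values are rounded half-up.
#'
#' @param tp,fp,fn Non-negative integer counts; `tp + fn` and `tp + fp`
#'   must be positive.
#' @param decimals Decimal places for half-up rounding (default 3).
#' @return One-row tibble with `tp`, `fp`, `fn`, `tpr`, `ppv`, `fnr`,
#'   `fdr`, `f1`, `fp_fn` (`NaN` when `fn = 0`).
#' @examples
#' classification_metrics(17, 2, 10)
#' @export
classification_metrics <- function(tp, fp, fn, decimals = 3L) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fn == 0) {
    rlang::abort("sensitivity undefined: TP + FN = 0", class = "regflux_config_error")
  }
  if (tp + fp == 0) {
    rlang::abort("precision undefined: TP + FP = 0", class = "regflux_config_error")
  }
  tpr <- tp / (tp + fn)
  ppv <- tp / (tp + fp)
  f1 <- 2 * ppv * tpr / (ppv + tpr)
  r <- function(x) round_half_up(x, decimals)
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 tpr = r(tpr), ppv = r(ppv),
                 fnr = r(1 - tpr), fdr = r(1 - ppv),
                 f1 = r(f1), fp_fn = r(fp / fn))
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
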