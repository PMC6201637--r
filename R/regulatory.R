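NRS_DENOM_TOL <- 1e-8 # |dTR| below this fraction of TR_nonprod => undefined nRS

# effect vocabularies by TRN dialect
effect_vocab <- function(dialect) {
  pos <- c("+", "1", "+1", "activator", "activation")
  neg <- c("-", "-1", "repressor", "repression")
  dual <- c("+-", "-+", "±", "+/-", "?", "0", "dual", "unknown")
  switch(dialect,
    regulondb = list(pos = c("+"), neg = c("-"), dual = c("+-", "-+", "?")),
    abasy = list(pos = c("activator", "+"), neg = c("repressor", "-"),
                 dual = c("dual", "unknown", "?")),
    generic = list(pos = pos, neg = neg, dual = dual),
    rlang::abort(sprintf("unknown TRN dialect '%s'", dialect),
                 class = "regflux_config_error")
  )
}

#' Read a signed transcriptional regulatory network
#'
#' Expects a TSV with a header and three columns: regulator, target,
#' effect. The effect vocabulary is mapped to `{+1, -1, 0}` (0 = dual or
#' unknown sign) according to the dialect. Self-interactions are dropped;
#' duplicate regulator-target pairs are collapsed, with conflicting signs
#' demoted to 0 (dual).
#'
#' @param path TSV file path.
#' @param dialect One of `"generic"` (default; accepts symbolic and word
#'   vocabularies), `"regulondb"` (`+`/`-`/`+-`/`?`) or `"abasy"`
#'   (`activator`/`repressor`/`dual`).
#' @return Tibble `(regulator, target, effect)` with attribute
#'   `exclusions` — a tibble of dropped rows with a `reason` column
#'   (`"self_loop"`, `"duplicate"`).
#' @export
read_trn <- function(path, dialect = c("generic", "regulondb", "abasy")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(sprintf("TRN file not found: %s", path),
                 class = "regflux_io_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 3L) {
    rlang::abort("TRN file needs columns: regulator, target, effect",
                 class = "regflux_io_error")
  }
  names(raw)[1:3] <- c("regulator", "target", "effect_raw")
  voc <- effect_vocab(dialect)
  eff_norm <- tolower(trimws(raw$effect_raw))
  effect <- dplyr::case_when(
    eff_norm %in% voc$pos ~ 1,
    eff_norm %in% voc$neg ~ -1,
    eff_norm %in% voc$dual ~ 0,
    TRUE ~ NA_real_
  )
  if (anyNA(effect)) {
    bad <- which(is.na(effect))
    rlang::abort(sprintf(
      "unknown effect token(s) '%s' in %s at line(s) %s (dialect '%s')",
      paste(unique(raw$effect_raw[bad]), collapse = "', '"), path,
      paste(bad + 1L, collapse = ", "), dialect),
      class = "regflux_io_error")
  }
  edges <- tibble::tibble(regulator = raw$regulator, target = raw$target,
                          effect = effect)

  self <- edges$regulator == edges$target
  excl <- dplyr::mutate(edges[self, ], reason = "self_loop")
  edges <- edges[!self, ]
  if (nrow(excl) > 0L) {
    message(sprintf("read_trn: dropped %d self-interaction(s)", nrow(excl)))
  }

  collapsed <- edges %>%
    dplyr::group_by(.data$regulator, .data$target) %>%
    dplyr::summarise(
      n = dplyr::n(),
      effect = if (dplyr::n_distinct(.data$effect) > 1L) 0 else .data$effect[[1L]],
      .groups = "drop")
  dup <- collapsed %>%
    dplyr::filter(.data$n > 1L) %>%
    dplyr::mutate(reason = "duplicate") %>%
    dplyr::select("regulator", "target", "effect", "reason")
  out <- dplyr::select(collapsed, "regulator", "target", "effect")
  attr(out, "exclusions") <- dplyr::bind_rows(excl, dup)
  out
}

#' Read a two-condition expression table
#'
#' Expects a TSV whose first column is the gene/TR id, with at least one
#' `producer*` and one `nonproducer*` column (replicates). Replicates are
#' averaged per condition; rows with missing or non-positive intensity in
#' either condition are excluded (the regulatory-strength ratio is
#' undefined for them).
#'
#' @param path TSV file path.
#' @return Tibble `(id, producer, nonproducer)` with attribute
#'   `n_excluded`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("expression file not found: %s", path),
                 class = "regflux_io_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  names(raw)[1L] <- "id"
  pc <- grep("^producer", names(raw), value = TRUE)
  nc <- grep("^non_?producer", names(raw), value = TRUE)
  if (length(pc) == 0L || length(nc) == 0L) {
    rlang::abort("expression file needs producer_* and nonproducer_* columns",
                 class = "regflux_io_error")
  }
  if (anyDuplicated(raw$id)) {
    rlang::abort("duplicated ids in expression table",
                 class = "regflux_io_error")
  }
  out <- tibble::tibble(
    id = as.character(raw$id),
    producer = rowMeans(raw[pc]),
    nonproducer = rowMeans(raw[nc]))
  keep <- is.finite(out$producer) & is.finite(out$nonproducer) &
    out$producer > 0 & out$nonproducer > 0
  if (any(!keep)) {
    message(sprintf("read_expression: excluded %d row(s) with missing or non-positive intensities",
                    sum(!keep)))
  }
  out <- out[keep, ]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Normalized regulatory strengths (nRS)
#'
#' For a regulator `i` and target `j`,
#' `nRS = ((Gene_prod - Gene_nonprod) / (TR_prod - TR_nonprod)) *
#' (TR_nonprod / Gene_nonprod)`: the ratio of absolute expression changes,
#' normalized so that lowly and highly expressed regulators with the same
#' relative effect receive the same strength (nRS equals the ratio of
#' relative changes). Interactions whose regulator expression is unchanged
#' within tolerance, or whose regulator or target is unmeasured, get
#' `nRS = NA` and are excluded downstream.
#'
#' @param interactions Tibble from [read_trn()].
#' @param expression Tibble from [read_expression()].
#' @param tol Relative tolerance on the TR expression change
#'   (default 1e-8).
#' @return `interactions` with added columns `nrs` and `excluded_reason`
#'   (`NA`, `"missing_expression"` or `"zero_tr_change"`).
#' @export
compute_nrs <- function(interactions, expression, tol = NRS_DENOM_TOL) {
  ex <- dplyr::select(expression, "id", "producer", "nonproducer")
  out <- interactions %>%
    dplyr::left_join(dplyr::rename(ex, tr_prod = "producer", tr_nonprod = "nonproducer"),
                     by = c(regulator = "id")) %>%
    dplyr::left_join(dplyr::rename(ex, g_prod = "producer", g_nonprod = "nonproducer"),
                     by = c(target = "id"))
  if (!any(!is.na(out$tr_prod) & !is.na(out$g_prod))) {
    rlang::abort("no overlap between expression ids and TRN ids",
                 class = "regflux_io_error")
  }
  out %>%
    dplyr::mutate(
      excluded_reason = dplyr::case_when(
        is.na(.data$tr_prod) | is.na(.data$g_prod) ~ "missing_expression",
        abs(.data$tr_prod - .data$tr_nonprod) < tol * .data$tr_nonprod ~ "zero_tr_change",
        TRUE ~ NA_character_),
      nrs = dplyr::if_else(
        is.na(.data$excluded_reason),
        (.data$g_prod - .data$g_nonprod) / (.data$tr_prod - .data$tr_nonprod) *
          .data$tr_nonprod / .data$g_nonprod,
        NA_real_)) %>%
    dplyr::select("regulator", "target", "effect", "nrs", "excluded_reason")
}

#' Activator/repressor sign-consistency filter
#'
#' Removes interactions whose measured nRS contradicts the curated effect:
#' activators (`effect = +1`) with negative nRS and repressors
#' (`effect = -1`) with positive nRS. Dual-sign interactions
#' (`effect = 0`) pass regardless. Interactions with undefined nRS are also
#' removed here (they cannot contribute to any score). nRS values are never
#' modified, only rows removed.
#'
#' @param interactions Tibble from [compute_nrs()].
#' @param per_tr If `TRUE`, a single inconsistent edge disqualifies the
#'   whole regulator (every edge of that TR is removed) — the literal
#'   reading of eliminating inconsistent TRs; default `FALSE` filters per
#'   edge, keeping the TR's consistent regulon members.
#' @return Filtered tibble with attribute `removed` (rows with a `reason`
#'   column: `"sign_conflict"`, `"missing_expression"`,
#'   `"zero_tr_change"`, `"inconsistent_tr"`).
#' @export
filter_sign_consistency <- function(interactions, per_tr = FALSE) {
  x <- interactions
  undef <- !is.na(x$excluded_reason)
  conflict <- !undef & ((x$effect == 1 & x$nrs < 0) | (x$effect == -1 & x$nrs > 0))
  if (per_tr) {
    bad_trs <- unique(x$regulator[conflict])
    drop <- undef | x$regulator %in% bad_trs
    reason <- dplyr::case_when(
      undef ~ x$excluded_reason,
      conflict ~ "sign_conflict",
      x$regulator %in% bad_trs ~ "inconsistent_tr",
      TRUE ~ NA_character_)
  } else {
    drop <- undef | conflict
    reason <- dplyr::case_when(
      undef ~ x$excluded_reason,
      conflict ~ "sign_conflict",
      TRUE ~ NA_character_)
  }
  removed <- dplyr::mutate(x[drop, ], reason = reason[drop])
  out <- x[!drop, ]
  attr(out, "removed") <- removed
  out
}
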