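#' Pipeline configuration
#'
#' Bundles and validates every knob of the ranking pipeline. Defaults
#' follow the method's stated operating point: growth constraint at half
#' the maximal biomass flux, an 11-point sweep (`k_step = 0.1`), 1000
#' randomization draws with a ±10% window at a 0.05 threshold, and the
#' alternate-route extension off.
#'
#' @param model,trn,expression Input file paths (SBML, TRN TSV,
#'   expression TSV).
#' @param biomass_id,target_id Biomass and product-exchange reaction ids.
#' @param output_dir Directory for intermediate TSV artifacts and the run
#'   manifest; `NULL` (default) writes nothing.
#' @param growth_fraction,loopless,k_step,alternate_rounds Flux-scoring
#'   knobs; `alternate_rounds = 0` disables the alternate-route extension.
#' @param n_draws,window,alpha,seed Significance-filter knobs.
#' @param trn_dialect Effect vocabulary, see [read_trn()].
#' @param per_tr_filter,strict_significance Behaviour switches, see
#'   [filter_sign_consistency()] and [compute_gtre()].
#' @return A `regflux_config` list.
#' @export
run_config <- function(model, trn, expression, biomass_id, target_id,
                       output_dir = NULL,
                       growth_fraction = 0.5, loopless = FALSE, k_step = 0.1,
                       alternate_rounds = 0L,
                       n_draws = 1000L, window = 0.10, alpha = 0.05,
                       seed = 1L, trn_dialect = "generic",
                       per_tr_filter = FALSE, strict_significance = FALSE) {
  cfg <- list(model = model, trn = trn, expression = expression,
              biomass_id = biomass_id, target_id = target_id,
              output_dir = output_dir,
              growth_fraction = growth_fraction, loopless = loopless,
              k_step = k_step, alternate_rounds = alternate_rounds,
              n_draws = n_draws, window = window, alpha = alpha,
              seed = seed, trn_dialect = trn_dialect,
              per_tr_filter = per_tr_filter,
              strict_significance = strict_significance)
  bad <- function(msg) rlang::abort(msg, class = "regflux_config_error")
  if (!is.numeric(cfg$growth_fraction) || cfg$growth_fraction < 0 ||
      cfg$growth_fraction > 1) bad("growth_fraction must be in [0, 1]")
  if (!is.numeric(cfg$k_step) || cfg$k_step <= 0 || cfg$k_step > 1)
    bad("k_step must be in (0, 1]")
  if (cfg$n_draws < 1) bad("n_draws must be >= 1")
  if (cfg$window <= 0) bad("window must be positive")
  if (cfg$alpha <= 0 || cfg$alpha > 1) bad("alpha must be in (0, 1]")
  if (cfg$alternate_rounds < 0) bad("alternate_rounds must be >= 0")
  structure(cfg, class = "regflux_config")
}

stage <- function(name, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      if (is.null(attr(e, "regflux_stage"))) {
        rlang::abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
                     class = c(class(e)[class(e) != "error" &
                                          class(e) != "condition"],
                               "regflux_stage_error"),
                     parent = e, regflux_stage = name)
      }
    })
}

#' Run the full TR-ranking pipeline
#'
#' Executes read, FVA, nRAP sweep (optionally extended to alternate
#' routes), GPR factors and nGAP, nRS and the sign-consistency filter,
#' TRE, the randomization significance filter, hierarchy construction and
#' bottom-up gTRE propagation, and final ranking. When
#' `config$output_dir` is set, every intermediate table is written as TSV
#' alongside a `manifest.txt` echoing the configuration and the exclusion
#' counts of each stage, so each step is independently inspectable.
#'
#' @param config A [run_config()].
#' @return A `regflux_result`: list with `ranking` (the ranked TR report),
#'   `hierarchy`, `rap`, `gap`, `nrs` (post-filter, with the removed rows
#'   as attribute), `tre`, `significance`, `exclusions` and `config`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "regflux_config"))

  model <- stage("model", read_sbml_model(config$model, config$biomass_id,
                                          config$target_id))
  trn <- stage("regulatory", read_trn(config$trn, config$trn_dialect))
  expr <- stage("regulatory", read_expression(config$expression))

  ranges <- stage("fva", flux_variability(model,
                                          growth_fraction = config$growth_fraction,
                                          loopless = config$loopless))
  rap <- stage("nrap", compute_nrap(model, ranges,
                                    growth_fraction = config$growth_fraction,
                                    k_step = config$k_step))
  if (config$alternate_rounds > 0) {
    rap <- stage("nrap", extend_alternate_routes(
      model, rap, growth_fraction = config$growth_fraction,
      max_rounds = config$alternate_rounds))
  }
  gap <- stage("ngap", compute_ngap(rap, gpr_factor_table(model)))

  nrs <- stage("nrs", compute_nrs(trn, expr))
  filtered <- stage("nrs", filter_sign_consistency(nrs, per_tr = config$per_tr_filter))

  tr_set <- sort(unique(trn$regulator))
  tr_edges <- dplyr::filter(filtered, .data$target %in% tr_set)
  gene_edges <- dplyr::filter(filtered, !.data$target %in% tr_set)

  tre <- stage("tre", compute_tre(gap, gene_edges, trs = tr_set))
  sig <- stage("significance",
               significance_filter(gap, rap, gene_edges, tre,
                                   n_draws = config$n_draws,
                                   window = config$window,
                                   alpha = config$alpha, seed = config$seed))
  hier <- stage("hierarchy", build_hierarchy(tr_edges, trs = tr_set))
  scores <- stage("gtre", compute_gtre(hier, tre, sig,
                                       strict = config$strict_significance))
  ranking <- stage("rank",
                   rank_targets(dplyr::left_join(
                     scores, dplyr::select(sig, "tr", "q", "significant"),
                     by = "tr")) %>%
                     dplyr::select("tr", "level", "tre", "q", "significant",
                                   "gtre", "rank", "direction"))

  exclusions <- list(trn = attr(trn, "exclusions"),
                     expression_rows = attr(expr, "n_excluded"),
                     interactions = attr(filtered, "removed"))
  result <- structure(
    list(ranking = ranking, hierarchy = hier, rap = rap, gap = gap,
         nrs = filtered, tre = tre, significance = sig,
         exclusions = exclusions, config = config),
    class = "regflux_result")
  if (!is.null(config$output_dir)) write_artifacts(result, config$output_dir)
  result
}

write_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(dir, name))
  w(dplyr::select(result$rap, -"sweep"), "nrap.tsv")
  w(result$gap, "ngap.tsv")
  w(result$nrs, "nrs.tsv")
  w(result$tre, "tre.tsv")
  w(result$significance, "significance.tsv")
  w(result$hierarchy$levels, "hierarchy_levels.tsv")
  w(result$hierarchy$edges, "hierarchy_edges.tsv")
  w(result$hierarchy$excluded, "hierarchy_excluded.tsv")
  w(result$ranking, "ranking.tsv")
  cfg <- result$config
  lines <- c(
    vapply(names(cfg), function(k) {
      sprintf("%s: %s", k,
              if (is.null(cfg[[k]])) "NULL" else paste(cfg[[k]], collapse = ","))
    }, character(1L)),
    sprintf("n_trn_exclusions: %d", nrow(result$exclusions$trn %||% data.frame())),
    sprintf("n_expression_rows_excluded: %d", result$exclusions$expression_rows %||% 0L),
    sprintf("n_interactions_removed: %d",
            nrow(result$exclusions$interactions %||% data.frame())),
    if (cfg$alpha >= 1) "note: alpha >= 1 is degenerate; every TR with q < 1 passes the filter")
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @export
print.regflux_result <- function(x, n = 10L, ...) {
  cat(sprintf("<regflux_result> %d TRs ranked, %d hierarchy level(s), %d significant\n",
              nrow(x$ranking), x$hierarchy$h, sum(x$ranking$significant)))
  print(utils::head(x$ranking, n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the ranked TR report
#'
#' @param x A `regflux_result`.
#' @param ... Unused.
#' @return The ranking tibble (`tr`, `level`, `tre`, `q`, `significant`,
#'   `gtre`, `rank`, `direction`).
#' @export
tidy.regflux_result <- function(x, ...) x$ranking

#' One-row summary of a pipeline run
#'
#' @param x A `regflux_result`.
#' @param ... Unused.
#' @return Tibble with TR/level counts, the number of significant TRs and
#'   the top candidate in each direction.
#' @export
glance.regflux_result <- function(x, ...) {
  rk <- x$ranking
  up <- rk$tr[rk$direction == "upregulate"]
  dn <- rk$tr[rk$direction == "downregulate"]
  tibble::tibble(
    n_tr = nrow(rk),
    n_levels = x$hierarchy$h,
    n_significant = sum(rk$significant),
    n_scored_reactions = sum(!x$rap$flagged),
    top_upregulate = if (length(up)) up[[1L]] else NA_character_,
    top_downregulate = if (length(dn)) dn[[length(dn)]] else NA_character_)
}

#' Plot a ranked TR report
#'
#' Horizontal bar chart of gTRE by TR, coloured by manipulation direction,
#' with non-significant TRs de-emphasised.
#'
#' @param object A `regflux_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regflux_result <- function(object, ...) {
  rk <- object$ranking
  rk$tr <- factor(rk$tr, levels = rev(rk$tr))
  ggplot2::ggplot(rk, ggplot2::aes(x = .data$gtre, y = .data$tr,
                                   fill = .data$direction,
                                   alpha = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
                                guide = "none") +
    ggplot2::scale_fill_manual(values = c(upregulate = "#2166ac",
                                          downregulate = "#b2182b",
                                          neutral = "grey60")) +
    ggplot2::labs(x = "global TR effect on product flux (gTRE)", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the sweep behind one reaction's nRAP score
#'
#' @param rap A [compute_nrap()] table.
#' @param reaction Reaction id to plot.
#' @return A ggplot of maximal product flux against the sweep fraction k.
#' @export
plot_nrap_sweep <- function(rap, reaction) {
  i <- match(reaction, rap$reaction)
  if (is.na(i) || is.null(rap$sweep[[i]])) {
    rlang::abort(sprintf("no sweep recorded for reaction '%s'", reaction),
                 class = "regflux_config_error")
  }
  ggplot2::ggplot(rap$sweep[[i]], ggplot2::aes(x = .data$k, y = .data$v_target)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "#2166ac") +
    ggplot2::labs(title = sprintf("%s: nRAP = %.4g", reaction, rap$nrap[[i]]),
                  x = "sweep fraction k", y = "max product flux") +
    ggplot2::theme_minimal()
}
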