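# End-to-end pipeline: run the grid, analyse it, classify the models, and
# write the full artifact set with a manifest. This is the package's
# programmatic equivalent of a command-line `reproduce` run; the individual
# stages are exported separately (administer / run_grid / analyze_results /
# classify_models).

#' Analyse a results table
#'
#' The full statistics stage on one results table: cycle-group
#' descriptives, one-way ANOVA on PE by cycle budget, ANCOVA controlling
#' for categories obtained and NPE, and Bonferroni pairwise comparisons
#' after each.
#'
#' @param results A [run_grid()] results table.
#' @return A list with `descriptives`, `anova`, `ancova`,
#'   `pairwise` (after the ANOVA), `pairwise_adjusted` (differences of
#'   covariate-adjusted means).
#' @export
analyze_results <- function(results) {
  desc <- cycle_descriptives(results)
  av <- one_way_anova(results, outcome = "pe", factor = "cycles")
  ac <- ancova(results, outcome = "pe", factor = "cycles",
               covariates = c("categories", "npe"))
  pw <- pairwise_comparisons(results, outcome = "pe", factor = "cycles")
  # pairwise differences of adjusted means, Bonferroni over pairs
  em <- ac$emmeans
  k <- nrow(em)
  pairs <- utils::combn(k, 2)
  mse <- sum(stats::residuals(ac$fit)^2) / ac$df_within
  ns <- table(base::factor(results$cycles))
  pw_adj <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- em$emmean[a] - em$emmean[b]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tstat <- diff / se
    p_raw <- 2 * stats::pt(-abs(tstat), ac$df_within)
    tcrit <- stats::qt(1 - 0.05 / 2 / ncol(pairs), ac$df_within)
    tibble::tibble(
      group_a = em$group[a], group_b = em$group[b],
      mean_diff = diff, se = se,
      ci_lower = diff - tcrit * se, ci_upper = diff + tcrit * se,
      p_adjusted = min(1, p_raw * ncol(pairs))
    )
  })
  list(descriptives = desc, anova = av, ancova = ac,
       pairwise = pw, pairwise_adjusted = pw_adj)
}

#' Reproduce the full computational experiment
#'
#' Chains every stage with one master seed: runs the default 2,880-session
#' grid (48 variants x budgets 20/40/60 x 20 participants), writes the
#' results table, the descriptive/ANOVA/ANCOVA/pairwise tables, the
#' per-model classification against the packaged comparison boundaries, a
#' comparison against the packaged published reference classification, and
#' a manifest listing every artifact. Two runs with the same seed and
#' config produce byte-identical CSVs.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param config A [grid_config()]; its `master_seed` is replaced by `seed`.
#' @param write_plot Also write the boundary figure as SVG (default FALSE).
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
wcst_reproduce <- function(out_dir, seed = 1L, config = NULL,
                           write_plot = FALSE) {
  if (is.null(config)) config <- grid_config(master_seed = seed)
  config$master_seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  results <- run_grid(config)
  readr::write_csv(results, p("results.csv"))

  ana <- analyze_results(results)
  readr::write_csv(ana$descriptives, p("descriptives.csv"))
  readr::write_csv(dplyr::bind_rows(tidy.wcst_anova(ana$anova),
                                    tidy.wcst_anova(ana$ancova)),
                   p("anova.csv"))
  readr::write_csv(ana$pairwise, p("pairwise_anova.csv"))
  readr::write_csv(ana$pairwise_adjusted, p("pairwise_ancova.csv"))

  summaries <- summarize_models(results)
  classified <- classify_models(summaries)
  readr::write_csv(classified, p("classification.csv"))
  tally <- count_simulating(classified)

  ref <- classify_models(load_reference_models())
  ref_tally <- count_simulating(ref)

  summary <- list(
    n_sessions = nrow(results),
    n_variants = dplyr::n_distinct(results$variant_id),
    n_models = dplyr::n_distinct(results$model_id),
    grand_mean_pe = mean(results$pe),
    group_mean_pe = as.list(tapply(results$pe, results$cycles, mean)),
    anova_F = ana$anova$F, anova_p = ana$anova$p,
    anova_eta_squared = ana$anova$eta_squared,
    ancova_F = ana$ancova$F, ancova_p = ana$ancova$p,
    simulated_counts = as.list(tally$counts),
    n_simulating_both = tally$n_both,
    reference_n_simulating_both = ref_tally$n_both,
    completion_rate = mean(results$categories == 6 &
                             results$correct_sorts >= 60)
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)

  files <- c("results.csv", "descriptives.csv", "anova.csv",
             "pairwise_anova.csv", "pairwise_ancova.csv",
             "classification.csv", "summary.json")
  if (write_plot) {
    gg <- plot_simulation_boundaries(classified)
    ggplot2::ggsave(p("boundaries.svg"), gg, width = 8, height = 5)
    files <- c(files, "boundaries.svg")
  }
  files <- c(files, "manifest.json")
  manifest <- list(
    package = "wcstsim",
    version = as.character(utils::packageVersion("wcstsim")),
    master_seed = as.integer(seed),
    n_participants = config$n_participants,
    cycle_budgets = config$cycle_budgets,
    constants = config$constants,
    artifacts = as.list(stats::setNames(file.path(out_dir, files), files)),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
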