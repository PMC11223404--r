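# ggplot2 figures for grid results and classifications.

#' Plot model means against the simulation boundary band
#'
#' Per-model mean PE by cycle budget, overlaid with the union of the two
#' comparison-group boundary intervals as a shaded band: points inside the
#' band simulate at least one cancer-survivor group.
#'
#' @param model_summaries A tibble with `mean_pe` and `cycles` columns
#'   (e.g. [summarize_models()] output or [load_reference_models()]).
#' @param lt_bounds,ct_bounds Boundary intervals.
#' @return A ggplot object.
#' @export
plot_simulation_boundaries <- function(model_summaries,
                                       lt_bounds = c(12.50, 15.90),
                                       ct_bounds = c(13.27, 15.93)) {
  band <- c(min(lt_bounds[1], ct_bounds[1]), max(lt_bounds[2], ct_bounds[2]))
  df <- dplyr::mutate(model_summaries,
                      cycles = base::factor(.data$cycles))
  ggplot2::ggplot(df, ggplot2::aes(
    x = seq_along(.data$mean_pe), y = .data$mean_pe,
    colour = .data$cycles
  )) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = band[1], ymax = band[2],
                      alpha = 0.2, fill = "grey40") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(
      x = "model (ordered as supplied)",
      y = "mean perseveration errors",
      colour = "cycle budget",
      title = "Model mean PE against cancer-survivor simulation boundaries"
    ) +
    ggplot2::theme_minimal()
}

#' Plot perseveration errors by cycle budget
#'
#' Distribution of per-participant PE for each cycle budget, with group
#' means; the visual counterpart of the one-way analysis.
#'
#' @param results A [run_grid()] results table.
#' @return A ggplot object.
#' @export
plot_pe_by_cycles <- function(results) {
  df <- dplyr::mutate(results, cycles = base::factor(.data$cycles))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycles, y = .data$pe)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          size = 3, colour = "firebrick") +
    ggplot2::labs(x = "cycle budget",
                  y = "perseveration errors per session",
                  title = "Additional processing cycles reduce perseveration") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.wcst_anova <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$outcome)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.2, size = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          size = 3, colour = "firebrick") +
    ggplot2::labs(
      x = object$term, y = "outcome",
      title = sprintf("%s: F(%d, %d) = %.2f", toupper(object$kind),
                      object$df_between, object$df_within, object$F)
    ) +
    ggplot2::theme_minimal()
}
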