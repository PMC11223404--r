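# Classification of model mean PE against +/- 1 SE boundary intervals of
# the two cancer-survivor comparison groups (local therapy, chemotherapy).

#' Simulation boundary interval
#'
#' The closed interval `[mean - se, mean + se]`, endpoints inclusive: a
#' model whose mean PE lands inside it simulates that comparison group.
#'
#' @param mean Group mean.
#' @param se Group standard error (>= 0).
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @examples
#' se_bounds(12.5, 1.33)
#' @export
se_bounds <- function(mean, se) {
  if (!is.numeric(se) || any(se < 0)) {
    rlang::abort("`se` must be non-negative.", class = "wcstsim_config_error")
  }
  c(lower = mean - se, upper = mean + se)
}

#' Simulation label vocabulary
#'
#' @return The five labels, partitioning the real line given two
#'   overlapping boundary intervals: `"LT-"` (below both), `"LT"` (inside
#'   the local-therapy interval only), `"LT, CT"` (inside both), `"CT"`
#'   (inside the chemotherapy interval only), `"CT+"` (above both).
#' @export
simulation_labels <- function() c("LT-", "LT", "LT, CT", "CT", "CT+")

#' Classify mean PE against the two group intervals
#'
#' Vectorised over `mean_pe`. Endpoints are inclusive. Means are classified
#' exactly as supplied (printed two-decimal means are not re-rounded).
#'
#' @param mean_pe Numeric vector of model mean PE values.
#' @param lt_bounds,ct_bounds Length-2 `c(lower, upper)` intervals; defaults
#'   are the packaged printed boundaries (see [load_comparison_groups()]).
#' @return Character vector of labels from [simulation_labels()].
#' @examples
#' classify_pe(c(15.20, 43.10, 15.90, 0))
#' @export
classify_pe <- function(mean_pe,
                        lt_bounds = c(12.50, 15.90),
                        ct_bounds = c(13.27, 15.93)) {
  stopifnot(length(lt_bounds) == 2, length(ct_bounds) == 2,
            lt_bounds[1] <= lt_bounds[2], ct_bounds[1] <= ct_bounds[2])
  in_lt <- mean_pe >= lt_bounds[1] & mean_pe <= lt_bounds[2]
  in_ct <- mean_pe >= ct_bounds[1] & mean_pe <= ct_bounds[2]
  out <- dplyr::case_when(
    in_lt & in_ct ~ "LT, CT",
    in_lt ~ "LT",
    in_ct ~ "CT",
    mean_pe < lt_bounds[1] & mean_pe < ct_bounds[1] ~ "LT-",
    mean_pe > lt_bounds[2] & mean_pe > ct_bounds[2] ~ "CT+",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    rlang::warn("Some means fall in a gap between disjoint intervals.")
  }
  out
}

#' Classify a table of model summaries
#'
#' Adds a `label` column to per-model summaries (any table with a `mean_pe`
#' column, e.g. from [summarize_models()] or [load_table6()]).
#'
#' @param model_summaries A tibble with a `mean_pe` column.
#' @inheritParams classify_pe
#' @return The input with a `label` column appended.
#' @export
classify_models <- function(model_summaries,
                            lt_bounds = c(12.50, 15.90),
                            ct_bounds = c(13.27, 15.93)) {
  dplyr::mutate(
    model_summaries,
    label = classify_pe(.data$mean_pe, lt_bounds, ct_bounds)
  )
}

#' Tally simulation labels
#'
#' Counts models per label and lists the models simulating both groups.
#'
#' @param classified A tibble with a `label` column (from
#'   [classify_models()]).
#' @return A list with `counts` (named integer vector over the full label
#'   vocabulary), `n_both` (number of models labelled `"LT, CT"`), and
#'   `both_models` (the rows so labelled).
#' @examples
#' count_simulating(classify_models(load_reference_models()))$n_both
#' @export
count_simulating <- function(classified) {
  labs <- simulation_labels()
  counts <- stats::setNames(integer(length(labs)), labs)
  if (nrow(classified) > 0) {
    tab <- table(base::factor(classified$label, levels = labs))
    counts[names(tab)] <- as.integer(tab)
  }
  both <- classified[!is.na(classified$label) &
                       classified$label == "LT, CT", , drop = FALSE]
  list(counts = counts, n_both = nrow(both), both_models = both)
}
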