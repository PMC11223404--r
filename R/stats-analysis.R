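# Statistical pipeline: descriptives, one-way ANOVA with eta squared,
# ANCOVA with covariate adjustment and estimated marginal means, and
# Bonferroni-adjusted pairwise comparisons with Cohen's d.

#' Group descriptives
#'
#' n, mean, sample SD, SE = SD / sqrt(n), normal-approximation 95% CI
#' (mean +/- 1.96 SE), minimum and maximum, per group. Accepts a grouped or
#' ungrouped data frame; when ungrouped a single row is returned.
#'
#' @param data A (possibly grouped) data frame.
#' @param value Column to summarise (default `pe`).
#' @return A tibble with columns `n`, `mean`, `sd`, `se`, `ci_lower`,
#'   `ci_upper`, `min`, `max` (plus the grouping columns).
#' @examples
#' library(dplyr)
#' tibble::tibble(g = c("a", "a", "a"), pe = c(1, 2, 3)) |>
#'   group_by(g) |>
#'   pe_descriptives()
#' @export
pe_descriptives <- function(data, value = "pe") {
  if (nrow(data) == 0) {
    rlang::abort("No data to summarise.", class = "wcstsim_no_data")
  }
  out <- dplyr::summarise(
    data,
    n = dplyr::n(),
    mean = mean(.data[[value]]),
    sd = ifelse(dplyr::n() > 1, stats::sd(.data[[value]]), 0),
    min = min(.data[[value]]),
    max = max(.data[[value]]),
    .groups = "drop"
  )
  dplyr::mutate(
    out,
    se = .data$sd / sqrt(.data$n),
    ci_lower = .data$mean - 1.96 * .data$se,
    ci_upper = .data$mean + 1.96 * .data$se,
    .after = "sd"
  )
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA of an outcome on a grouping
#' factor, with effect size eta squared = SS_between / SS_total.
#'
#' @param data A data frame.
#' @param outcome Name of the numeric outcome column (default `"pe"`).
#' @param factor Name of the grouping column (default `"cycles"`).
#' @return A list of class `wcst_anova` with `F`, `df_between`, `df_within`,
#'   `p`, `eta_squared`, the underlying `lm` fit, and the group table.
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 4),
#'                     pe = c(1, 2, 3, 4, 2, 3, 4, 5, 6, 7, 8, 9))
#' one_way_anova(d, outcome = "pe", factor = "g")
#' @export
one_way_anova <- function(data, outcome = "pe", factor = "cycles") {
  grp <- base::factor(data[[factor]])
  y <- data[[outcome]]
  if (nlevels(grp) < 2) {
    rlang::abort("ANOVA needs at least 2 groups.",
                 class = "wcstsim_design_error")
  }
  if (any(table(grp) < 2)) {
    rlang::abort("Every group needs at least 2 observations.",
                 class = "wcstsim_design_error")
  }
  fit <- stats::lm(y ~ grp)
  av <- stats::anova(fit)
  ss_b <- av$`Sum Sq`[1]
  ss_w <- av$`Sum Sq`[2]
  structure(
    list(
      F = av$`F value`[1],
      df_between = av$Df[1],
      df_within = av$Df[2],
      p = av$`Pr(>F)`[1],
      eta_squared = ss_b / (ss_b + ss_w),
      fit = fit,
      data = tibble::tibble(group = grp, outcome = y),
      term = factor,
      kind = "anova"
    ),
    class = "wcst_anova"
  )
}

#' Analysis of covariance
#'
#' Linear model `outcome ~ factor + covariates` with the covariates entered
#' simultaneously. The factor test is the partial (type-III-style) F
#' comparing the full model with the covariates-only model, and eta squared
#' is the factor partial SS over the total SS. Covariates with zero variance
#' are dropped with a warning; a covariate collinear with the remaining
#' design is an error. Estimated marginal means are the per-level
#' predictions with every covariate held at its grand mean.
#'
#' @param data A data frame.
#' @param outcome,factor Column names as in [one_way_anova()].
#' @param covariates Character vector of numeric covariate columns
#'   (default `c("categories", "npe")`).
#' @return A list of class `wcst_anova` (kind `"ancova"`) with the factor
#'   test, the overall model F, `emmeans` (a tibble of adjusted means), and
#'   the retained covariates.
#' @export
ancova <- function(data, outcome = "pe", factor = "cycles",
                   covariates = c("categories", "npe")) {
  grp <- base::factor(data[[factor]])
  y <- data[[outcome]]
  if (nlevels(grp) < 2) {
    rlang::abort("ANCOVA needs at least 2 groups.",
                 class = "wcstsim_design_error")
  }
  keep <- character(0)
  for (cv in covariates) {
    v <- data[[cv]]
    if (!is.numeric(v)) {
      rlang::abort(sprintf("Covariate `%s` must be numeric.", cv),
                   class = "wcstsim_design_error")
    }
    if (stats::var(v) == 0) {
      rlang::warn(sprintf(
        "Covariate `%s` has zero variance and was dropped.", cv))
    } else {
      keep <- c(keep, cv)
    }
  }
  df <- data.frame(.y = y, .grp = grp)
  for (cv in keep) df[[cv]] <- data[[cv]]
  rhs_cov <- if (length(keep)) paste(keep, collapse = " + ") else NULL
  full_f <- stats::as.formula(paste(
    ".y ~ .grp", if (!is.null(rhs_cov)) paste("+", rhs_cov) else ""))
  fit <- stats::lm(full_f, data = df)
  if (any(is.na(stats::coef(fit)))) {
    rlang::abort("Design matrix is rank deficient (collinear covariates).",
                 class = "wcstsim_design_error")
  }
  reduced_f <- stats::as.formula(paste(
    ".y ~", if (!is.null(rhs_cov)) rhs_cov else "1"))
  reduced <- stats::lm(reduced_f, data = df)
  cmp <- stats::anova(reduced, fit)
  ss_factor <- cmp$`Sum of Sq`[2]
  df_factor <- cmp$Df[2]
  ss_total <- sum((y - mean(y))^2)
  # overall model F (all predictors vs intercept)
  sm <- summary(fit)
  overall <- sm$fstatistic

  # estimated marginal means: predictions at covariate grand means
  new <- data.frame(.grp = base::factor(levels(grp), levels = levels(grp)))
  for (cv in keep) new[[cv]] <- mean(df[[cv]])
  pr <- stats::predict(fit, newdata = new, se.fit = TRUE)
  emmeans <- tibble::tibble(
    group = levels(grp),
    emmean = as.numeric(pr$fit),
    se = as.numeric(pr$se.fit)
  )
  structure(
    list(
      F = cmp$F[2],
      df_between = df_factor,
      df_within = cmp$Res.Df[2],
      p = cmp$`Pr(>F)`[2],
      eta_squared = ss_factor / ss_total,
      model_F = unname(overall[1]),
      model_df = unname(overall[2:3]),
      model_r_squared = sm$r.squared,
      fit = fit,
      emmeans = emmeans,
      covariates = keep,
      data = tibble::tibble(group = grp, outcome = y),
      term = factor,
      kind = "ancova"
    ),
    class = "wcst_anova"
  )
}

#' @export
print.wcst_anova <- function(x, ...) {
  cat(sprintf(
    "<%s> F(%d, %d) = %.2f, p = %.3g, eta^2 = %.3f\n",
    toupper(x$kind), x$df_between, x$df_within, x$F, x$p, x$eta_squared
  ))
  invisible(x)
}

#' Broom-style accessors for ANOVA/ANCOVA fits
#'
#' @param x A `wcst_anova`.
#' @param ... Unused.
#' @return `tidy()` returns one row per term of the underlying test;
#'   `glance()` returns a one-row model summary.
#' @export
tidy.wcst_anova <- function(x, ...) {
  tibble::tibble(
    term = x$term,
    df = x$df_between,
    df_residual = x$df_within,
    statistic = x$F,
    p_value = x$p,
    eta_squared = x$eta_squared
  )
}

#' @rdname tidy.wcst_anova
#' @export
glance.wcst_anova <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    statistic = x$F,
    df = x$df_between,
    df_residual = x$df_within,
    p_value = x$p,
    eta_squared = x$eta_squared,
    n = nrow(x$data)
  )
}

#' Pairwise comparisons from group summary statistics
#'
#' The summary-statistics route used when only printed group means and SDs
#' are available: for every unordered pair of groups it gives the mean
#' difference, its standard error from the pooled within-group mean square,
#' the Bonferroni-adjusted p value and simultaneous confidence interval, and
#' Cohen's d with the two-group pooled SD `sqrt((s_a^2 + s_b^2) / 2)`.
#'
#' @param stats_tbl A tibble with columns `group`, `n`, `mean`, `sd`.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per pair: `group_a`, `group_b`,
#'   `mean_diff`, `se`, `ci_lower`, `ci_upper`, `p_adjusted`, `cohens_d`.
#' @examples
#' tbl <- tibble::tibble(group = c("20", "40"), n = c(960, 960),
#'                       mean = c(13.55, 6.90), sd = c(9.34, 6.31))
#' pairwise_from_stats(tbl)
#' @export
pairwise_from_stats <- function(stats_tbl, conf_level = 0.95) {
  k <- nrow(stats_tbl)
  if (k < 2) {
    rlang::abort("Need at least 2 groups.", class = "wcstsim_design_error")
  }
  mse <- sum((stats_tbl$n - 1) * stats_tbl$sd^2) / sum(stats_tbl$n - 1)
  df_w <- sum(stats_tbl$n) - k
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  alpha_adj <- (1 - conf_level) / m
  purrr::map_dfr(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- stats_tbl$mean[a] - stats_tbl$mean[b]
    se <- sqrt(mse * (1 / stats_tbl$n[a] + 1 / stats_tbl$n[b]))
    tstat <- diff / se
    p_raw <- 2 * stats::pt(-abs(tstat), df_w)
    tcrit <- stats::qt(1 - alpha_adj / 2, df_w)
    d <- diff / sqrt((stats_tbl$sd[a]^2 + stats_tbl$sd[b]^2) / 2)
    tibble::tibble(
      group_a = as.character(stats_tbl$group[a]),
      group_b = as.character(stats_tbl$group[b]),
      mean_diff = diff, se = se,
      ci_lower = diff - tcrit * se, ci_upper = diff + tcrit * se,
      p_adjusted = min(1, p_raw * m),
      cohens_d = d
    )
  })
}

#' Pairwise comparisons from raw data
#'
#' All unordered group pairs after a one-way design, with Bonferroni
#' adjustment; delegates to [pairwise_from_stats()] on the observed group
#' summaries.
#'
#' @param data A data frame.
#' @param outcome,factor Column names as in [one_way_anova()].
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble as in [pairwise_from_stats()].
#' @export
pairwise_comparisons <- function(data, outcome = "pe", factor = "cycles",
                                 conf_level = 0.95) {
  grp <- base::factor(data[[factor]])
  if (nlevels(grp) < 2) {
    rlang::abort("Need at least 2 groups.", class = "wcstsim_design_error")
  }
  y <- data[[outcome]]
  tbl <- tibble::tibble(group = grp, y = y) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$y),
                     sd = stats::sd(.data$y), .groups = "drop")
  pairwise_from_stats(tbl, conf_level = conf_level)
}
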