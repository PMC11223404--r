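# Statistical pipeline: descriptives, ANOVA/ANCOVA against brute-force
# oracles, pairwise comparisons and Cohen's d from printed inputs.

test_that("descriptives reproduce the printed comparison-group SEs", {
  # chemotherapy: SD 6.9, n 27 -> SE 1.33; local therapy: SD 9.3, n 30 -> 1.70
  expect_equal(round(6.9 / sqrt(27), 2), 1.33)
  expect_equal(round(9.3 / sqrt(30), 2), 1.70)
  d <- tibble::tibble(pe = c(1, 2, 3)) |> pe_descriptives()
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$se, 1 / sqrt(3))
  expect_equal(d$min, 1)
  expect_equal(d$max, 3)
  expect_error(pe_descriptives(tibble::tibble(pe = numeric(0))),
               class = "wcstsim_no_data")
})

test_that("one-way ANOVA matches the brute-force sums-of-squares oracle", {
  set.seed(31)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    n_per <- sample(3:7, 1)
    y <- rnorm(k * n_per, mean = rep(sample(5, k), each = n_per))
    g <- rep(letters[1:k], each = n_per)
    got <- one_way_anova(tibble::tibble(pe = y, cycles = g))
    want <- anova_oracle(y, g)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    expect_equal(got$eta_squared, want$eta_squared, tolerance = 1e-8)
    expect_equal(got$df_between, want$df_between)
    expect_equal(got$df_within, want$df_within)
    expect_gte(got$eta_squared, 0)
    expect_lte(got$eta_squared, 1)
  }
})

test_that("ANOVA degenerate designs behave as specified", {
  # identical groups: F = 0, eta^2 = 0
  d <- tibble::tibble(pe = rep(c(1, 2, 3), 2),
                      cycles = rep(c("a", "b"), each = 3))
  a <- one_way_anova(d)
  expect_equal(a$F, 0)
  expect_equal(a$eta_squared, 0)
  # equal means, unequal variances: F ~ 0
  d2 <- tibble::tibble(pe = c(4, 6, 5, 1, 9, 5), cycles = rep(c("a", "b"), each = 3))
  expect_lt(one_way_anova(d2)$F, 1e-10)
  expect_error(one_way_anova(tibble::tibble(pe = 1:4, cycles = "a")),
               class = "wcstsim_design_error")
})

test_that("ANCOVA matches the normal-equations oracle on small instances", {
  set.seed(53)
  for (rep in 1:5) {
    n <- sample(c(12, 18, 24, 30), 1)
    g <- sample(c("g1", "g2", "g3"), n, replace = TRUE)
    while (length(unique(g)) < 3) g <- sample(c("g1", "g2", "g3"), n, TRUE)
    covs <- data.frame(categories = rnorm(n, 6, 1), npe = rnorm(n, 4, 2))
    y <- 2 + 3 * (g == "g2") + 0.5 * covs$categories - 0.2 * covs$npe + rnorm(n)
    d <- tibble::tibble(pe = y, cycles = g,
                        categories = covs$categories, npe = covs$npe)
    got <- ancova(d)
    want <- ancova_oracle(y, g, covs)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    expect_equal(got$eta_squared, want$eta_squared, tolerance = 1e-8)
    expect_equal(got$df_within, want$df_within)
    # coefficients match the hand normal-equations solution
    expect_equal(sort(unname(stats::coef(got$fit))),
                 sort(as.numeric(want$coef)), tolerance = 1e-8)
  }
})

test_that("ANCOVA handles degenerate covariates as documented", {
  set.seed(11)
  d <- tibble::tibble(
    pe = c(rnorm(6, 10), rnorm(6, 5)),
    cycles = rep(c("a", "b"), each = 6),
    categories = 6, # zero variance -> dropped with a warning
    npe = rnorm(12, 4)
  )
  expect_warning(ac <- ancova(d), "zero variance")
  # with both covariates constant the factor test reduces to the ANOVA
  d2 <- dplyr::mutate(d, npe = 2)
  ac2 <- suppressWarnings(ancova(d2))
  av <- one_way_anova(d2)
  expect_equal(ac2$F, av$F, tolerance = 1e-10)
  # covariate perfectly collinear with the factor: error
  d3 <- dplyr::mutate(d, npe = as.numeric(cycles == "a"))
  expect_error(suppressWarnings(ancova(d3)), class = "wcstsim_design_error")
})

test_that("ANCOVA marginal means are predictions at covariate grand means", {
  set.seed(17)
  d <- tibble::tibble(
    pe = rnorm(20, 8), cycles = rep(c("a", "b"), each = 10),
    categories = rnorm(20, 6), npe = rnorm(20, 4)
  )
  ac <- ancova(d)
  # hand prediction for group a at grand means
  cf <- stats::coef(ac$fit)
  pred_a <- cf[["(Intercept)"]] + cf[["categories"]] * mean(d$categories) +
    cf[["npe"]] * mean(d$npe)
  expect_equal(ac$emmeans$emmean[ac$emmeans$group == "a"], pred_a)
  # when covariates explain nothing systematic the adjusted means track the
  # raw means
  expect_equal(ac$emmeans$group, c("a", "b"))
})

test_that("pairwise comparisons reproduce the printed group contrasts", {
  # printed descriptives for the three cycle groups (n = 960 each)
  tbl <- tibble::tibble(
    group = c("20-cycles", "40-cycles", "60-cycles"),
    n = 960, mean = c(13.55, 6.90, 5.28), sd = c(9.34, 6.31, 5.98)
  )
  pw <- pairwise_from_stats(tbl)
  r12 <- pw[pw$group_a == "20-cycles" & pw$group_b == "40-cycles", ]
  expect_equal(round(r12$mean_diff, 2), 6.65)
  expect_equal(round(r12$se, 3), 0.336)
  # Bonferroni-adjusted simultaneous CI; the printed interval was computed
  # from unrounded group means, so allow the rounding slack
  expect_lt(abs(r12$ci_lower - 5.84), 0.02)
  expect_lt(abs(r12$ci_upper - 7.45), 0.02)
  expect_equal(round(r12$cohens_d, 3), 0.834)
  r13 <- pw[pw$group_a == "20-cycles" & pw$group_b == "60-cycles", ]
  expect_equal(round(r13$mean_diff, 2), 8.27) # printed as 8.28 from rounding
  expect_equal(round(r13$cohens_d, 2), 1.05)
  r23 <- pw[pw$group_a == "40-cycles" & pw$group_b == "60-cycles", ]
  expect_equal(round(r23$mean_diff, 2), 1.62)
  expect_equal(round(r23$cohens_d, 3), 0.264)
  # grand mean of the three printed group means
  expect_equal(round(mean(c(13.55, 6.90, 5.28)), 2), 8.58)
})

test_that("pairwise comparisons on identical groups are null results", {
  d <- tibble::tibble(pe = rep(c(1, 2, 3, 4), 2),
                      cycles = rep(c("a", "b"), each = 4))
  pw <- pairwise_comparisons(d)
  expect_equal(pw$mean_diff, 0)
  expect_equal(pw$cohens_d, 0)
  expect_equal(pw$p_adjusted, 1)
  expect_true(pw$ci_lower <= 0 && pw$ci_upper >= 0)
})

test_that("Bonferroni adjustment never drops below the raw p value", {
  set.seed(61)
  d <- tibble::tibble(pe = rnorm(30), cycles = rep(c("a", "b", "c"), 10))
  pw <- pairwise_comparisons(d)
  raw <- sapply(seq_len(nrow(pw)), function(i) {
    2 * stats::pt(-abs(pw$mean_diff[i] / pw$se[i]), 27)
  })
  expect_true(all(pw$p_adjusted >= raw - 1e-12))
  expect_true(all(pw$p_adjusted <= 1))
  # CI contains the point estimate
  expect_true(all(pw$ci_lower <= pw$mean_diff & pw$mean_diff <= pw$ci_upper))
})

test_that("tidy and glance methods expose the fitted tests", {
  d <- tibble::tibble(pe = rnorm(20, 8), cycles = rep(c("a", "b"), each = 10),
                      categories = rnorm(20, 6), npe = rnorm(20, 4))
  av <- one_way_anova(d)
  td <- tidy(av)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$statistic, av$F)
  gl <- glance(ancova(d))
  expect_equal(gl$kind, "ancova")
  expect_equal(gl$n, 20)
})
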