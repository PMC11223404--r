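# Shared helpers for the wcstsim test suite.

# Brute-force one-way sums-of-squares oracle, independent of the lm route
# used by the package.
anova_oracle <- function(y, g) {
  g <- as.character(g)
  grand <- mean(y)
  groups <- split(y, g)
  ss_b <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- length(groups) - 1
  df_w <- length(y) - length(groups)
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(F = f, df_between = df_b, df_within = df_w,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       eta_squared = ss_b / (ss_b + ss_w))
}

# Normal-equations least-squares oracle for the ANCOVA factor test:
# builds design matrices by hand, solves X'X b = X'y with solve(), and
# forms the partial F for the factor from residual sums of squares.
ancova_oracle <- function(y, g, covs) {
  g <- factor(g)
  n <- length(y)
  dummies <- sapply(levels(g)[-1], function(l) as.numeric(g == l))
  x_full <- cbind(1, dummies, as.matrix(covs))
  x_red <- cbind(1, as.matrix(covs))
  fit_rss <- function(x) {
    b <- solve(t(x) %*% x, t(x) %*% y)
    sum((y - x %*% b)^2)
  }
  rss_full <- fit_rss(x_full)
  rss_red <- fit_rss(x_red)
  df_b <- nlevels(g) - 1
  df_w <- n - ncol(x_full)
  f <- ((rss_red - rss_full) / df_b) / (rss_full / df_w)
  list(F = f, df_between = df_b, df_within = df_w,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       eta_squared = (rss_red - rss_full) / sum((y - mean(y))^2),
       coef = solve(t(x_full) %*% x_full, t(x_full) %*% y))
}

# A small grid configuration for fast structural tests.
tiny_grid_config <- function(n = 2L, seed = 101L) {
  grid_config(n_participants = n, master_seed = seed)
}
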