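#' Ordinary least-squares fit of one time series
#'
#' Fits `values ~ times` by ordinary least squares and reports the
#' coefficients with the quantities needed for slope inference.
#'
#' @param times Predictor (time) values; at least 2 distinct values.
#' @param values Response values, same length.
#' @return A `linear_fit` list: `slope`, `intercept`, `slope_se`,
#'   `residual_variance` (SSE / (n - 2)), `n`, `r_squared` (1 for an exact
#'   fit, including constant series), `p_value` (two-sided test of slope = 0),
#'   plus internals `sse` and `sxx` used by the slope-comparison test.
#' @export
fit_linear <- function(times, values) {
  if (length(times) != length(values)) {
    abort_input("times and values must have equal length")
  }
  if (length(times) < 2L || length(unique(times)) < 2L) {
    abort_input("at least 2 distinct time values are required")
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    abort_input("times and values must be finite")
  }
  fit <- stats::lm(values ~ times)
  n <- length(times)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((values - mean(values))^2)
  sxx <- sum((times - mean(times))^2)
  resid_var <- if (n > 2L) sse / (n - 2L) else 0
  slope <- unname(stats::coef(fit)[2L])
  slope_se <- if (n > 2L) sqrt(resid_var / sxx) else NA_real_
  p_value <- if (n > 2L && slope_se > 0) {
    2 * stats::pt(-abs(slope / slope_se), df = n - 2L)
  } else if (n > 2L) {
    if (slope == 0) 1 else 0
  } else {
    NA_real_
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_se = slope_se,
                 residual_variance = resid_var,
                 n = n,
                 r_squared = if (sst == 0) as.numeric(sse == 0) else 1 - sse / sst,
                 p_value = p_value,
                 sse = sse, sxx = sxx, tbar = mean(times)),
            class = "linear_fit")
}

as_series <- function(x, name) {
  if (inherits(x, "linear_fit")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("times", "values") %in% names(x))) {
      abort_input(name, " must have columns times and values")
    }
    return(fit_linear(x$times, x$values))
  }
  if (is.list(x) && all(c("times", "values") %in% names(x))) {
    return(fit_linear(x$times, x$values))
  }
  abort_input(name, " must be a list/data frame with times and values, ",
              "or a linear_fit")
}

#' Compare the slopes of two expression time series (ANCOVA)
#'
#' Fits independent linear models to each series and compares their slope
#' coefficients with the classical two-regression equality-of-slopes t-test:
#' the pooled residual variance is `(SSE_a + SSE_b) / (n_a + n_b - 4)`, the
#' statistic `(b_a - b_b) / sqrt(s2 * (1/Sxx_a + 1/Sxx_b))` on
#' `n_a + n_b - 4` degrees of freedom, two-sided. The intercept comparison is
#' reported secondarily. When both fits are exact and the slopes are equal the
#' series dynamics are indistinguishable and p = 1 by convention.
#'
#' @param a,b Series as `list(times, values)` (or data frames, or
#'   pre-computed [fit_linear()] objects).
#' @param alpha Significance level for the `significant` flag.
#' @return A `slope_comparison` list: `delta_slope`, `test_statistic`, `dof`,
#'   `p_value`, `significant`, and secondary `delta_intercept`,
#'   `p_intercept`.
#' @export
compare_timeseries_ancova <- function(a, b, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE)
  fa <- as_series(a, "a")
  fb <- as_series(b, "b")
  dof <- fa$n + fb$n - 4L
  if (dof < 1L) abort_input("too few observations: dof = n_a + n_b - 4 < 1")
  s2 <- (fa$sse + fb$sse) / dof
  delta <- fa$slope - fb$slope
  se <- sqrt(s2 * (1 / fa$sxx + 1 / fb$sxx))
  if (se == 0) {
    tstat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    tstat <- delta / se
    p <- 2 * stats::pt(-abs(tstat), df = dof)
  }
  # intercept comparison with the same pooled variance
  d_int <- fa$intercept - fb$intercept
  se_int <- sqrt(s2 * (1 / fa$n + mean_sq(fa) / fa$sxx +
                         1 / fb$n + mean_sq(fb) / fb$sxx))
  p_int <- if (se_int == 0) {
    if (d_int == 0) 1 else 0
  } else {
    2 * stats::pt(-abs(d_int / se_int), df = dof)
  }
  structure(list(delta_slope = delta, test_statistic = tstat, dof = dof,
                 p_value = p, significant = p < alpha, alpha = alpha,
                 delta_intercept = d_int, p_intercept = p_int),
            class = "slope_comparison")
}

# fits carry the mean of their time values for the intercept-comparison SE
mean_sq <- function(f) {
  if (!is.null(f$tbar)) f$tbar^2 else 0
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values controlling the FDR; a validated front end to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @return q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    abort_input("p_values must all lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA: `F = MS_between / MS_within`. When
#' the between-group mean square is 0 (identical group means) `F = 0` and
#' `p = 1`, including the fully degenerate all-constant case.
#'
#' @param groups A list of numeric samples, each with >= 2 observations.
#' @return A list: `F`, `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort_input("at least 2 groups are required")
  }
  if (any(vapply(groups, length, 0L) < 2L)) {
    abort_input("every group needs >= 2 observations")
  }
  y <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(y))) abort_input("observations must be finite")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  ms_between <- sum(tapply(y, g, length) * (tapply(y, g, mean) - mean(y))^2) /
    (nlevels(g) - 1L)
  if (ms_between == 0) {
    return(list(F = 0, df_between = nlevels(g) - 1L,
                df_within = length(y) - nlevels(g), p_value = 1))
  }
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = tab[["F value"]][1L],
       df_between = tab[["Df"]][1L],
       df_within = tab[["Df"]][2L],
       p_value = tab[["Pr(>F)"]][1L])
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Two-sided pooled-variance t-test. Degenerate data (zero pooled variance)
#' follows the limit convention: equal means give `p = 1`, unequal means give
#' `p = 0` with a warning.
#'
#' @param a,b Numeric samples, each with >= 2 observations.
#' @return A list: `statistic`, `dof`, `p_value`.
#' @export
students_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_input("each sample needs >= 2 observations")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort_input("samples must be finite")
  }
  dof <- length(a) + length(b) - 2L
  pooled <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / dof
  if (pooled == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, dof = dof, p_value = 1))
    }
    warning("zero pooled variance with unequal means; p = 0 limit")
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, dof = dof,
                p_value = 0))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Bonferroni multiple range test
#'
#' All pairwise pooled-variance t-tests between group means; a pair is
#' declared significant when its raw p-value is below `alpha / m` where `m`
#' is the number of pairs (Bonferroni multiple-range procedure).
#'
#' @param groups Named list of numeric samples (>= 2 groups, each >= 2
#'   observations).
#' @param alpha Familywise significance level (default 0.05).
#' @return A `multiple_range` list: `means`, `comparisons` (data frame of
#'   pair, statistic, raw p, significance flag), `n_pairs`, `adjusted_alpha`.
#' @export
multiple_range_bonferroni <- function(groups, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (!is.list(groups) || length(groups) < 2L) {
    abort_input("at least 2 groups are required")
  }
  if (any(vapply(groups, length, 0L) < 2L)) {
    abort_input("every group needs >= 2 observations")
  }
  nm <- names(groups) %||% as.character(seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nm
  k <- length(groups)
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  adj <- alpha / m
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tt <- students_t(groups[[i1]], groups[[i2]])
    data.frame(group1 = nm[i1], group2 = nm[i2],
               statistic = tt$statistic, p_value = tt$p_value,
               significant = tt$p_value < adj, stringsAsFactors = FALSE)
  })
  structure(list(means = vapply(groups, mean, 0),
                 comparisons = do.call(rbind, rows),
                 n_pairs = m, alpha = alpha, adjusted_alpha = adj),
            class = "multiple_range")
}
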