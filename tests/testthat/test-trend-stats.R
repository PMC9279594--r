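test_that("linear fit matches the independent normal-equations solution", {
  t4 <- c(0, 1, 2, 3)
  exact <- fit_linear(t4, 2 * t4 + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$residual_variance, 0)
  expect_equal(exact$r_squared, 1)
  flat <- fit_linear(t4, rep(5, 4))
  expect_equal(flat$slope, 0)
  set.seed(3)
  y <- 0.7 * t4 - 2 + rnorm(4)
  fit <- fit_linear(t4, y)
  oracle <- oracle_ols(t4, y)
  expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-12)
  expect_error(fit_linear(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(fit_linear(1, 2), "2")
})

test_that("slope-comparison ANCOVA is symmetric and handles exact ties", {
  set.seed(4)
  a <- list(times = 0:5, values = 1 + 0.5 * (0:5) + rnorm(6, sd = 0.3))
  b <- list(times = 0:5, values = 2 + 0.5 * (0:5) + rnorm(6, sd = 0.3))
  ab <- compare_timeseries_ancova(a, b)
  ba <- compare_timeseries_ancova(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$delta_slope, -ba$delta_slope)
  expect_identical(ab$dof, 6L + 6L - 4L)
  expect_true(ab$p_value >= 0 && ab$p_value <= 1)
  # identical exact series: delta 0, p = 1 by convention
  exact <- list(times = 0:3, values = 2 * (0:3) + 1)
  tie <- compare_timeseries_ancova(exact, exact)
  expect_equal(tie$delta_slope, 0)
  expect_equal(tie$p_value, 1)
})

test_that("ANCOVA agrees with the lm interaction-term test", {
  # independent cross-check: the classical slope-equality t-test equals the
  # group:time interaction t-test of a joint separate-variances-free model
  set.seed(12)
  for (i in 1:20) {
    ta <- 0:5; tb <- 0:4
    ya <- 1 + 0.4 * ta + rnorm(6, sd = 0.5)
    yb <- 2 + 0.9 * tb + rnorm(5, sd = 0.5)
    ours <- compare_timeseries_ancova(list(times = ta, values = ya),
                                      list(times = tb, values = yb))
    df <- data.frame(y = c(ya, yb), t = c(ta, tb),
                     g = rep(c("a", "b"), c(6, 5)))
    lmfit <- summary(lm(y ~ t * g, data = df))$coefficients
    expect_equal(abs(ours$test_statistic), abs(lmfit["t:gb", "t value"]),
                 tolerance = 1e-10)
    expect_equal(ours$p_value, lmfit["t:gb", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the hand step-up and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)
  # hand step-up: q_i = min_{j >= i} m p_(j) / j, here all 4 * 0.04 / 4 chain
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  for (i in 1:25) {
    p <- runif(40)
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-15))
    # independent hand step-up oracle on the sorted p-values
    ps <- sort(p); m <- length(p)
    hand <- pmin(rev(cummin(rev(m * ps / seq_len(m)))), 1)
    expect_equal(sort(q), hand, tolerance = 1e-12)
    # monotone in p; the step-up enforcement needs no second pass
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    qs <- sort(q)
    expect_equal(rev(cummin(rev(qs))), qs)
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
  }
  # fully tied adjusted vectors are fixed points of the whole adjustment
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  expect_equal(bh_fdr(bh_fdr(c(0.01, 0.02, 0.03, 0.04))), rep(0.04, 4))
})

test_that("one-way ANOVA matches manual sums of squares and t-squared", {
  groups <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8))
  out <- one_way_anova(groups)
  # brute-force sums of squares
  y <- unlist(groups); gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f_manual <- (ssb / 2) / (ssw / 6)
  expect_equal(out$F, f_manual, tolerance = 1e-12)
  expect_equal(out$p_value, pf(f_manual, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(one_way_anova(same)$F, 0)
  expect_equal(one_way_anova(same)$p_value, 1)
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(6) + 0.5
    f2 <- one_way_anova(list(a, b))$F
    t2 <- students_t(a, b)$statistic^2
    expect_equal(f2, t2, tolerance = 1e-10)
  }
})

test_that("pooled t-test handles symmetry and degenerate samples", {
  a <- c(1.1, 2.3, 3.1, 4.0)
  expect_equal(students_t(a, a)$statistic, 0)
  expect_equal(students_t(a, a)$p_value, 1)
  b <- a + 2
  expect_equal(students_t(a, b)$statistic, -students_t(b, a)$statistic)
  expect_equal(students_t(a, b)$p_value, students_t(b, a)$p_value)
  # textbook pooled-variance instance, hand computed
  x <- c(10, 12, 14); y <- c(9, 11, 13, 15)
  sp2 <- (sum((x - 12)^2) + sum((y - 12)^2)) / (3 + 4 - 2)
  t_manual <- (12 - 12) / sqrt(sp2 * (1 / 3 + 1 / 4))
  expect_equal(students_t(x, y)$statistic, t_manual)
  const <- c(2, 2, 2)
  expect_equal(students_t(const, const)$p_value, 1)
  expect_warning(deg <- students_t(const, const + 1), "zero pooled")
  expect_equal(deg$p_value, 0)
})

test_that("t and F statistics are invariant under positive affine transforms", {
  set.seed(14)
  a <- rnorm(6); b <- rnorm(7) + 1; c_ <- rnorm(5) - 1
  t0 <- students_t(a, b)$statistic
  f0 <- one_way_anova(list(a, b, c_))$F
  for (tr in list(c(2.5, 3), c(0.1, -7))) {
    expect_equal(students_t(tr[1] * a + tr[2], tr[1] * b + tr[2])$statistic,
                 t0, tolerance = 1e-10)
    expect_equal(one_way_anova(lapply(list(a, b, c_),
                                      function(g) tr[1] * g + tr[2]))$F,
                 f0, tolerance = 1e-10)
  }
})

test_that("Bonferroni multiple range flags only truly shifted groups", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  out <- multiple_range_bonferroni(same)
  expect_identical(out$n_pairs, 3L)
  expect_equal(out$adjusted_alpha, 0.05 / 3)
  expect_false(any(out$comparisons$significant))
  # one group shifted by ~10 pooled SDs: exactly its two pairs significant
  set.seed(21)
  base_sd <- 1
  g <- list(a = rnorm(8, 0, base_sd), b = rnorm(8, 0, base_sd),
            c = rnorm(8, 10 * base_sd, base_sd))
  shifted <- multiple_range_bonferroni(g)
  cmp <- shifted$comparisons
  involves_c <- cmp$group1 == "c" | cmp$group2 == "c"
  expect_true(all(cmp$significant[involves_c]))
  expect_false(any(cmp$significant[!involves_c]))
  expect_error(multiple_range_bonferroni(list(a = 1:3)), "2 groups")
})
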