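test_that("failed-status features are removed in every culture", {
  mat <- toy_matrix(list(
    C1 = list(A = c(2, 3, 4), B = c(5, 5, 5), C = c(9, 9, 9)),
    C2 = list(A = c(2, 3, 4), B = c(5, 5, 5), C = c(9, 9, 9))),
    status = "B")
  out <- filter_failed(mat)
  expect_setequal(unique(out$matrix$feature_id), c("A", "C"))
  expect_identical(out$report$n_removed_fail, 1L)
  expect_identical(out$report$n_kept, 2L)
  # no fails: identity
  clean <- toy_matrix(list(C1 = list(A = c(2, 3, 4))))
  expect_identical(filter_failed(clean)$matrix, clean)
  # all fail: empty result allowed
  allbad <- toy_matrix(list(C1 = list(A = c(1, 1, 1))), status = "A")
  expect_identical(filter_failed(allbad)$report$n_kept, 0L)
})

test_that("low-expression filter applies strict thresholds per culture", {
  mat <- toy_matrix(list(C1 = list(
    low_init = c(0.5, 3.0, 3.0),   # initial 0.5 < 1 -> removed
    low_sum  = c(1.0, 2.0, 1.9),   # sum 4.9 < 5 -> removed
    boundary = c(1.0, 2.0, 2.0),   # sum = 5, initial = 1 -> kept (strict)
    high     = c(10, 10, 10))))
  out <- filter_low_expression(mat)
  expect_setequal(unique(out$matrix$feature_id), c("boundary", "high"))
  expect_setequal(out$report$removed_low, c("low_init", "low_sum"))
  # failing in one culture removes the feature globally
  two <- toy_matrix(list(C1 = list(A = c(10, 10, 10)),
                         C2 = list(A = c(0.5, 10, 10))))
  expect_identical(nrow(filter_low_expression(two)$matrix), 0L)
  expect_error(filter_low_expression(mat, sum_threshold = -1), ">= 0")
})

test_that("filter order does not matter when no feature triggers both rules", {
  mat <- toy_matrix(list(C1 = list(
    failed = c(10, 10, 10), low = c(0.2, 0.2, 0.2), good = c(5, 6, 7))),
    status = "failed")
  a <- filter_low_expression(filter_failed(mat)$matrix)$matrix
  b <- filter_failed(filter_low_expression(mat)$matrix)$matrix
  expect_identical(a, b)
  expect_setequal(unique(a$feature_id), "good")
})

test_that("housekeeping normalization divides per time-point and culture", {
  mat <- toy_single_culture(list(A = c(2, 4, 8)), hk = c(1, 2, 4))
  out <- normalize_housekeeping(mat, "GAPDH")
  expect_equal(unlist(out[out$feature_id == "A", c("t0", "t1", "t2")],
                      use.names = FALSE), c(2, 2, 2))
  # the housekeeping gene maps to the all-ones series
  expect_equal(unlist(out[out$feature_id == "GAPDH", c("t0", "t1", "t2")],
                      use.names = FALSE), c(1, 1, 1))
  zero <- toy_single_culture(list(A = c(2, 4, 8)), hk = c(1, 0, 2))
  expect_error(normalize_housekeeping(zero, "GAPDH"), "t1")
  expect_error(normalize_housekeeping(mat, "ACTB"), "not found")
})

test_that("housekeeping anomalies are flagged against the series median", {
  mat <- toy_single_culture(list(A = c(2, 4, 8)), hk = c(100, 110, 900))
  flags <- flag_housekeeping_anomaly(mat, "GAPDH", fold_limit = 3)
  expect_identical(flags$timepoint, "t2")
  expect_equal(flags$ratio, 900 / 110)
  # constant series and infinite limit yield no flags
  flat <- toy_single_culture(list(A = c(2, 4, 8)), hk = c(100, 100, 100))
  expect_identical(nrow(flag_housekeeping_anomaly(flat, "GAPDH")), 0L)
  expect_identical(
    nrow(flag_housekeeping_anomaly(mat, "GAPDH", fold_limit = Inf)), 0L)
  # low outliers are flagged too
  lowmat <- toy_single_culture(list(A = c(2, 4, 8)), hk = c(100, 110, 20))
  expect_identical(flag_housekeeping_anomaly(lowmat, "GAPDH")$timepoint, "t2")
})

test_that("baseline normalization and log2 evolution behave as specified", {
  expect_equal(normalize_baseline(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(normalize_baseline(c(4, 2, 1)), c(1, 0.5, 0.25))
  expect_error(normalize_baseline(c(0, 1, 2)), "positive")
  expect_equal(normalize_baseline(c(0, 1, 2), pseudocount = 1),
               c(1, 2, 3))
  expect_equal(log2_evolution(c(1, 2, 4)), c(0, 1, 2))
  expect_equal(log2_evolution(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(log2_evolution(c(1, 0.5)), c(0, -1))
  expect_error(log2_evolution(c(1, 0)), "positive")
})

test_that("coefficient of variation is the sample SD over the mean", {
  expect_equal(coefficient_of_variation(c(3, 3, 3)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  s <- c(1.3, 4.2, 2.2)
  expect_equal(coefficient_of_variation(7 * s), coefficient_of_variation(s))
  expect_warning(cv0 <- coefficient_of_variation(c(-1, 1)), "zero-mean")
  expect_true(is.na(cv0))
})

test_that("trend classification is strict, thresholded, and antisymmetric", {
  expect_identical(classify_trend(c(0, 1, 2)), "up")
  expect_identical(classify_trend(c(0, -1, -2)), "down")
  expect_identical(classify_trend(c(0, 1, 0.5)), "none")
  expect_identical(classify_trend(c(0, 0.3, 0.6), min_step = 0.5), "none")
  expect_warning(short <- classify_trend(0), "fewer than 2")
  expect_identical(short, "none")
  # time reversal swaps up and down; flat series map to none either way
  set.seed(8)
  for (i in 1:50) {
    s <- cumsum(rnorm(4))
    fwd <- classify_trend(s)
    rev_call <- classify_trend(rev(s))
    expect_identical(rev_call,
                     switch(fwd, up = "down", down = "up", none = "none"))
  }
})

test_that("consensus requires full agreement on a real direction", {
  expect_identical(consensus_across_cultures(
    c(C1 = "up", C2 = "up", C3 = "up", C4 = "up")), "up")
  expect_identical(consensus_across_cultures(
    c(C1 = "up", C2 = "up", C3 = "down", C4 = "up")), "none")
  expect_identical(consensus_across_cultures(
    c(C1 = "up", C2 = "none", C3 = "up", C4 = "up")), "none")
  expect_error(consensus_across_cultures(c(C1 = "up"), required = c("C1", "C2")),
               "C2")
})

test_that("the pipeline recovers noiseless planted truth exactly", {
  cfg <- fpkm_sim_config(n_features = 200, n_cultures = 4, noise_cv = 0,
                         frac_up = 0.1, frac_down = 0.1, seed = 23)
  ds <- gen_fpkm_dataset(cfg)
  res <- run_fpkm_pipeline(ds$matrix)
  calls <- res$trends$consensus[match(ds$truth$feature_id,
                                      res$trends$feature_id)]
  truth <- ifelse(ds$truth$direction == "flat", "none", ds$truth$direction)
  expect_identical(unname(calls), truth)
  # count conservation through the filter stages
  rep <- res$report
  expect_identical(rep$n_input,
                   rep$n_removed_fail + rep$n_removed_low + rep$n_kept)
})

test_that("trend calls are invariant under positive scaling of raw series", {
  cfg <- fpkm_sim_config(n_features = 40, noise_cv = 0.1, seed = 77)
  ds <- gen_fpkm_dataset(cfg)
  scaled <- ds$matrix
  vc <- grep("^t[0-9]+$", names(scaled))
  scaled[vc] <- scaled[vc] * 13.7
  a <- run_fpkm_pipeline(ds$matrix)
  b <- run_fpkm_pipeline(scaled)
  expect_identical(a$trends, b$trends)
})

test_that("anomalous housekeeping time-points are excluded from trends", {
  # without the anomaly flag the inflated hk at t2 would drag every gene down
  mat <- toy_single_culture(
    list(A = c(10, 20, 40), B = c(40, 20, 10)),
    hk = c(100, 100, 1000))
  res <- run_fpkm_pipeline(mat, fold_limit = 3)
  expect_identical(res$anomalies$timepoint, "t2")
  expect_identical(res$trends$C1[res$trends$feature_id == "A"], "up")
  expect_identical(res$trends$C1[res$trends$feature_id == "B"], "down")
  # with flagging disabled the hk artifact corrupts the calls
  res2 <- run_fpkm_pipeline(mat, fold_limit = Inf)
  expect_identical(res2$trends$C1[res2$trends$feature_id == "A"], "none")
})

test_that("empty and degenerate matrices give empty outputs with zero counts", {
  empty <- toy_matrix(list(C1 = list(A = c(1, 1, 1))))[0, ]
  res <- run_fpkm_pipeline(empty)
  expect_identical(nrow(res$trends), 0L)
  expect_identical(res$report$n_input, 0L)
})
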