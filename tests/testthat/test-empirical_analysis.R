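test_that("forward pairs enumerate every ordered scan combination", {
  s2 <- nodule_series("a", c(0, 90), c(100, 105))
  expect_equal(nrow(forward_pairs(s2)), 1)
  s4 <- nodule_series("b", c(0, 90, 200, 330), c(100, 105, 98, 102))
  p4 <- forward_pairs(s4)
  expect_equal(nrow(p4), 6)
  expect_equal(p4[, c("scan_index_1", "scan_index_2")],
               data.frame(scan_index_1 = c(1, 1, 1, 2, 2, 3),
                          scan_index_2 = c(2, 3, 4, 3, 4, 4)),
               ignore_attr = TRUE)
  s8 <- nodule_series("c", seq(0, 700, by = 100), runif(8, 90, 110))
  expect_equal(nrow(forward_pairs(s8)), 28)
  expect_true(all(forward_pairs(s8)$delta_t > 0))
  dup <- nodule_series("d", c(0, 0, 90), c(100, 101, 102))
  expect_error(forward_pairs(dup), "duplicate scan dates")
})

test_that("pair counts match the closed form sum of C(n,2) over a cohort", {
  cohort <- simulate_cohort(cohort_config(n_nodules = 40, seed = 8))
  n_i <- vapply(cohort, length, integer(1))
  res <- empirical_fpr(cohort)
  expect_equal(res$total_pairs, sum(choose(n_i, 2)))
  # brute-force oracle: count index pairs by double loop
  brute <- sum(vapply(n_i, function(n) {
    cnt <- 0L
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) cnt <- cnt + 1L
    cnt
  }, integer(1)))
  expect_equal(res$total_pairs, brute)
  # the published scan-count mix gives 573 combinatorial pairs
  mix <- rep(3:8, times = c(44, 26, 9, 6, 1, 3))
  expect_equal(sum(choose(mix, 2)), 573)
})

test_that("empirical FPR classifies pairs by the strict k-window", {
  const <- lapply(1:5, function(i) {
    nodule_series(paste0("n", i), c(0, 100, 250), c(50, 50, 50) * i)
  })
  expect_equal(empirical_fpr(const)$fraction, 0)
  one <- list(nodule_series("g", c(0, 30), c(100, 110)))
  res <- empirical_fpr(one)
  expect_equal(res$fraction, 1)
  expect_equal(res$pairs$k, log(1.1) / 30)
  expect_error(empirical_fpr(list()), "empty")
})

test_that("empirical FPR on a large stable cohort matches the analytic rate", {
  # fixed 90-day schedule so the analytic FPR is a single number
  set.seed(314)
  n <- 5200  # 2 scans each -> >1e4 measurement draws, 5200 pairs
  cohort <- lapply(seq_len(n), function(i) {
    v <- runif(1, 3, 1300)
    nodule_series(paste0("s", i), c(0, 90),
                  simulate_measurement(v, 0.057, 2))
  })
  res <- empirical_fpr(cohort)
  p <- stable_fpr(90, 0.057)
  se <- sqrt(p * (1 - p) / res$total_pairs)
  expect_lt(abs(res$fraction - p), 3 * se)
})

test_that("stability filter applies the 25% rule and is scale invariant", {
  expect_true(stability_filter(c(100, 100, 100)))
  expect_true(stability_filter(c(100, 130)))   # 13.04% off the mean
  expect_false(stability_filter(c(100, 200)))  # 33.3% off the mean
  set.seed(5)
  for (i in 1:10) {
    v <- runif(4, 50, 150)
    expect_identical(stability_filter(v), stability_filter(v * 1000))
  }
  expect_false(stability_filter(c(100, 130), reference = "first"))
  expect_true(stability_filter(c(100, 120), reference = "first"))
})

test_that("simulated interval sweep re-dates pairs and tracks the analytic shape", {
  noiseless <- lapply(1:10, function(i) {
    nodule_series(paste0("n", i), c(0, 1), c(i * 10, i * 10))
  })
  sw <- simulated_interval_sweep(noiseless, c(30, 90, 180))
  expect_equal(sw$fpr, c(0, 0, 0))

  one <- list(nodule_series("x", c(0, 1), c(100, 105)))
  sw1 <- simulated_interval_sweep(one, c(30, 180))
  # k = ln(1.05)/dt: 0.001626 at 30 d (below k_low) and 0.000271 at 180 d
  expect_equal(log(1.05) / c(30, 180), c(0.001626, 0.000271),
               tolerance = 1e-3)
  expect_equal(sw1$fpr, c(0, 0))

  set.seed(99)
  pairs <- lapply(1:4000, function(i) {
    v <- runif(1, 3, 1300)
    nodule_series(paste0("p", i), c(0, 1), simulate_measurement(v, 0.054, 2))
  })
  sw2 <- simulated_interval_sweep(pairs, seq(30, 180, 30))
  expect_true(all(diff(sw2$fpr) <= 0))
  p_pred <- stable_fpr(seq(30, 180, 30), 0.054)
  expect_lt(max(abs(sw2$fpr - p_pred)), 3 * sqrt(max(p_pred) / 4000))

  expect_error(simulated_interval_sweep(
    list(nodule_series("y", c(0, 10, 20), c(1, 1, 1))), 30), "exactly 2")
})
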