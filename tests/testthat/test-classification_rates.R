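test_that("decision window maps doubling-time limits into k-space", {
  w <- malignant_window(30, 400)
  expect_equal(w$k_low, 0.00173, tolerance = 2e-3)
  expect_equal(w$k_high, 0.0231, tolerance = 1e-3)
  expect_equal(w$k_low * w$dt_max, log(2))
  expect_equal(w$k_high * w$dt_min, log(2))
  w2 <- malignant_window(100, 200)
  expect_equal(w2$k_high / w2$k_low, 2)
  w3 <- malignant_window(50, 500)
  expect_equal(c(w3$k_low, w3$k_high), c(0.0013863, 0.0138629),
               tolerance = 1e-4)
  expect_error(malignant_window(400, 30))
  expect_error(malignant_window(0, 30))
})

test_that("stable-nodule FPR matches the normal-CDF oracle", {
  expect_equal(stable_fpr(c(10, 81, 400), 0), c(0, 0, 0))
  expect_equal(stable_fpr(81, 0.057), 0.04082, tolerance = 1e-3)
  expect_equal(stable_fpr(30, 0.057), 0.25949, tolerance = 1e-3)
  # oracle: direct pnorm difference at arbitrary settings
  w <- malignant_window()
  for (dt in c(15, 60, 120, 365)) {
    sk <- 0.057 * sqrt(2) / dt
    expect_equal(stable_fpr(dt, 0.057),
                 pnorm(w$k_high / sk) - pnorm(w$k_low / sk))
  }
  expect_error(stable_fpr(0, 0.057))
})

test_that("FPR decreases with interval in the one-sided regime and stays in [0,1]", {
  w <- malignant_window()
  grid <- seq(ceiling(0.057 * sqrt(2) / w$k_high), 1000, by = 7)
  f <- stable_fpr(grid, 0.057, w)
  expect_true(all(f >= 0 & f <= 1))
  one_sided <- grid >= 0.057 * sqrt(2) / w$k_low
  expect_true(all(diff(f[one_sided]) <= 0))
  expect_lt(stable_fpr(5000, 0.057, w), 1e-10)
})

test_that("pure TPR is the lognormal mass on the window", {
  m <- lognormal_growth_model(log(0.015), 0.83)
  expect_equal(tpr_pure(m, malignant_window(1e-6, 1e9)), 1, tolerance = 1e-6)
  # near-point mass at the geometric midpoint of the window
  w <- malignant_window()
  mid <- sqrt(w$k_low * w$k_high)
  expect_equal(tpr_pure(lognormal_growth_model(log(mid), 1e-6), w), 1)
  expect_equal(tpr_pure(m, w), 0.69398, tolerance = 1e-4)
})

test_that("blurred TPR equals pure TPR for noiseless measurement and approaches it for long intervals", {
  m <- lognormal_growth_model()
  w <- malignant_window()
  expect_identical(tpr_blurred(m, 0, 81, w), tpr_pure(m, w))
  # vanishing-kernel limit
  dt_big <- 10 * 0.057 * sqrt(2) / w$k_low
  expect_equal(tpr_blurred(m, 0.057, dt_big, w), tpr_pure(m, w),
               tolerance = 1e-3)
  # monotone approach over decades of delta_t
  vals <- vapply(c(1e2, 1e3, 1e4), function(dt) tpr_blurred(m, 0.057, dt, w),
                 numeric(1))
  gaps <- abs(vals - tpr_pure(m, w))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-4)
  # short-interval blurring moves mass out of the window
  expect_lt(tpr_blurred(m, 0.057, 30, w), tpr_pure(m, w))
})

test_that("blurred density is a proper density and matches pure density when unblurred", {
  m <- lognormal_growth_model()
  mass <- integrate(function(k) blurred_density(k, m, 0.057, 30),
                    lower = -0.05, upper = 2, rel.tol = 1e-7)$value
  expect_equal(mass, 1, tolerance = 1e-6)
  k <- c(0.001, 0.01, 0.05)
  expect_equal(blurred_density(k, m, 0, 81), dlnorm(k, m$mu_log, m$sigma_log))
})

test_that("optimal interval is the exact integer argmin of the FPR threshold crossing", {
  expect_equal(optimal_interval(0.057, 0.05), 77)
  expect_lt(stable_fpr(77, 0.057), 0.05)
  expect_gte(stable_fpr(76, 0.057), 0.05)
  expect_warning(opt <- optimal_interval(0.057, 0.999), "degenerate")
  expect_equal(opt, 1)
  # sigma_k scale law: doubling a doubles the required interval (+/- 1 day)
  expect_lte(abs(optimal_interval(0.114, 0.05) - 2 * 77), 1)
  # brute-force oracle agreement at other settings
  for (a in c(0.03, 0.0597, 0.08)) {
    fpr <- stable_fpr(1:2000, a)
    expect_equal(optimal_interval(a, 0.05), which(fpr < 0.05)[1])
  }
})

test_that("lognormal histogram fit recovers parameters and amplitude", {
  centers <- exp(seq(log(0.001), log(0.1), length.out = 20))
  dens <- dlnorm(centers, log(0.015), 0.83)
  fit <- fit_lognormal_to_histogram(centers, dens)
  expect_equal(fit$mu_log, log(0.015), tolerance = 1e-6)
  expect_equal(fit$sigma_log, 0.83, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  # scaling counts scales only the amplitude
  fit50 <- fit_lognormal_to_histogram(centers, 50 * dens)
  expect_equal(fit50$mu_log, fit$mu_log, tolerance = 1e-6)
  expect_equal(fit50$sigma_log, fit$sigma_log, tolerance = 1e-6)
  expect_equal(fit50$amplitude, 50, tolerance = 1e-4)
  expect_error(fit_lognormal_to_histogram(centers[1:2], dens[1:2]), "3")
  expect_error(fit_lognormal_to_histogram(c(0.001, 0.01, 0.1), c(0, 5, 0)),
               "degenerate")
})

test_that("histogram fit recovers the malignant k-distribution from sampled data", {
  set.seed(9)
  k <- rlnorm(120, log(0.015), 0.83)
  h <- hist(k, breaks = 12, plot = FALSE)
  fit <- fit_lognormal_to_histogram(h$mids, h$counts)
  expect_lt(abs(fit$mu_log - log(0.015)), 0.15)
  expect_lt(abs(fit$sigma_log - 0.83), 0.15)
})

test_that("rate curve is consistent with direct calls and monotone in FPR", {
  m <- lognormal_growth_model()
  w <- malignant_window()
  rc0 <- rate_curve(0, m, w, c(30, 60))
  expect_equal(rc0$fpr, c(0, 0))
  expect_equal(rc0$tpr, rep(tpr_pure(m, w), 2))
  rc1 <- rate_curve(0.057, m, w, 81)
  expect_equal(rc1$fpr, stable_fpr(81, 0.057, w))
  expect_equal(rc1$tpr, tpr_blurred(m, 0.057, 81, w))
  rc <- rate_curve(0.057, m, w, seq(30, 180, 10))
  expect_true(all(diff(rc$fpr) < 0))
})
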