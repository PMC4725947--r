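test_that("bi-exponential model function evaluates correctly", {
  expect_equal(model_decay(decay_params(0.5, 0.4, 0.5, 2.5), 0), 1.0)
  expect_equal(model_decay(decay_params(1, 1.0, 0, 2.0), 1.0), exp(-1))
  expect_equal(model_decay(decay_params(2, 0.4, 1, 2.5), 0.8),
               2 * exp(-2) + exp(-0.32))
  # strictly decreasing in t
  t <- seq(0, 5, by = 0.1)
  v <- model_decay(decay_params(1, 0.4, 1, 2.5), t)
  expect_true(all(diff(v) < 0))
  expect_error(decay_params(1, -0.4, 1, 2.5), "positive")
  expect_error(decay_params(0, 0.4, 0, 2.5), "amplitudes")
  expect_error(model_decay(decay_params(1, 1, 1, 2), -1), ">= 0")
})

test_that("parameters are canonically ordered with tau1 <= tau2", {
  p <- decay_params(a1 = 1, tau1 = 2.5, a2 = 3, tau2 = 0.4)
  expect_equal(p$tau1, 0.4)
  expect_equal(p$a1, 3)
  expect_equal(p$tau2, 2.5)
  expect_equal(p$a2, 1)
})

test_that("average lifetime matches both weighting conventions", {
  expect_equal(average_lifetime(decay_params(1, 0.4, 0, 2.5)), 0.4)
  expect_equal(average_lifetime(decay_params(1, 0.4, 0, 2.5), "intensity"), 0.4)
  expect_equal(average_lifetime(decay_params(1, 1, 1, 3)), 2.0)
  expect_equal(average_lifetime(decay_params(2, 0.4, 1, 2.5)), 1.1)
  p <- decay_params(2, 0.4, 1, 2.5)
  expect_equal(average_lifetime(p, "intensity"),
               (2 * 0.4^2 + 1 * 2.5^2) / (2 * 0.4 + 1 * 2.5))
  # both modes lie in [tau1, tau2]
  for (mode in c("amplitude", "intensity")) {
    av <- average_lifetime(p, mode)
    expect_gte(av, p$tau1)
    expect_lte(av, p$tau2)
  }
})

test_that("average lifetime is monotone in the lifetimes", {
  # amplitude weighting is strictly increasing in either lifetime; intensity
  # weighting is strictly increasing in tau2 but can genuinely decrease with
  # tau1 when tau2 > 2 * tau1 and a1 is small (d tau_I / d tau1 =
  # a1*tau1^2 + a2*tau2*(2*tau1 - tau2), which then goes negative)
  set.seed(11)
  for (i in 1:25) {
    a1 <- runif(1, 0.1, 3); a2 <- runif(1, 0.1, 3)
    t1 <- runif(1, 0.1, 1); t2 <- runif(1, 1.5, 4)
    base_a <- average_lifetime(decay_params(a1, t1, a2, t2), "amplitude")
    expect_gt(average_lifetime(decay_params(a1, t1 * 1.05, a2, t2), "amplitude"),
              base_a)
    expect_gt(average_lifetime(decay_params(a1, t1, a2, t2 * 1.05), "amplitude"),
              base_a)
    base_i <- average_lifetime(decay_params(a1, t1, a2, t2), "intensity")
    expect_gt(average_lifetime(decay_params(a1, t1, a2, t2 * 1.05), "intensity"),
              base_i)
  }
  expect_lt(average_lifetime(decay_params(0.1, 0.4, 1, 2.5), "intensity") -
              average_lifetime(decay_params(0.1, 0.3, 1, 2.5), "intensity"), 0)
})

test_that("Gaussian IRF is normalised with the requested width", {
  expect_equal(sum(irf0$profile), 1, tolerance = 1e-12)
  # >= 99% of mass within center +/- 0.4 ns (Gaussian tail bound:
  # 0.4 ns is 5.2 sigma for fwhm 0.181)
  win <- abs(ax0$times - irf0$center) <= 0.4
  expect_gte(sum(irf0$profile[win]), 0.99)
  # half-maximum points separated by fwhm in the fine-bin limit
  fine <- time_axis(n_bins = 4096, bin_width = 12195 / 4096)
  irf_f <- gaussian_irf(fine, fwhm = 0.181, center = 2)
  prof <- irf_f$profile / max(irf_f$profile)
  above <- range(fine$times[prof >= 0.5])
  expect_equal(diff(above), 0.181, tolerance = 0.02)
  expect_error(gaussian_irf(ax0, fwhm = -1), "fwhm")
  expect_error(gaussian_irf(ax0, center = 100), "center")
})

test_that("periodic convolution: delta IRF reproduces the wrapped decay", {
  delta <- irf_model(c(1, rep(0, ax0$n_bins - 1)), ax0)
  p <- decay_params(0.6, 0.4, 0.4, 2.5)
  got <- convolve_periodic(p, delta, ax0, 1e5)
  # independent wrap-around: explicit pulse-train sum
  w <- 0
  for (k in 0:300)
    w <- w + model_decay(p, ax0$times + k * ax0$period)
  expect_equal(got, w * (1e5 / sum(w)), tolerance = 1e-9)
})

test_that("periodic convolution conserves counts under any unit-sum IRF", {
  set.seed(3)
  for (i in 1:5) {
    prof <- runif(ax0$n_bins)
    irf <- irf_model(prof, ax0)
    p <- decay_params(runif(1, 0.2, 1), runif(1, 0.2, 0.8),
                      runif(1, 0.2, 1), runif(1, 1.5, 3.5))
    mu <- convolve_periodic(p, irf, ax0, 12345)
    expect_equal(sum(mu), 12345, tolerance = 1e-6)
    expect_true(all(mu >= 0))
  }
})

test_that("fft convolution agrees with the O(n^2) direct-sum oracle", {
  for (n in c(100L, 256L)) {
    axis <- time_axis(n_bins = n, bin_width = 12195 / n)
    irf <- gaussian_irf(axis, 0.181, 0.6)
    p <- decay_params(0.6, 0.4, 0.4, 2.5, background = 3)
    got <- convolve_periodic(p, irf, axis, 1e6)
    want <- brute_force_expectation(p, irf, axis, 1e6)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("narrow-IRF limit converges to the wrapped pure decay", {
  narrow <- gaussian_irf(ax0, fwhm = ax0$dt / 10, center = ax0$times[1])
  p <- decay_params(0.6, 0.4, 0.4, 2.5)
  got <- convolve_periodic(p, narrow, ax0, 1)
  w <- 0
  for (k in 0:300) w <- w + model_decay(p, ax0$times + k * ax0$period)
  expect_equal(got, w / sum(w), tolerance = 1e-6)
})

test_that("axis mismatch and bad inputs are rejected", {
  other <- time_axis(n_bins = 128, bin_width = 47.6)
  expect_error(convolve_periodic(nadh_truth, irf0, other, 1), "axes differ")
  expect_error(convolve_periodic(nadh_truth, irf0, ax0, 0), "total_counts")
  expect_error(time_axis(n_bins = 512, bin_width = 47.6), "period")
  expect_error(irf_model(rep(-1, ax0$n_bins), ax0), "non-negative")
})

test_that("IRF CSV exchange round-trips", {
  path <- tempfile(fileext = ".csv")
  write_irf_csv(irf0, path)
  back <- read_irf_csv(path, ax0)
  expect_equal(back$profile, irf0$profile, tolerance = 1e-9)
  expect_error(read_irf_csv(path, time_axis(128, 47.6)), "does not match")
})
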