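test_that("initial parameter estimates are usable", {
  # noise-free single exponential, tau = 2.0
  p1 <- decay_params(1, 2.0, 1e-12, 2.0)
  mu <- convolve_periodic(p1, irf0, ax0, 1e6)
  init <- estimate_initial_params(decay_histogram(mu, ax0))
  expect_equal(init$tau2, 2.0, tolerance = 0.1)
  expect_error(estimate_initial_params(decay_histogram(rep(0, 256), ax0)),
               "insufficient data")
  # simulated bi-exponential: tail estimate lands in a sane window
  h <- simulate_histogram(nadh_truth, 1e5, ax0, irf0, seed = 7)
  init2 <- estimate_initial_params(h)
  expect_gte(init2$tau2, 1.5)
  expect_lte(init2$tau2, 3.5)
})

test_that("noise-free fits round-trip the forward model to 0.1%", {
  truth <- decay_params(0.6, 0.4, 0.4, 2.5, background = 0, shift = 0)
  mu <- convolve_periodic(truth, irf0, ax0, 1e6)
  fit <- fit_decay(decay_histogram(mu, ax0), irf0)
  expect_true(fit$converged)
  expect_equal(fit$params$tau1, 0.4, tolerance = 1e-3)
  expect_equal(fit$params$tau2, 2.5, tolerance = 1e-3)
  expect_equal(fit$free_bound_ratio, 1.5, tolerance = 1e-3)
})

test_that("Poisson-noise parameter recovery meets photon-budget bounds", {
  run_mc <- function(n_photons, n_rep, seed) {
    set.seed(seed)
    t(replicate(n_rep, {
      h <- simulate_histogram(nadh_truth, n_photons, ax0, irf0)
      f <- fit_decay(h, irf0)
      c(tau1 = f$params$tau1, tau2 = f$params$tau2,
        ratio = f$free_bound_ratio, chi2 = f$chi2_reduced,
        conv = f$converged)
    }))
  }
  relerr <- function(x, truth) abs(x / truth - 1)
  # 1e5 photons: median |relative error| of tau1, tau2, a1/a2 <= 10%
  r5 <- run_mc(1e5, 100, 101)
  expect_lte(median(relerr(r5[, "tau1"], 0.4)), 0.10)
  expect_lte(median(relerr(r5[, "tau2"], 2.5)), 0.10)
  expect_lte(median(relerr(r5[, "ratio"], 2.0)), 0.10)
  # 1e6 photons: <= 3%, chi2 near 1, individual errors within 5%
  r6 <- run_mc(1e6, 100, 102)
  expect_lte(median(relerr(r6[, "tau1"], 0.4)), 0.03)
  expect_lte(median(relerr(r6[, "tau2"], 2.5)), 0.03)
  expect_lte(median(relerr(r6[, "ratio"], 2.0)), 0.03)
  expect_gte(mean(r6[, "chi2"]), 0.8)
  expect_lte(mean(r6[, "chi2"]), 1.2)
  expect_true(all(r6[, "conv"] == 1))
})

test_that("fit output is canonically ordered and flags poor separation", {
  set.seed(5)
  for (i in 1:5) {
    h <- simulate_histogram(nadh_truth, 2e5, ax0, irf0)
    f <- fit_decay(h, irf0)
    expect_lte(f$params$tau1, f$params$tau2)
    expect_false(f$poorly_separated)
  }
  # nearly equal lifetimes get flagged (noise-free, so the fit is exact)
  close_truth <- decay_params(0.5, 1.7, 0.5, 2.0, background = 1)
  mu <- convolve_periodic(close_truth, irf0, ax0, 1e6)
  f <- fit_decay(decay_histogram(mu, ax0), irf0)
  expect_true(f$poorly_separated)
  expect_true(is.finite(f$free_bound_ratio))
})

test_that("integer-bin shifts of histogram and IRF leave the fit invariant", {
  h <- simulate_histogram(nadh_truth, 5e5, ax0, irf0, seed = 21)
  init <- decay_params(1000, 0.5, 500, 2.2, background = 1, shift = 0)
  f0 <- fit_decay(h, irf0, init = init)
  rot <- function(x, k) c(x[(length(x) - k + 1):length(x)], x[1:(length(x) - k)])
  k <- 17L
  h2 <- decay_histogram(rot(h$counts, k), ax0)
  irf2 <- irf_model(rot(irf0$profile, k), ax0)
  f2 <- fit_decay(h2, irf2, init = init)
  expect_equal(f2$params$tau1, f0$params$tau1, tolerance = 1e-6)
  expect_equal(f2$params$tau2, f0$params$tau2, tolerance = 1e-6)
  expect_equal(f2$free_bound_ratio, f0$free_bound_ratio, tolerance = 1e-6)
})

test_that("pure-background histograms are flagged, not silently reported", {
  set.seed(33)
  h <- decay_histogram(rpois(256, 5), ax0)
  f <- fit_decay(h, irf0)
  # either non-convergence or decay amplitudes at the noise floor
  decay_total <- sum(f$fitted) - f$params$background * 256
  expect_true(!f$converged || decay_total < 5 * sqrt(sum(h$counts)))
})

test_that("reduced chi-square follows its definition and calibration", {
  mu <- convolve_periodic(nadh_truth, irf0, ax0, 1e5)
  expect_equal(reduced_chi_square(mu, mu, 6), 0)
  expect_error(reduced_chi_square(mu, mu, 256), "degrees of freedom")
  expect_error(reduced_chi_square(mu[1:10], mu, 2), "equal length")
  # bins with obs = 0 are excluded and the result stays finite
  obs <- c(rep(0, 50), rpois(206, 50))
  expect_true(is.finite(reduced_chi_square(obs, c(rep(0, 50), rep(50, 206)), 6)))
  # Monte-Carlo calibration against the true model
  set.seed(12)
  chis <- replicate(500, reduced_chi_square(rpois(length(mu), mu), mu, 6))
  expect_equal(mean(chis), 1.0, tolerance = 0.15)
})

test_that("runs test detects structure and is calibrated under the null", {
  expect_lt(residual_runs_test(rep(c(1, -1), 50)), 0.01)
  expect_lt(residual_runs_test(rep(1, 30)), 0.001)
  expect_error(residual_runs_test(c(1, -1)), "at least 20")
  set.seed(8)
  ps <- replicate(1000, residual_runs_test(sample(c(-1, 1), 200, replace = TRUE)))
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.065)
})

test_that("flim_fit methods are coherent", {
  h <- simulate_histogram(nadh_truth, 2e5, ax0, irf0, seed = 4)
  f <- fit_decay(h, irf0)
  expect_named(coef(f), c("a1", "tau1", "a2", "tau2", "background", "shift"))
  expect_equal(fitted(f), predict(f))
  expect_equal(residuals(f, "raw"), h$counts - fitted(f))
  expect_equal(residuals(f),
               (h$counts - fitted(f)) / sqrt(pmax(h$counts, 1)))
  # predict with a photon budget rescales the decay part
  mu2 <- predict(f, total_counts = 1e4)
  expect_equal(sum(mu2 - f$params$background), 1e4, tolerance = 1e-6)
  s <- summary(f)
  expect_s3_class(s, "summary.flim_fit")
  expect_gte(s$tau_avg_intensity, s$tau_avg_amplitude)
  sim <- simulate(f, seed = 1)
  expect_equal(length(sim), 256)
  expect_true(all(sim >= 0 & sim == round(sim)))
  expect_output(print(f), "bi-exponential")
})
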