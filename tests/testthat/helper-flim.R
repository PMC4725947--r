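# shared fixtures: default 82 MHz axis, 0.181 ns Gaussian IRF, NADH-like truth
ax0 <- time_axis()
irf0 <- gaussian_irf(ax0)
nadh_truth <- decay_params(a1 = 2/3, tau1 = 0.4, a2 = 1/3, tau2 = 2.5,
                           background = 2)

# Independent O(n^2) oracle for the periodic forward model: wrap-around by
# explicit summation over past pulses, circular convolution by double loop.
brute_force_expectation <- function(params, irf, axis, total_counts) {
  n <- axis$n_bins
  d <- numeric(n)
  for (k in 0:300) {
    d <- d + params$a1 * exp(-(axis$times + k * axis$period) / params$tau1) +
      params$a2 * exp(-(axis$times + k * axis$period) / params$tau2)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i] <- out[i] + d[j] * irf$profile[((i - j) %% n) + 1]
    }
  }
  out * (total_counts / sum(out)) + params$background
}

# uniform-truth FLIM stack over a phantom, small enough for test runtime
small_phantom_stack <- function(seed, width = 64, height = 64,
                                photons = 1500, preset = NULL) {
  ph <- generate_phantom(seed, width = width, height = height, n_cells = 1)
  if (is.null(preset)) preset <- default_presets()[default_presets()$channel == "NADH" &
                                                     default_presets()$concentration == 0, ]
  simulate_flim_stack(ph, preset, photons, ax0, irf0, seed = seed + 1)
}
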