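test_that("adaptive binning grows kernels to the photon floor", {
  # uniform 100 photons/pixel: 3x3 = 900 < 1000, 5x5 = 2500 passes (interior)
  cube <- array(0L, c(20, 20, 4))
  cube[, , 1] <- 100L
  st <- flim_stack(cube, time_axis(4, 47.6), "NADH")
  b <- adaptive_bin(st, min_photons = 1000)
  interior <- b$kernel[5:16, 5:16]
  expect_true(all(interior == 5L))
  expect_true(all(b$total[5:16, 5:16] == 2500))
  # a single bright pixel needs no binning
  cube2 <- array(0L, c(20, 20, 4))
  cube2[10, 10, 1] <- 1e6
  b2 <- adaptive_bin(flim_stack(cube2, time_axis(4, 47.6), "NADH"), 1000)
  expect_equal(b2$kernel[10, 10], 1L)
  # an all-zero stack is entirely invalid
  b3 <- adaptive_bin(flim_stack(array(0L, c(20, 20, 4)),
                                time_axis(4, 47.6), "NADH"), 1000)
  expect_false(any(b3$valid))
  expect_error(adaptive_bin(st, min_photons = 0), "min_photons")
})

test_that("every valid binned pixel meets the photon floor (random phantoms)", {
  for (seed in 1:3) {
    set.seed(seed)
    cube <- array(rpois(24 * 24 * 8, lambda = runif(1, 5, 60)), c(24, 24, 8))
    st <- flim_stack(cube, time_axis(8, 47.6), "NADH")
    floor_n <- sample(500:3000, 1)
    b <- adaptive_bin(st, min_photons = floor_n)
    expect_true(all(b$total[b$valid] >= floor_n))
    # 1x1 kernels conserve the raw histogram total
    ones <- which(b$kernel == 1L, arr.ind = TRUE)
    if (nrow(ones)) {
      i <- ones[1, ]
      expect_equal(sum(binned_histogram(st, i[1], i[2], 1L)$counts),
                   b$raw_total[i[1], i[2]])
    }
    # binned histogram equals the clipped neighbourhood sum
    v <- which(b$valid, arr.ind = TRUE)[1, ]
    k <- b$kernel[v[1], v[2]]
    expect_equal(sum(binned_histogram(st, v[1], v[2], k)$counts),
                 b$total[v[1], v[2]])
  }
})

# one moderately sized pixel-wise fit, reused by several assertions below
sim48 <- small_phantom_stack(seed = 14, photons = 1500)
maps48 <- fit_image(sim48$stack, irf0, sim48$mask, min_photons = 10000)

test_that("pixel-wise fitting of a homogeneous phantom is spatially uniform", {
  vals <- maps48$tau_avg[maps48$valid]
  expect_gt(length(vals), 50)
  expect_lt(sd(vals) / mean(vals), 0.05)        # CV below 5%
  truth_avg <- average_lifetime(sim48$truth)
  expect_equal(mean(vals), truth_avg, tolerance = 0.05)
  # tau_avg within [tau1, tau2] wherever valid
  ok <- maps48$valid
  expect_true(all(maps48$tau_avg[ok] >= maps48$tau1[ok] - 1e-9))
  expect_true(all(maps48$tau_avg[ok] <= maps48$tau2[ok] + 1e-9))
  # valid pixels respect the photon floor
  expect_true(all(maps48$photons[ok] >= 10000))
  # the nucleus is excluded by the mask
  ph <- generate_phantom(14, 64, 64, 1)
  expect_false(any(maps48$valid[ph$nucleus]))
})

test_that("pooled-ROI and pixel-averaged estimates agree on homogeneous ROIs", {
  rois <- roi_mean_params(maps48, sim48$mask)
  expect_equal(nrow(rois), 1)
  expect_false(rois$flagged)
  idx <- which(sim48$mask$labels == 1, arr.ind = TRUE)
  pooled_counts <- rep(0, ax0$n_bins)
  for (i in seq_len(nrow(idx)))
    pooled_counts <- pooled_counts +
      binned_histogram(sim48$stack, idx[i, 1], idx[i, 2], 1L)$counts
  pooled_fit <- fit_decay(decay_histogram(pooled_counts, ax0), irf0)
  pooled_avg <- average_lifetime(pooled_fit$params)
  expect_equal(rois$tau_avg, pooled_avg, tolerance = 0.10)
})

test_that("ROI means distinguish two regions with different truths", {
  ph <- generate_phantom(31, width = 128, height = 64, n_cells = 2)
  pr <- default_presets()
  pa <- pr[pr$channel == "NADH" & pr$concentration == 0, ]
  pb <- pr[pr$channel == "NADH" & pr$concentration == 1000, ]
  simA <- simulate_flim_stack(ph, pa, 1500, ax0, irf0, seed = 41)
  simB <- simulate_flim_stack(ph, pb, 1500, ax0, irf0, seed = 42)
  cube <- simA$stack$counts
  sel2 <- ph$cells == 2
  for (b in seq_len(ax0$n_bins)) {
    pg <- cube[, , b]; pg[sel2] <- simB$stack$counts[, , b][sel2]
    cube[, , b] <- pg
  }
  st <- flim_stack(cube, ax0, "NADH")
  maps <- fit_image(st, irf0, ph$mask, min_photons = 10000)
  rois <- roi_mean_params(maps, ph$mask)
  expect_equal(nrow(rois), 2)
  expect_equal(rois$tau_avg[rois$roi == 1],
               average_lifetime(decay_params(pa$a1, pa$tau1, pa$a2, pa$tau2)),
               tolerance = 0.08)
  expect_equal(rois$tau_avg[rois$roi == 2],
               average_lifetime(decay_params(pb$a1, pb$tau1, pb$a2, pb$tau2)),
               tolerance = 0.08)
})

test_that("degenerate masks and fully invalid ROIs are handled explicitly", {
  cube <- array(1L, c(16, 16, 8))
  st <- flim_stack(cube, time_axis(8, 47.6), "NADH")
  expect_error(fit_image(st, gaussian_irf(time_axis(8, 47.6)),
                         roi_mask(matrix(0L, 16, 16))),
               "mask excludes")
  # ROI with no valid pixels is flagged, not dropped
  m <- maps48
  mask2 <- sim48$mask$labels
  mask2[1:3, 1:3] <- 2L   # background corner: never valid
  rois <- roi_mean_params(m, roi_mask(mask2))
  r2 <- rois[rois$roi == 2, ]
  expect_true(r2$flagged)
  expect_equal(r2$n_pixels, 0)
})

test_that("pseudocolour rendering is deterministic, clipped and black where invalid", {
  m <- maps48
  img <- render_lifetime_map(m, c(0.5, 2))
  expect_equal(dim(img), c(64, 64, 3))
  # invalid pixels are black
  inv <- !m$valid
  for (ch in 1:3) expect_true(all(img[, , ch][inv] == 0))
  # same range -> identical colours for identical values
  img2 <- render_lifetime_map(m, c(0.5, 2))
  expect_identical(img, img2)
  # all values at lo map to the first palette colour
  m2 <- m
  m2$tau_avg[m2$valid] <- 0.5
  img3 <- render_lifetime_map(m2, c(0.5, 2))
  first <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")[1]) / 255
  ok <- m2$valid
  for (ch in 1:3) expect_true(all(abs(img3[, , ch][ok] - first[ch]) < 1e-9))
  expect_error(render_lifetime_map(m, c(2, 0.5)), "lo < hi")
})
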