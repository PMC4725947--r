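#' FLIM photon-count stack
#'
#' A 3-D TCSPC image: integer photon counts indexed (row, column, time-bin),
#' with its time axis, fluorophore channel and free-form acquisition metadata.
#'
#' @param counts 3-D non-negative array `height x width x n_bins`.
#' @param axis A [time_axis()]; third array dimension must equal
#'   `axis$n_bins`.
#' @param channel `"NADH"` or `"FAD"`.
#' @param metadata Optional named list of acquisition descriptors.
#' @return An object of class `flim_stack`.
#' @export
flim_stack <- function(counts, axis, channel = c("NADH", "FAD"),
                       metadata = list()) {
  stopifnot(is_time_axis(axis))
  channel <- match.arg(channel)
  d <- dim(counts)
  if (length(d) != 3L)
    stop("counts must be a 3-D array (row, column, time-bin)", call. = FALSE)
  if (d[3] != axis$n_bins)
    stop("third dimension must equal axis$n_bins", call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and >= 0", call. = FALSE)
  structure(list(counts = counts, axis = axis, channel = channel,
                 height = d[1], width = d[2], metadata = metadata),
            class = "flim_stack")
}

#' @export
print.flim_stack <- function(x, ...) {
  cat(sprintf("FLIM stack: %d x %d px, %d time bins, channel %s, %.3g photons\n",
              x$height, x$width, x$axis$n_bins, x$channel, sum(x$counts)))
  invisible(x)
}

#' ROI label mask
#'
#' Integer label image: 0 = excluded (background / nuclei), `k > 0` = ROI
#' `k`. In the intended workflow ROIs cover the cytoplasm of one cell or a
#' group of cells, with nuclei excluded.
#'
#' @param labels Integer matrix of non-negative labels.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels) {
  if (!is.matrix(labels) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be a matrix of non-negative integers", call. = FALSE)
  structure(list(labels = matrix(as.integer(labels), nrow(labels))),
            class = "roi_mask")
}

# summed-area table with a leading zero row/column
integral_image <- function(m) {
  s <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed after second apply
  s <- t(s)
  rbind(0, cbind(0, s))
}

# sum of m over rows r1..r2, cols c1..c2 via the integral image
window_sum <- function(ii, r1, r2, c1, c2) {
  ii[r2 + 1, c2 + 1] - ii[r1, c2 + 1] - ii[r2 + 1, c1] + ii[r1, c1]
}

#' Adaptive spatial binning to a photon-count floor
#'
#' For every pixel, grows a centred square neighbourhood through kernel sizes
#' 1, 3, 5, ..., `max_kernel` (clipped at image borders, no padding) until the
#' summed photon count reaches `min_photons`. Pixels that never reach the
#' floor are flagged invalid. Reliable bi-exponential fits need on the order
#' of 1000 photons, hence the default floor.
#'
#' @param stack A [flim_stack()].
#' @param min_photons Photon-count floor per binned pixel (default 1000).
#' @param max_kernel Largest kernel side length (odd, default 15).
#' @return A list of class `adaptive_binning`: `kernel` (side-length map,
#'   `NA` where invalid), `valid` (logical map), `total` (binned photon
#'   totals), `min_photons`, and the raw per-pixel totals `raw_total`.
#' @export
adaptive_bin <- function(stack, min_photons = 1000L, max_kernel = 15L) {
  stopifnot(inherits(stack, "flim_stack"))
  if (min_photons <= 0) stop("min_photons must be > 0", call. = FALSE)
  h <- stack$height; w <- stack$width
  tot <- rowSums(stack$counts, dims = 2)
  ii <- integral_image(tot)
  kernel <- matrix(NA_integer_, h, w)
  binned <- matrix(NA_real_, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  todo <- matrix(TRUE, h, w)
  for (k in seq(1L, max_kernel, by = 2L)) {
    r <- (k - 1L) %/% 2L
    if (!any(todo)) break
    idx <- which(todo)
    r1 <- pmax(rows[idx] - r, 1L); r2 <- pmin(rows[idx] + r, h)
    c1 <- pmax(cols[idx] - r, 1L); c2 <- pmin(cols[idx] + r, w)
    s <- ii[cbind(r2 + 1L, c2 + 1L)] - ii[cbind(r1, c2 + 1L)] -
      ii[cbind(r2 + 1L, c1)] + ii[cbind(r1, c1)]
    ok <- s >= min_photons
    kernel[idx[ok]] <- k
    binned[idx[ok]] <- s[ok]
    todo[idx[ok]] <- FALSE
  }
  structure(list(kernel = kernel, valid = !is.na(kernel), total = binned,
                 raw_total = tot, min_photons = min_photons,
                 max_kernel = max_kernel),
            class = "adaptive_binning")
}

#' Binned histogram of one pixel
#'
#' Sums the per-pixel time histograms over the centred square neighbourhood
#' of side `kernel` (clipped at borders) around `(row, col)`.
#'
#' @param stack A [flim_stack()].
#' @param row,col Pixel coordinates.
#' @param kernel Odd kernel side length (1 = the raw pixel histogram).
#' @return A [decay_histogram()].
#' @export
binned_histogram <- function(stack, row, col, kernel = 1L) {
  stopifnot(inherits(stack, "flim_stack"))
  r <- (kernel - 1L) %/% 2L
  r1 <- max(row - r, 1L); r2 <- min(row + r, stack$height)
  c1 <- max(col - r, 1L); c2 <- min(col + r, stack$width)
  block <- stack$counts[r1:r2, c1:c2, , drop = FALSE]
  decay_histogram(colSums(block, dims = 2), stack$axis,
                  origin = sprintf("px(%d,%d)k%d", row, col, kernel))
}

#' Pixel-wise decay fitting of a FLIM stack
#'
#' Runs [adaptive_bin()] and then [fit_decay()] at every masked pixel whose
#' binned histogram reaches the photon floor, producing per-pixel parameter
#' maps. Out-of-mask and below-floor pixels are invalid.
#'
#' @param stack A [flim_stack()].
#' @param irf An `irf_model` on the stack's axis.
#' @param mask A [roi_mask()] matching the stack geometry.
#' @param min_photons Photon floor passed to [adaptive_bin()].
#' @param options [fit_options()] for the per-pixel fits.
#' @return An object of class `parameter_maps`: matrices `tau1`, `tau2`,
#'   `tau_avg` (amplitude-weighted), `tau_avg_int` (intensity-weighted),
#'   `ratio` (`a1/a2`), `chi2_reduced`, `photons` (post-binning), `kernel`,
#'   and logical `valid`; plus the `axis` and `channel`.
#' @export
fit_image <- function(stack, irf, mask, min_photons = 1000L,
                      options = fit_options()) {
  stopifnot(inherits(stack, "flim_stack"), inherits(mask, "roi_mask"))
  if (!all(dim(mask$labels) == c(stack$height, stack$width)))
    stop("mask geometry does not match the stack", call. = FALSE)
  if (!any(mask$labels > 0))
    stop("mask excludes every pixel", call. = FALSE)
  bins <- adaptive_bin(stack, min_photons = min_photons)
  h <- stack$height; w <- stack$width
  blank <- matrix(NA_real_, h, w)
  maps <- list(tau1 = blank, tau2 = blank, tau_avg = blank,
               tau_avg_int = blank, ratio = blank, chi2_reduced = blank,
               photons = bins$total, kernel = bins$kernel,
               valid = matrix(FALSE, h, w),
               axis = stack$axis, channel = stack$channel,
               min_photons = min_photons)
  idx <- which(mask$labels > 0 & bins$valid, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    hist <- binned_histogram(stack, r, c, bins$kernel[r, c])
    fit <- try(fit_decay(hist, irf, options = options), silent = TRUE)
    if (inherits(fit, "try-error")) next
    p <- fit$params
    maps$tau1[r, c] <- p$tau1
    maps$tau2[r, c] <- p$tau2
    maps$tau_avg[r, c] <- average_lifetime(p, "amplitude")
    maps$tau_avg_int[r, c] <- average_lifetime(p, "intensity")
    maps$ratio[r, c] <- fit$free_bound_ratio
    maps$chi2_reduced[r, c] <- fit$chi2_reduced
    maps$valid[r, c] <- TRUE
  }
  structure(maps, class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("FLIM parameter maps (%s): %d x %d px, %d valid (photon floor %d)\n",
              x$channel, nrow(x$valid), ncol(x$valid), sum(x$valid),
              x$min_photons))
  invisible(x)
}

#' ROI-level parameter summary
#'
#' Unweighted means of the per-pixel fitted parameters over the valid pixels
#' of each ROI label. ROIs with no valid pixels are kept in the output with
#' `n_pixels = 0` and `flagged = TRUE` rather than silently dropped.
#'
#' @param maps A `parameter_maps` object from [fit_image()].
#' @param mask The [roi_mask()] used (or any mask of matching geometry).
#' @return A data frame with one row per ROI: `roi`, `n_pixels`, means of
#'   `tau1`, `tau2`, `tau_avg`, `tau_avg_int`, `ratio`, `chi2_reduced`, and a
#'   `flagged` column.
#' @export
roi_mean_params <- function(maps, mask) {
  stopifnot(inherits(maps, "parameter_maps"), inherits(mask, "roi_mask"))
  rois <- sort(unique(mask$labels[mask$labels > 0]))
  if (!length(rois)) stop("mask contains no ROI labels", call. = FALSE)
  rows <- lapply(rois, function(k) {
    in_roi <- mask$labels == k & maps$valid
    n <- sum(in_roi)
    mean_of <- function(m) if (n > 0) mean(m[in_roi]) else NA_real_
    data.frame(roi = k, n_pixels = n,
               tau1 = mean_of(maps$tau1), tau2 = mean_of(maps$tau2),
               tau_avg = mean_of(maps$tau_avg),
               tau_avg_int = mean_of(maps$tau_avg_int),
               ratio = mean_of(maps$ratio),
               chi2_reduced = mean_of(maps$chi2_reduced),
               flagged = n == 0)
  })
  do.call(rbind, rows)
}

#' Pseudocolour rendering of a lifetime map
#'
#' Maps values to a fixed continuous colour scale clipped to `value_range`;
#' invalid pixels are black. Using the same `value_range` across images makes
#' their colours directly comparable.
#'
#' @param maps A `parameter_maps` object.
#' @param value_range `c(lo, hi)` in ns, `lo < hi`.
#' @param what Which map to render (default `"tau_avg"`).
#' @param palette Colour palette name passed to [grDevices::hcl.colors()].
#' @return An `height x width x 3` RGB array in `[0, 1]`.
#' @export
render_lifetime_map <- function(maps, value_range, what = "tau_avg",
                                palette = "viridis") {
  stopifnot(inherits(maps, "parameter_maps"))
  if (length(value_range) != 2 || value_range[1] >= value_range[2])
    stop("value_range must be c(lo, hi) with lo < hi", call. = FALSE)
  vals <- maps[[what]]
  if (is.null(vals)) stop("unknown map: ", what, call. = FALSE)
  n_col <- 256L
  cols <- grDevices::hcl.colors(n_col, palette)
  rgbm <- grDevices::col2rgb(cols) / 255
  u <- (vals - value_range[1]) / diff(value_range)
  idx <- pmin(pmax(floor(u * (n_col - 1L)) + 1L, 1L), n_col)
  h <- nrow(vals); w <- ncol(vals)
  img <- array(0, c(h, w, 3))
  ok <- maps$valid & !is.na(vals)
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[ok] <- rgbm[ch, idx[ok]]
    img[, , ch] <- plane
  }
  img
}
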