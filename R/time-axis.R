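#' TCSPC time axis
#'
#' Describes the histogram time base of a TCSPC measurement: the number of
#' bins, the bin width, and the excitation repetition period. The default
#' corresponds to 82 MHz pulsed excitation (period 1/82 MHz = 12.195 ns)
#' histogrammed into 256 bins of 47.6 ps.
#'
#' @param n_bins Number of histogram bins (positive integer).
#' @param bin_width Bin width in picoseconds.
#' @param period Excitation repetition period in nanoseconds. The histogram
#'   window `n_bins * bin_width` must fit within one period.
#'
#' @return An object of class `time_axis` with elements `n_bins`, `bin_width`
#'   (ps), `period` (ns), `dt` (bin width in ns) and `times` (bin-centre times
#'   in ns).
#' @examples
#' ax <- time_axis()
#' ax$dt * ax$n_bins   # histogram window, ns
#' @export
time_axis <- function(n_bins = 256L, bin_width = 47.6, period = 1e3 / 82) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("n_bins must be an integer >= 2", call. = FALSE)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  if (!is.finite(period) || period <= 0)
    stop("period must be > 0", call. = FALSE)
  dt <- bin_width / 1000
  if (n_bins * dt > period * (1 + 1e-9))
    stop("histogram window n_bins * bin_width exceeds the excitation period",
         call. = FALSE)
  structure(
    list(n_bins = n_bins, bin_width = bin_width, period = period,
         dt = dt, times = (seq_len(n_bins) - 0.5) * dt),
    class = "time_axis")
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf("TCSPC time axis: %d bins x %.3g ps (window %.4g ns, period %.4g ns)\n",
              x$n_bins, x$bin_width, x$n_bins * x$dt, x$period))
  invisible(x)
}

is_time_axis <- function(x) inherits(x, "time_axis")

same_axis <- function(a, b) {
  is_time_axis(a) && is_time_axis(b) && a$n_bins == b$n_bins &&
    isTRUE(all.equal(a$bin_width, b$bin_width)) &&
    isTRUE(all.equal(a$period, b$period))
}
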