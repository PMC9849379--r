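#' Log-spaced comodulogram frequency grid
#'
#' Builds the frequency grid over which CV-PAC comodulograms are computed:
#' a low-frequency (phase) axis and a high-frequency (amplitude) axis, each
#' divided into `n_low` / `n_high` intervals with edges equally spaced in log
#' frequency.  Interval centers are the geometric means of consecutive edges.
#' The defaults give the standard 10 x 10 grid: phase frequencies 1-10 Hz,
#' amplitude frequencies 30-160 Hz, with 18 phase bins tiling `[-pi, pi)`.
#'
#' @param low_range Numeric length-2, range of the phase (low) axis in Hz.
#' @param high_range Numeric length-2, range of the amplitude (high) axis in Hz.
#' @param n_low,n_high Number of intervals on each axis.
#' @param n_bins Number of phase bins used when forming the phase-amplitude
#'   distribution at each pixel.
#'
#' @return An object of class `cvpac_grid`: a list with `low_edges`,
#'   `high_edges`, `low_centers`, `high_centers`, `n_bins` and the phase
#'   `bin_centers`.
#' @examples
#' g <- frequency_grid()
#' g$low_centers
#' @export
frequency_grid <- function(low_range = c(1, 10), high_range = c(30, 160),
                           n_low = 10, n_high = 10, n_bins = 18) {
  stopifnot(length(low_range) == 2, length(high_range) == 2,
            low_range[1] > 0, diff(low_range) > 0, diff(high_range) > 0,
            n_low >= 1, n_high >= 1, n_bins >= 2)
  low_edges <- exp(seq(log(low_range[1]), log(low_range[2]), length.out = n_low + 1))
  high_edges <- exp(seq(log(high_range[1]), log(high_range[2]), length.out = n_high + 1))
  g <- list(
    low_edges = low_edges,
    high_edges = high_edges,
    low_centers = sqrt(low_edges[-1] * low_edges[-(n_low + 1)]),
    high_centers = sqrt(high_edges[-1] * high_edges[-(n_high + 1)]),
    n_bins = as.integer(n_bins),
    bin_centers = phase_bin_centers(n_bins)
  )
  class(g) <- "cvpac_grid"
  g
}

#' @export
print.cvpac_grid <- function(x, ...) {
  cat("<cvpac_grid> ",
      length(x$low_centers), " low x ", length(x$high_centers), " high intervals\n",
      "  phase axis:     ", signif(min(x$low_edges), 4), "-",
      signif(max(x$low_edges), 4), " Hz (log-spaced)\n",
      "  amplitude axis: ", signif(min(x$high_edges), 4), "-",
      signif(max(x$high_edges), 4), " Hz (log-spaced)\n",
      "  phase bins:     ", x$n_bins, " over [-pi, pi)\n", sep = "")
  invisible(x)
}

# Centers of n equal-width phase bins tiling [-pi, pi).
phase_bin_centers <- function(n_bins) {
  -pi + (seq_len(n_bins) - 0.5) * (2 * pi / n_bins)
}

# Map phase values in [-pi, pi) (any reals accepted; wrapped first) to bin
# indices 1..n_bins.
phase_bin_index <- function(phase, n_bins) {
  w <- wrap_phase(phase)
  idx <- floor((w + pi) / (2 * pi / n_bins)) + 1L
  # guard against w == pi after floating-point wrap
  pmin.int(as.integer(idx), n_bins)
}

# Wrap angles into [-pi, pi).
wrap_phase <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}
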