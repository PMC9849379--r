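#' @importFrom tibble tibble as_tibble
#' @importFrom rlang %||% abort
NULL

new_cvpac_image <- function(pixels, grid, provenance = list()) {
  stopifnot(is.complex(pixels), is.matrix(pixels),
            nrow(pixels) == length(grid$high_centers),
            ncol(pixels) == length(grid$low_centers))
  structure(list(pixels = pixels, grid = grid, provenance = provenance),
            class = "cvpac_image")
}

#' Complex-valued comodulogram of a single window
#'
#' Computes the CV-PAC image of one analysis window: for every (low, high)
#' frequency pair of the grid, the instantaneous phase at the low center and
#' the amplitude envelope at the high center are extracted by complex Morlet
#' CWT, the phase-binned mean-amplitude distribution is formed, and the
#' pixel is stored as the complex number whose modulus is the modulation
#' index and whose argument is the coupled phase (the peak bin's center).
#'
#' Wavelet edge effects can be controlled by passing `pad`: the first/last
#' `pad` samples are treated as context, transformed but excluded from the
#' phase-amplitude binning.
#'
#' @param samples Numeric vector of raw samples (window plus any context).
#' @param rate Sampling rate in Hz; must exceed twice the highest grid
#'   frequency.
#' @param grid A [frequency_grid()].
#' @param n_cycles Morlet bandwidth in cycles, see [cwt_band()].
#' @param pad Integer length-2: number of leading/trailing context samples
#'   to trim after the wavelet transform.
#' @param empty_bin Passed to the binning step; `"zero"` flags windows in
#'   which some phase bin was empty, `"reject"` errors.
#' @param provenance Optional named list (channel, patient, label, ...)
#'   carried with the image.
#'
#' @return A `cvpac_image`: complex matrix `pixels` (rows = high-frequency
#'   intervals, columns = low-frequency intervals), the `grid`, and
#'   `provenance`.
#' @examples
#' t <- seq(0, 12, by = 1 / 500)
#' x <- cos(2 * pi * 3 * t) + (1 + cos(2 * pi * 3 * t)) / 2 * cos(2 * pi * 90 * t)
#' img <- cvpac_image(x, rate = 500, pad = c(500, 500))
#' @export
cvpac_image <- function(samples, rate, grid = frequency_grid(), n_cycles = 7,
                        pad = c(0L, 0L), empty_bin = c("zero", "reject"),
                        provenance = list()) {
  empty_bin <- match.arg(empty_bin)
  if (rate <= 2 * max(grid$high_edges)) {
    stop("sampling rate must exceed twice the highest analysis frequency (",
         2 * max(grid$high_edges), " Hz)", call. = FALSE)
  }
  pad <- rep_len(as.integer(pad), 2L)
  n <- length(samples)
  if (pad[1] + pad[2] >= n - 1L) {
    stop("window shorter than its padding", call. = FALSE)
  }
  keep <- seq.int(pad[1] + 1L, n - pad[2])
  low <- cwt_bands(samples, rate, grid$low_centers, n_cycles)
  high <- cwt_bands(samples, rate, grid$high_centers, n_cycles)
  phase_mat <- vapply(low, function(z) Arg(z[keep]), numeric(length(keep)))
  amp_mat <- vapply(high, function(z) Mod(z[keep]), numeric(length(keep)))
  cvpac_from_bands(phase_mat, amp_mat, grid, empty_bin, provenance)
}

# Core binning path shared by cvpac_image() and the surrogate test: takes
# per-column phase / amplitude series already trimmed of padding.
cvpac_from_bands <- function(phase_mat, amp_mat, grid, empty_bin = "zero",
                             provenance = list()) {
  n_bins <- grid$n_bins
  n_low <- ncol(phase_mat)
  n_high <- ncol(amp_mat)
  S <- matrix(0, n_high, n_low)
  PSI <- matrix(0, n_high, n_low)
  empty <- FALSE
  for (cc in seq_len(n_low)) {
    bins <- phase_bin_index(phase_mat[, cc], n_bins)
    counts <- tabulate(bins, n_bins)
    if (any(counts == 0)) {
      if (empty_bin == "reject") {
        stop("empty phase bin in low-frequency interval ", cc, call. = FALSE)
      }
      empty <- TRUE
    }
    sums <- matrix(0, n_bins, n_high)
    got <- rowsum(amp_mat, bins)
    sums[as.integer(rownames(got)), ] <- got
    M <- sums / pmax(counts, 1L)            # recycled down the 18 rows
    tot <- colSums(M)
    tot[tot <= 0] <- 1
    P <- M / rep(tot, each = n_bins)
    L <- n_bins * P
    L[L <= 0] <- 1                          # 0 * log(0) := 0
    S[, cc] <- colSums(P * log(L)) / log(n_bins)
    PSI[, cc] <- grid$bin_centers[max.col(t(P), ties.method = "first")]
  }
  pix <- matrix(cvpac_pixel(as.vector(S), as.vector(PSI)), n_high, n_low)
  if (empty) provenance$flags <- union(provenance$flags %||% character(), "empty_bin")
  new_cvpac_image(pix, grid, provenance)
}

#' Strength and phase accessors of a CV-PAC image
#'
#' `coupling_strengths()` returns the modulus of every pixel (the
#' modulation-index comodulogram, values in `[0, 1]`);
#' `coupling_phases()` returns the argument of every pixel in `[-pi, pi)`
#' (0 for zeroed pixels).  Rows are high-frequency intervals, columns
#' low-frequency intervals.
#'
#' @param image A `cvpac_image`.
#' @return A numeric matrix.
#' @export
coupling_strengths <- function(image) {
  stopifnot(inherits(image, "cvpac_image"))
  Mod(image$pixels)
}

#' @rdname coupling_strengths
#' @export
coupling_phases <- function(image) {
  stopifnot(inherits(image, "cvpac_image"))
  Arg(image$pixels)
}

#' @export
print.cvpac_image <- function(x, ...) {
  s <- coupling_strengths(x)
  top <- arrayInd(which.max(s), dim(s))
  cat("<cvpac_image> ", nrow(s), " x ", ncol(s),
      " pixels; max strength ", signif(max(s), 3),
      " at (", signif(x$grid$low_centers[top[2]], 3), " Hz, ",
      signif(x$grid$high_centers[top[1]], 3), " Hz)",
      if (length(x$provenance$flags)) paste0(" [", paste(x$provenance$flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Compute CV-PAC images for a table of windows
#'
#' Data-frame-first wrapper over [cvpac_image()]: takes a windows tibble (as
#' produced by [sliding_windows()] or [simulate_windows()]) with a `samples`
#' list-column and adds an `image` list-column of `cvpac_image` objects.
#' Padding columns `pad_left` / `pad_right`, when present, are honoured.
#'
#' @param windows A tibble with a `samples` list-column; identifier columns
#'   (`channel`, `patient`, `label`, `window_id`) are copied into each
#'   image's provenance.
#' @param rate Sampling rate in Hz; defaults to `attr(windows, "rate")`.
#' @inheritParams cvpac_image
#' @return The input tibble with an added `image` list-column.
#' @export
compute_cvpac <- function(windows, rate = NULL, grid = frequency_grid(),
                          n_cycles = 7, empty_bin = c("zero", "reject")) {
  empty_bin <- match.arg(empty_bin)
  stopifnot(is.data.frame(windows), "samples" %in% names(windows))
  rate <- rate %||% attr(windows, "rate")
  if (is.null(rate)) abort("no sampling rate: pass `rate` or set attr(windows, 'rate')")
  pl <- windows$pad_left %||% rep(0L, nrow(windows))
  pr <- windows$pad_right %||% rep(0L, nrow(windows))
  keys <- intersect(c("window_id", "channel", "patient", "label"), names(windows))
  windows$image <- purrr::map(seq_len(nrow(windows)), function(i) {
    prov <- as.list(windows[i, keys, drop = FALSE])
    prov <- lapply(prov, as.character)
    cvpac_image(windows$samples[[i]], rate, grid, n_cycles,
                pad = c(pl[i], pr[i]), empty_bin = empty_bin, provenance = prov)
  })
  windows
}
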