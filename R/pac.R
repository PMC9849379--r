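#' Phase-amplitude distribution over phase bins
#'
#' Bins the instantaneous low-frequency phase into `n_bins` equal-width bins
#' tiling `[-pi, pi)`, averages the high-frequency amplitude within each bin,
#' and normalizes the bin means to sum to one.  This distribution is the
#' basis of the modulation index: it is uniform when the amplitude does not
#' depend on the phase, and concentrates mass in few bins under coupling.
#'
#' @param phase Numeric vector of instantaneous phases (radians; wrapped
#'   internally into `[-pi, pi)`).
#' @param amplitude Numeric vector of non-negative instantaneous amplitudes,
#'   same length as `phase`.
#' @param n_bins Number of phase bins (default 18, bin width pi/9).
#' @param empty_bin How to handle a phase bin that receives no samples:
#'   `"zero"` treats its mean amplitude as 0 and flags the result,
#'   `"reject"` throws an error.
#'
#' @return An object of class `pa_distribution`: list with `p` (the
#'   normalized weights, summing to 1), `bin_centers`, `counts` and
#'   `flags` (character, possibly `"empty_bin"`).
#' @examples
#' ph <- runif(5000, -pi, pi)
#' d <- phase_amplitude_distribution(ph, 1 + cos(ph))
#' sum(d$p)
#' @export
phase_amplitude_distribution <- function(phase, amplitude, n_bins = 18,
                                         empty_bin = c("zero", "reject")) {
  empty_bin <- match.arg(empty_bin)
  stopifnot(length(phase) == length(amplitude), length(phase) > 0)
  if (any(amplitude < 0)) stop("amplitude must be non-negative", call. = FALSE)
  bins <- phase_bin_index(phase, n_bins)
  counts <- tabulate(bins, n_bins)
  flags <- character()
  if (any(counts == 0)) {
    if (empty_bin == "reject") {
      stop("phase bin(s) ", paste(which(counts == 0), collapse = ", "),
           " received no samples", call. = FALSE)
    }
    flags <- "empty_bin"
  }
  sums <- numeric(n_bins)
  s <- rowsum(amplitude, bins)
  sums[as.integer(rownames(s))] <- s
  means <- sums / pmax(counts, 1L)
  tot <- sum(means)
  p <- if (tot > 0) means / tot else rep(1 / n_bins, n_bins)
  structure(list(p = p, bin_centers = phase_bin_centers(n_bins),
                 counts = counts, flags = flags),
            class = "pa_distribution")
}

#' @export
print.pa_distribution <- function(x, ...) {
  cat("<pa_distribution> ", length(x$p), " phase bins, MI = ",
      signif(modulation_index(x), 4), "\n", sep = "")
  invisible(x)
}

# Accept either a pa_distribution or a bare probability vector.
as_pvec <- function(dist) {
  p <- if (inherits(dist, "pa_distribution")) dist$p else as.numeric(dist)
  if (any(p < 0)) stop("distribution weights must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) {
    stop("distribution is not normalized (sum = ", format(sum(p)), ")", call. = FALSE)
  }
  p
}

#' Kullback-Leibler distance to the uniform distribution
#'
#' Computes `D_KL(P, U) = sum_j P(j) log(P(j) / U(j))` with `U(j) = 1/N`,
#' using the natural logarithm.  Terms with `P(j) = 0` contribute zero.  The
#' result lies in `[0, log N]`, the maximum attained by a one-hot
#' distribution.
#'
#' @param dist A [phase_amplitude_distribution()] result, or a bare
#'   normalized non-negative weight vector.
#' @return A single non-negative number.
#' @examples
#' kl_to_uniform(rep(1 / 18, 18))        # 0
#' kl_to_uniform(c(1, rep(0, 17)))       # log(18)
#' @export
kl_to_uniform <- function(dist) {
  p <- as_pvec(dist)
  n <- length(p)
  nz <- p > 0
  sum(p[nz] * log(n * p[nz]))
}

#' Modulation index (coupling strength)
#'
#' The coupling strength of a phase-amplitude distribution: its KL distance
#' to uniform normalized by `log N`, so the value lies in `[0, 1]` --- 0 for
#' a uniform distribution (no coupling), 1 when all amplitude falls in a
#' single phase bin.  The normalization makes the value independent of the
#' logarithm base.
#'
#' @inheritParams kl_to_uniform
#' @return A number in `[0, 1]`.
#' @export
modulation_index <- function(dist) {
  p <- as_pvec(dist)
  kl_to_uniform(p) / log(length(p))
}

#' Coupled phase of a phase-amplitude distribution
#'
#' The center angle of the phase bin in which the distribution peaks,
#' reported in `[-pi, pi)`.  Ties are broken toward the lowest bin index
#' (the bin nearest `-pi`).
#'
#' @inheritParams kl_to_uniform
#' @return An angle in radians.
#' @export
coupling_phase <- function(dist) {
  p <- as_pvec(dist)
  phase_bin_centers(length(p))[which.max(p)]
}

#' Complex CV-PAC pixel from strength and phase
#'
#' Combines a coupling strength and a coupled phase into one complex number
#' `S * cos(psi) + i * S * sin(psi)`, whose modulus is the strength and
#' whose argument is the phase.  A zero-strength pixel is stored as exactly
#' `0 + 0i`.
#'
#' @param strength Coupling strength(s) in `[0, 1]`.
#' @param phase Coupled phase(s) in radians.
#' @return Complex vector.
#' @examples
#' cvpac_pixel(0.5, pi / 2)   # 0 + 0.5i
#' @export
cvpac_pixel <- function(strength, phase) {
  if (any(strength < -1e-12) || any(strength > 1 + 1e-12)) {
    stop("strength must lie in [0, 1]", call. = FALSE)
  }
  s <- pmin(pmax(strength, 0), 1)
  out <- complex(modulus = s, argument = phase)
  out[s == 0] <- 0 + 0i
  out
}
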