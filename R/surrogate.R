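#' Surrogate-tested CV-PAC (ST-CV-PAC)
#'
#' Screens every pixel of a CV-PAC image for significance against a null
#' distribution obtained by shuffling the low-frequency phase series: for
#' each low-frequency interval the pairing between phase and amplitude is
#' destroyed `n_shuffles` times and the modulation index recomputed.  A
#' pixel whose observed strength falls below the top `alpha` fraction of its
#' shuffled strengths (i.e. below the smallest of the `floor(alpha *
#' n_shuffles)` largest null values) is set to `0 + 0i`; surviving pixels
#' are kept unchanged.
#'
#' Two shuffling schemes are available.  `"shift"` (the default) rotates
#' the amplitude series against the phase series by a random circular time
#' shift, preserving the autocorrelation of both series --- the appropriate
#' null for oscillatory data, under which the retention rate on uncoupled
#' noise is calibrated to `alpha`.  `"permute"` applies a full random
#' permutation; it preserves only the phase histogram and is
#' anti-conservative on autocorrelated signals (retained as an option for
#' comparison).
#'
#' @inheritParams cvpac_image
#' @param n_shuffles Number of shuffles per low-frequency interval
#'   (at least 20, and `alpha * n_shuffles >= 1`).
#' @param alpha Significance level in `(0, 1]`; `alpha = 1` zeroes every
#'   pixel.
#' @param method `"shift"` (circular time shift) or `"permute"` (full
#'   permutation).
#' @param seed Optional integer seed making the shuffles reproducible.
#'
#' @return A `cvpac_image` whose non-significant pixels are `0 + 0i`.  The
#'   provenance gains `n_retained`, the number of surviving pixels.
#' @export
st_cvpac_image <- function(samples, rate, grid = frequency_grid(), n_cycles = 7,
                           pad = c(0L, 0L), n_shuffles = 100, alpha = 0.05,
                           method = c("shift", "permute"), seed = NULL,
                           empty_bin = c("zero", "reject"), provenance = list()) {
  method <- match.arg(method)
  empty_bin <- match.arg(empty_bin)
  if (n_shuffles < 20) stop("n_shuffles must be at least 20", call. = FALSE)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (alpha < 1 && alpha * n_shuffles < 1) {
    stop("alpha * n_shuffles must be at least 1", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  pad <- rep_len(as.integer(pad), 2L)
  n_all <- length(samples)
  if (pad[1] + pad[2] >= n_all - 1L) {
    stop("window shorter than its padding", call. = FALSE)
  }
  keep <- seq.int(pad[1] + 1L, n_all - pad[2])
  low <- cwt_bands(samples, rate, grid$low_centers, n_cycles)
  high <- cwt_bands(samples, rate, grid$high_centers, n_cycles)
  phase_mat <- vapply(low, function(z) Arg(z[keep]), numeric(length(keep)))
  amp_mat <- vapply(high, function(z) Mod(z[keep]), numeric(length(keep)))
  img <- cvpac_from_bands(phase_mat, amp_mat, grid, empty_bin, provenance)

  if (alpha >= 1) {
    img$pixels[] <- 0 + 0i
    img$provenance$n_retained <- 0L
    return(img)
  }
  n <- length(keep)
  n_high <- ncol(amp_mat)
  n_low <- ncol(phase_mat)
  s_obs <- coupling_strengths(img)
  k <- n_shuffles - floor(alpha * n_shuffles) + 1L   # smallest of the top alpha block
  retain <- matrix(FALSE, n_high, n_low)
  for (cc in seq_len(n_low)) {
    bins <- phase_bin_index(phase_mat[, cc], grid$n_bins)
    null_s <- if (method == "shift") {
      offsets <- sample.int(n - 1L, n_shuffles, replace = TRUE)
      surr_strength_shift(bins, amp_mat, offsets, grid$n_bins)
    } else {
      perms <- vapply(seq_len(n_shuffles), function(i) sample.int(n),
                      integer(n))
      surr_strength_perm(bins, amp_mat, perms, grid$n_bins)
    }
    thr <- apply(null_s, 2L, function(v) sort(v, partial = k)[k])
    retain[, cc] <- s_obs[, cc] >= thr
  }
  img$pixels[!retain] <- 0 + 0i
  img$provenance$n_retained <- sum(retain)
  img
}

#' Surrogate-tested CV-PAC for a table of windows
#'
#' Data-frame-first wrapper over [st_cvpac_image()]: adds an `image`
#' list-column of surrogate-screened images to a windows tibble.  Each
#' window gets an independent child seed derived from `seed`.
#'
#' @inheritParams compute_cvpac
#' @inheritParams st_cvpac_image
#' @return The input tibble with an added `image` list-column.
#' @export
surrogate_cvpac <- function(windows, rate = NULL, grid = frequency_grid(),
                            n_cycles = 7, n_shuffles = 100, alpha = 0.05,
                            method = c("shift", "permute"), seed = NULL,
                            empty_bin = c("zero", "reject")) {
  method <- match.arg(method)
  empty_bin <- match.arg(empty_bin)
  stopifnot(is.data.frame(windows), "samples" %in% names(windows))
  rate <- rate %||% attr(windows, "rate")
  if (is.null(rate)) abort("no sampling rate: pass `rate` or set attr(windows, 'rate')")
  pl <- windows$pad_left %||% rep(0L, nrow(windows))
  pr <- windows$pad_right %||% rep(0L, nrow(windows))
  keys <- intersect(c("window_id", "channel", "patient", "label"), names(windows))
  seeds <- child_seeds(seed, nrow(windows))
  windows$image <- purrr::map(seq_len(nrow(windows)), function(i) {
    prov <- lapply(as.list(windows[i, keys, drop = FALSE]), as.character)
    st_cvpac_image(windows$samples[[i]], rate, grid, n_cycles,
                   pad = c(pl[i], pr[i]), n_shuffles = n_shuffles,
                   alpha = alpha, method = method, seed = seeds[[i]],
                   empty_bin = empty_bin, provenance = prov)
  })
  windows
}

# -- seed plumbing -----------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Derive n reproducible child seeds (< 2^31) from one parent seed; NULL
# parent gives NULL children (leave the RNG alone).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}
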