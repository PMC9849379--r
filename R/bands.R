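#' Clinical frequency-band masks over the comodulogram grid
#'
#' Maps the named clinical bands onto the log-spaced comodulogram grid.  A
#' grid interval belongs to a band iff its center frequency lies inside the
#' band's range (intervals are assigned by center because the log-spaced
#' edges do not align exactly with the clinical boundaries).  The four
#' low-frequency bands partition the columns; gamma and hfo partition the
#' rows.
#'
#' @param grid A [frequency_grid()].
#' @param band_name One of `"slow_delta"` (1-2 Hz), `"fast_delta"` (2-4 Hz),
#'   `"theta"` (4-8 Hz), `"alpha"` (8-10 Hz), `"gamma"` (30-80 Hz),
#'   `"hfo"` (80-160 Hz).
#'
#' @return An object of class `band_mask`: list with `name`, `axis`
#'   (`"low"` for column bands, `"high"` for row bands), `range` in Hz, and
#'   `selected`, a logical matrix over the grid pixels.
#' @examples
#' band_mask(frequency_grid(), "theta")
#' @export
band_mask <- function(grid, band_name) {
  bands <- cvpac_bands()
  band_name <- match.arg(band_name, names(bands))
  b <- bands[[band_name]]
  n_low <- length(grid$low_centers)
  n_high <- length(grid$high_centers)
  sel <- matrix(FALSE, n_high, n_low)
  if (b$axis == "low") {
    cols <- grid$low_centers >= b$range[1] & grid$low_centers < b$range[2]
    sel[, cols] <- TRUE
  } else {
    rows <- grid$high_centers >= b$range[1] & grid$high_centers < b$range[2]
    sel[rows, ] <- TRUE
  }
  structure(list(name = band_name, axis = b$axis, range = b$range,
                 selected = sel),
            class = "band_mask")
}

# The six named bands.  Upper limits of the top band on each axis are
# closed so the highest interval is always assigned.
cvpac_bands <- function() {
  list(
    slow_delta = list(axis = "low", range = c(1, 2)),
    fast_delta = list(axis = "low", range = c(2, 4)),
    theta      = list(axis = "low", range = c(4, 8)),
    alpha      = list(axis = "low", range = c(8, 10 + 1e-9)),
    gamma      = list(axis = "high", range = c(30, 80)),
    hfo        = list(axis = "high", range = c(80, 160 + 1e-9))
  )
}

#' @export
print.band_mask <- function(x, ...) {
  cat("<band_mask> ", x$name, " (", x$range[1], "-", x$range[2], " Hz, ",
      if (x$axis == "low") "columns" else "rows", "): ",
      sum(x$selected), " pixels\n", sep = "")
  invisible(x)
}

#' Replace a band of a CV-PAC image with moment-matched noise
#'
#' Band-ablation control: the pixels selected by `mask` are replaced with
#' random complex values whose real and imaginary parts are drawn
#' independently from normal distributions with the same per-part mean and
#' variance as the region being replaced, so a classifier can no longer read
#' structure from the band while its gross statistics are preserved.
#'
#' The replacement moments default to the masked region of `image` itself;
#' in an evaluation they should be pooled over the training split and passed
#' via `moments` (see [run_ablation_experiment()]).
#'
#' @param image A `cvpac_image`.
#' @param mask A [band_mask()] on the same grid.
#' @param seed Optional integer seed for reproducible replacement.
#' @param moments Optional list with `mean_re`, `sd_re`, `mean_im`, `sd_im`
#'   giving the replacement statistics (e.g. pooled over a dataset split).
#' @param mode `"independent"` draws real and imaginary parts independently
#'   (default); `"circular"` draws a circularly-symmetric complex Gaussian
#'   around the complex mean with matching total variance.
#'
#' @return The image with the masked pixels replaced.
#' @export
ablate_band <- function(image, mask, seed = NULL, moments = NULL,
                        mode = c("independent", "circular")) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "cvpac_image"), inherits(mask, "band_mask"),
            all(dim(mask$selected) == dim(image$pixels)))
  idx <- which(mask$selected)
  if (length(idx) == 0L) return(image)
  if (is.null(moments)) moments <- ablation_moments(list(image), mask)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n <- length(idx)
  repl <- if (mode == "independent") {
    complex(real = rnorm(n, moments$mean_re, moments$sd_re),
            imaginary = rnorm(n, moments$mean_im, moments$sd_im))
  } else {
    s <- sqrt((moments$sd_re^2 + moments$sd_im^2) / 2)
    complex(real = rnorm(n, moments$mean_re, s),
            imaginary = rnorm(n, moments$mean_im, s))
  }
  image$pixels[idx] <- repl
  image$provenance$ablated <- mask$name
  image
}

#' Pooled per-part moments of a masked region over a set of images
#'
#' Computes the mean and standard deviation of the real and imaginary parts
#' of the pixels selected by `mask`, pooled across `images` --- the
#' replacement statistics used by [ablate_band()].
#'
#' @param images List of `cvpac_image` objects.
#' @inheritParams ablate_band
#' @return List with `mean_re`, `sd_re`, `mean_im`, `sd_im`.
#' @export
ablation_moments <- function(images, mask) {
  idx <- which(mask$selected)
  vals <- unlist(lapply(images, function(im) im$pixels[idx]))
  list(mean_re = mean(Re(vals)),
       sd_re = if (length(vals) > 1) sd(Re(vals)) else 0,
       mean_im = mean(Im(vals)),
       sd_im = if (length(vals) > 1) sd(Im(vals)) else 0)
}

#' Restrict a CV-PAC image to one high-frequency band
#'
#' Keeps only the rows (high-frequency intervals) whose centers lie in the
#' given row band --- the LFO-gamma / LFO-HFO experiments.  Pixel values are
#' copied unchanged and the grid is cut down to the selected intervals.
#'
#' @param image A `cvpac_image`.
#' @param mask A row-axis [band_mask()] (`"gamma"` or `"hfo"`).
#' @return A `cvpac_image` with the reduced row set.
#' @export
restrict_rows <- function(image, mask) {
  stopifnot(inherits(image, "cvpac_image"), inherits(mask, "band_mask"))
  if (mask$axis != "high") {
    stop("restrict_rows() needs a high-frequency (row) band such as gamma or hfo",
         call. = FALSE)
  }
  rows <- which(mask$selected[, 1])
  g <- image$grid
  g$high_centers <- g$high_centers[rows]
  # keep the edges that bound the selected intervals
  g$high_edges <- g$high_edges[c(rows, max(rows) + 1L)]
  out <- image
  out$pixels <- image$pixels[rows, , drop = FALSE]
  out$grid <- g
  out
}
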