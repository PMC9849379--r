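#' Class specification for synthetic coupled signals
#'
#' Describes how one class (pathological or normal) couples in each
#' low-frequency band: the mean coupled phase, the circular spread of that
#' phase across channels, and the distribution of modulation depth.  Phases
#' are drawn from a wrapped (circular) Gaussian; modulation depths from a
#' normal clipped to `[0, 1]`.
#'
#' @param name Class name, `"pathological"` or `"normal"`.
#' @param bands A data frame with one row per low band and columns `band`
#'   (`slow_delta`, `fast_delta`, `theta`, `alpha`), `phase_mean` (rad),
#'   `phase_sd` (rad, circular spread), `strength_mean`, `strength_sd`
#'   (modulation depth in `[0, 1]`).
#' @param high_range Range in Hz from which each component's amplitude
#'   (high) frequency is drawn log-uniformly.
#' @param noise_sd Additive white-noise sd relative to the unit oscillation
#'   amplitude.
#' @return An object of class `class_spec`.
#' @seealso [default_class_specs()] for ready-made pairs.
#' @export
class_spec <- function(name, bands, high_range = c(30, 160), noise_sd = 0.5) {
  bands <- as_tibble(bands)
  stopifnot(all(c("band", "phase_mean", "phase_sd",
                  "strength_mean", "strength_sd") %in% names(bands)),
            all(bands$strength_mean >= 0), all(bands$strength_mean <= 1))
  bands$phase_mean <- wrap_phase(bands$phase_mean)
  structure(list(name = name, bands = bands, high_range = high_range,
                 noise_sd = noise_sd),
            class = "class_spec")
}

#' Default pathological / normal class pairs
#'
#' Two ready-made pairs of class specifications.  `"clinical"` mimics the
#' qualitative pattern reported for resected vs. non-resected tissue:
#' coupled phases separate the classes in the slow-delta, fast-delta and
#' alpha bands, while theta phases overlap and the pathological class
#' instead couples more strongly in theta.  `"phase_only"` gives both
#' classes identical strength distributions everywhere so they differ only
#' in coupled phase --- the construction under which strength-only features
#' carry no class information.  All numbers are synthetic stand-ins chosen
#' for qualitative shape, not measured values.
#'
#' @param profile `"clinical"` or `"phase_only"`.
#' @param noise_sd Additive noise sd passed to both classes.
#' @return Named list with elements `normal` and `pathological`.
#' @export
default_class_specs <- function(profile = c("clinical", "phase_only"),
                                noise_sd = 0.5) {
  profile <- match.arg(profile)
  bandnames <- c("slow_delta", "fast_delta", "theta", "alpha")
  ph_normal <- c(2.0, -2.4, 1.0, -0.6)
  ph_path <- c(-1.2, 0.6, 1.0, 2.2)
  if (profile == "clinical") {
    st_normal <- c(0.55, 0.55, 0.35, 0.55)
    st_path <- c(0.55, 0.55, 0.80, 0.55)
  } else {
    st_normal <- st_path <- rep(0.6, 4)
  }
  mk <- function(name, ph, st) {
    class_spec(name,
               tibble(band = bandnames, phase_mean = ph, phase_sd = 0.5,
                      strength_mean = st, strength_sd = 0.15),
               noise_sd = noise_sd)
  }
  list(normal = mk("normal", ph_normal, st_normal),
       pathological = mk("pathological", ph_path, st_path))
}

#' @export
print.class_spec <- function(x, ...) {
  cat("<class_spec> ", x$name, " (noise_sd ", x$noise_sd, ")\n", sep = "")
  print(as.data.frame(x$bands), row.names = FALSE)
  invisible(x)
}

# Wrapped-normal circular draws.
rwrapnorm <- function(n, mean, sd) {
  wrap_phase(rnorm(n, mean, sd))
}

# 1/f ("pink") noise via spectral shaping, unit sd.
pink_noise <- function(n) {
  nf <- stats::nextn(n, 2)
  w <- rnorm(nf)
  wf <- stats::fft(w)
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - f + 1)                 # two-sided frequency index
  x <- Re(stats::fft(wf / sqrt(f), inverse = TRUE))[seq_len(n)]
  x / sd(x)
}

#' Generate one phase-amplitude coupled signal
#'
#' Builds a time series in which the amplitude envelope of each fast
#' oscillation is locked to the instantaneous phase of its slow partner.
#' For every component the contribution is
#' `cos(2 pi f_low t + phi0) + m(t) cos(2 pi f_high t + theta0)` with the
#' sinusoidal envelope `m(t) = 1 - d + d (1 + cos(2 pi f_low t + phi0 -
#' phase)) / 2`, so the fast amplitude peaks when the slow phase equals
#' `phase` and the modulation depth `d` in `[0, 1]` sets the coupling
#' strength (0 = none).  Components are summed and additive noise appended.
#'
#' @param components Data frame with columns `f_low`, `f_high` (Hz),
#'   `strength` (modulation depth `d`), `phase` (rad).
#' @param duration_s Analysis duration in seconds.
#' @param rate Sampling rate in Hz (must exceed `2 * max(f_high)`).
#' @param noise_sd Additive noise sd.
#' @param pad_s Extra context generated on each side (seconds); the
#'   returned vector has `round(pad_s * rate)` pad samples per side.
#' @param noise `"white"` or `"pink"` (1/f).
#' @param seed Optional integer seed.
#' @return Numeric vector of `round((duration_s + 2 pad_s) * rate)` samples.
#' @export
generate_coupled_signal <- function(components, duration_s = 10, rate = 1000,
                                    noise_sd = 0.5, pad_s = 0,
                                    noise = c("white", "pink"), seed = NULL) {
  noise <- match.arg(noise)
  components <- as_tibble(components)
  stopifnot(all(c("f_low", "f_high", "strength", "phase") %in% names(components)),
            all(components$strength >= 0), all(components$strength <= 1))
  if (nrow(components) > 0 && rate <= 2 * max(components$f_high)) {
    stop("rate must exceed twice the highest amplitude frequency",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n <- round((duration_s + 2 * pad_s) * rate)
  t <- (seq_len(n) - 1L - round(pad_s * rate)) / rate
  x <- numeric(n)
  for (i in seq_len(nrow(components))) {
    d <- components$strength[i]
    phi0 <- runif(1, -pi, pi)
    theta0 <- runif(1, -pi, pi)
    slow <- 2 * pi * components$f_low[i] * t + phi0
    env <- 1 - d + d * (1 + cos(slow - components$phase[i])) / 2
    x <- x + cos(slow) + env * cos(2 * pi * components$f_high[i] * t + theta0)
  }
  if (noise_sd > 0) {
    eps <- if (noise == "white") rnorm(n) else pink_noise(n)
    x <- x + noise_sd * eps
  }
  x
}

# Draw one component per low band from a class spec.  Per-channel coupled
# phases (drawn once per channel) are passed in; strengths and frequencies
# are redrawn per window.
draw_components <- function(spec, channel_phases) {
  bands <- cvpac_bands()
  info <- spec$bands
  f_low <- vapply(info$band, function(b) {
    r <- bands[[b]]$range
    exp(runif(1, log(r[1]), log(min(r[2], 10))))
  }, 0)
  f_high <- exp(runif(nrow(info), log(spec$high_range[1]),
                      log(spec$high_range[2])))
  tibble(f_low = f_low, f_high = f_high,
         strength = pmin(pmax(rnorm(nrow(info), info$strength_mean,
                                    info$strength_sd), 0), 1),
         phase = channel_phases)
}

#' Simulate labeled windows of coupled signal
#'
#' Generates analysis windows for a pair of classes.  Windows are grouped
#' into synthetic channels: each channel draws its per-band coupled phases
#' once from its class distribution (so a channel has a consistent phase
#' fingerprint), then each of its windows redraws modulation depths and
#' component frequencies.
#'
#' @param specs A list with elements `normal` and `pathological` (see
#'   [default_class_specs()]).
#' @param n_per_class Number of windows per class (the normal class when
#'   `imbalance_ratio` is set).
#' @param windows_per_channel Windows per synthetic channel.
#' @param duration_s,rate,pad_s,noise As in [generate_coupled_signal()].
#' @param imbalance_ratio Optional pathological:normal count ratio, e.g.
#'   `1 / 2.77`; `NULL` keeps the classes balanced.
#' @param patient Patient identifier stamped on all windows.
#' @param seed Optional integer seed.
#' @return A windows tibble (as from [sliding_windows()]) with
#'   `attr(, "rate")` set.
#' @export
simulate_windows <- function(specs = default_class_specs(), n_per_class = 100,
                             windows_per_channel = 10, duration_s = 10,
                             rate = 1000, pad_s = 2,
                             noise = c("white", "pink"),
                             imbalance_ratio = NULL, patient = "S1",
                             seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(all(c("normal", "pathological") %in% names(specs)))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  counts <- c(normal = n_per_class,
              pathological = if (is.null(imbalance_ratio)) n_per_class
                             else max(0L, round(n_per_class * imbalance_ratio)))
  rows <- list()
  wid <- 0L
  for (cls in c("pathological", "normal")) {
    spec <- specs[[cls]]
    n_win <- counts[[cls]]
    if (n_win == 0) next
    n_ch <- ceiling(n_win / windows_per_channel)
    left <- n_win
    for (ch in seq_len(n_ch)) {
      ch_lab <- sprintf("%s%02d", toupper(substr(cls, 1, 1)), ch)
      ch_phases <- rwrapnorm(nrow(spec$bands), spec$bands$phase_mean,
                             spec$bands$phase_sd)
      for (w in seq_len(min(windows_per_channel, left))) {
        comp <- draw_components(spec, ch_phases)
        x <- generate_coupled_signal(comp, duration_s, rate, spec$noise_sd,
                                     pad_s, noise)
        wid <- wid + 1L
        rows[[wid]] <- tibble(
          window_id = wid, patient = patient, channel = ch_lab,
          label = cls, seizure = 1L, start_s = (w - 1) * duration_s,
          duration_s = duration_s, samples = list(x),
          pad_left = round(pad_s * rate), pad_right = round(pad_s * rate))
      }
      left <- left - windows_per_channel
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "rate") <- rate
  out
}

#' Windows of pure noise (no coupling)
#'
#' Convenience generator of uncoupled noise windows, the null input for
#' surrogate-calibration checks.
#'
#' @inheritParams simulate_windows
#' @param n Number of windows.
#' @return A windows tibble with `label = "normal"`.
#' @export
noise_windows <- function(n, duration_s = 10, rate = 1000, pad_s = 2,
                          noise = c("white", "pink"), seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n_samp <- round((duration_s + 2 * pad_s) * rate)
  out <- tibble(
    window_id = seq_len(n), patient = "NOISE",
    channel = sprintf("N%03d", seq_len(n)), label = "normal",
    seizure = 1L, start_s = 0, duration_s = duration_s,
    samples = purrr::map(seq_len(n), function(i) {
      if (noise == "white") rnorm(n_samp) else pink_noise(n_samp)
    }),
    pad_left = round(pad_s * rate), pad_right = round(pad_s * rate))
  attr(out, "rate") <- rate
  out
}

#' Simulate a labeled CV-PAC image dataset
#'
#' End-to-end synthetic dataset: simulates coupled windows with
#' [simulate_windows()] and computes every image through the comodulogram
#' pipeline (images are never drawn directly), so channel-level evaluation
#' and classifier training are exercised exactly as with real recordings.
#'
#' @inheritParams simulate_windows
#' @inheritParams compute_cvpac
#' @param surrogate If `TRUE`, images are surrogate-screened with
#'   [surrogate_cvpac()] (`n_shuffles = 100`, `alpha = 0.05`).
#' @return A tibble with window metadata and an `image` list-column.
#' @export
generate_labeled_dataset <- function(specs = default_class_specs(),
                                     n_per_class = 100,
                                     windows_per_channel = 10,
                                     duration_s = 10, rate = 1000, pad_s = 2,
                                     grid = frequency_grid(),
                                     imbalance_ratio = NULL, patient = "S1",
                                     surrogate = FALSE, seed = NULL) {
  seeds <- child_seeds(seed, 2L)
  win <- simulate_windows(specs, n_per_class, windows_per_channel, duration_s,
                          rate, pad_s, imbalance_ratio = imbalance_ratio,
                          patient = patient, seed = seeds[[1]])
  if (nrow(win) == 0) {
    win$image <- list()
    return(win)
  }
  if (surrogate) {
    surrogate_cvpac(win, rate, grid, seed = seeds[[2]])
  } else {
    compute_cvpac(win, rate, grid)
  }
}

#' Reference cohort layout for the synthetic pipeline
#'
#' Patient identifiers and per-patient seizure durations (seconds) of the
#' nine-patient, 23-seizure cohort layout used by [simulate_cohort()] to
#' exercise the full pipeline at realistic problem sizes.
#'
#' @return A tibble with columns `patient` and `durations` (list-column of
#'   numeric vectors).
#' @export
default_cohort <- function() {
  tibble(
    patient = paste0("P", 1:9),
    durations = list(c(66, 61, 48), c(74, 76, 77), c(75, 84),
                     c(42, 64, 120), c(65, 97, 67), 71,
                     c(44, 54, 55), c(59, 60, 82), c(76, 80)))
}

#' Simulate one patient's monopolar recording
#'
#' Builds a continuous multichannel recording for one synthetic patient:
#' `n_pairs` bipolar-ready contact pairs (anode carries the class signal,
#' cathode low-level noise), all contacts sharing a strong common reference
#' that only the bipolar montage removes.  Seizure spans (annotated) carry
#' phase-amplitude coupled signal drawn from the pathological spec on the
#' first `n_pathological` pairs and from the normal spec elsewhere;
#' inter-seizure gaps are noise.
#'
#' @param patient Patient identifier.
#' @param durations Numeric vector of seizure durations in seconds.
#' @param n_pairs Number of contact pairs (bipolar channels).
#' @param n_pathological Number of pairs whose contacts are marked resected.
#' @param rate Sampling rate in Hz.
#' @param specs Class specifications, see [default_class_specs()].
#' @param gap_s Noise gap before, between and after seizures (seconds).
#' @param ref_sd Amplitude of the shared common-reference noise.
#' @param seed Optional integer seed.
#' @return A [new_recording()] with `attr(, "bipolar_pairs")` set.
#' @export
simulate_patient <- function(patient, durations, n_pairs = 6,
                             n_pathological = 2, rate = 1000,
                             specs = default_class_specs(), gap_s = 4,
                             ref_sd = 2, seed = NULL) {
  stopifnot(n_pathological <= n_pairs, length(durations) >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n_seiz <- length(durations)
  seg_dur <- c(rbind(rep(gap_s, n_seiz), durations), gap_s)  # gap,s1,gap,s2,...,gap
  onsets <- cumsum(c(0, head(seg_dur, -1)))
  is_seiz <- c(rbind(rep(FALSE, n_seiz), rep(TRUE, n_seiz)), FALSE)
  total <- sum(seg_dur)
  n_total <- round(total * rate)
  labels <- paste0("E", seq_len(2 * n_pairs))
  samples <- matrix(0, n_total, 2 * n_pairs)
  ref <- ref_sd * rnorm(n_total)
  for (p in seq_len(n_pairs)) {
    spec <- specs[[if (p <= n_pathological) "pathological" else "normal"]]
    ch_phases <- rwrapnorm(nrow(spec$bands), spec$bands$phase_mean,
                           spec$bands$phase_sd)
    anode <- numeric(0)
    for (s in seq_along(seg_dur)) {
      n_seg <- round(seg_dur[s] * rate)
      seg <- if (is_seiz[s]) {
        comp <- draw_components(spec, ch_phases)
        generate_coupled_signal(comp, seg_dur[s], rate, spec$noise_sd)
      } else {
        spec$noise_sd * rnorm(n_seg)
      }
      anode <- c(anode, seg)
    }
    length(anode) <- n_total
    anode[is.na(anode)] <- 0
    samples[, 2 * p - 1] <- anode + ref
    samples[, 2 * p] <- 0.3 * rnorm(n_total) + ref
  }
  resected <- rep(seq_len(n_pairs) <= n_pathological, each = 2)
  rec <- new_recording(samples, rate, labels,
                       annotations = tibble(onset = onsets[is_seiz],
                                            termination = onsets[is_seiz] +
                                              durations),
                       resected = resected, patient = patient)
  attr(rec, "bipolar_pairs") <- tibble(
    anode = labels[2 * seq_len(n_pairs) - 1],
    cathode = labels[2 * seq_len(n_pairs)])
  rec
}

#' Simulate a multi-patient windows dataset through the full pipeline
#'
#' For every patient of `cohort`, simulates a monopolar recording
#' ([simulate_patient()]), applies the bipolar montage, cuts sliding
#' windows inside the seizure annotations, and row-binds the result ---
#' the input expected by [compute_cvpac()] and the LOOCV evaluation.
#'
#' @param cohort A tibble like [default_cohort()].
#' @inheritParams simulate_patient
#' @inheritParams sliding_windows
#' @return A windows tibble spanning all patients, `attr(, "rate")` set.
#' @export
simulate_cohort <- function(cohort = default_cohort(), n_pairs = 6,
                            n_pathological = 2, rate = 1000,
                            specs = default_class_specs(), window_s = 10,
                            step_s = 2, context_s = 2, seed = NULL) {
  seeds <- child_seeds(seed, nrow(cohort))
  out <- purrr::map(seq_len(nrow(cohort)), function(i) {
    rec <- simulate_patient(cohort$patient[i], cohort$durations[[i]],
                            n_pairs, n_pathological, rate, specs,
                            seed = seeds[[i]])
    bp <- to_bipolar(rec)
    sliding_windows(bp, window_s, step_s, context_s = context_s)
  })
  win <- dplyr::bind_rows(out)
  win$window_id <- seq_len(nrow(win))
  attr(win, "rate") <- rate
  win
}
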