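#' Multichannel recording container
#'
#' Constructs the in-memory representation of a (S)EEG recording: a
#' samples-by-channels numeric matrix with a sampling rate, channel labels,
#' seizure annotations, and per-channel resection / exclusion flags.  All
#' channels must have equal length and every annotation must lie within the
#' record with onset before termination.
#'
#' @param samples Numeric matrix, one column per channel.
#' @param rate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per column.
#' @param annotations A data frame with numeric columns `onset` and
#'   `termination` (seconds from record start), one row per seizure.
#' @param resected Logical per channel: lies in the surgical resection
#'   (ground-truth pathological).
#' @param excluded Logical per channel: artifact channel to drop.
#' @param patient Optional patient identifier.
#'
#' @return An object of class `seeg_recording`.
#' @export
new_recording <- function(samples, rate, channel_labels,
                          annotations = NULL, resected = NULL,
                          excluded = NULL, patient = NA_character_) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  dimnames(samples) <- NULL
  nc <- ncol(samples)
  stopifnot(rate > 0, length(channel_labels) == nc)
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  resected <- resected %||% rep(FALSE, nc)
  excluded <- excluded %||% rep(FALSE, nc)
  stopifnot(length(resected) == nc, length(excluded) == nc)
  dur <- nrow(samples) / rate
  ann <- if (is.null(annotations) || nrow(as.data.frame(annotations)) == 0) {
    tibble(onset = numeric(), termination = numeric())
  } else {
    a <- as_tibble(as.data.frame(annotations))
    stopifnot(all(c("onset", "termination") %in% names(a)))
    if (any(a$onset >= a$termination)) {
      stop("every annotation needs onset < termination", call. = FALSE)
    }
    if (any(a$onset < 0) || any(a$termination > dur + 1e-9)) {
      stop("annotation outside the record (duration ", round(dur, 3), " s)",
           call. = FALSE)
    }
    a[c("onset", "termination")]
  }
  structure(list(samples = samples, rate = rate,
                 channel_labels = as.character(channel_labels),
                 annotations = ann,
                 resected = as.logical(resected),
                 excluded = as.logical(excluded),
                 patient = patient),
            class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat("<seeg_recording> ", ncol(x$samples), " channels x ",
      nrow(x$samples), " samples @ ", x$rate, " Hz (",
      round(nrow(x$samples) / x$rate, 2), " s)\n",
      "  seizures: ", nrow(x$annotations),
      "; resected channels: ", sum(x$resected),
      "; excluded: ", sum(x$excluded), "\n", sep = "")
  invisible(x)
}

#' Read a recording from EDF or delimited text
#'
#' Loads a multichannel recording from a European Data Format file or from
#' delimited text (CSV/TSV, one column per channel, header row = channel
#' labels).  Metadata that the file format cannot carry --- sampling rate
#' for delimited files, seizure annotations, resected and excluded channel
#' lists, bipolar pairs --- is supplied through a sidecar YAML config, given
#' either as a path or a named list.  When `config` is `NULL` and a file
#' `<path>.yaml` exists next to the recording, it is used automatically.
#'
#' @param path Path to the recording file.
#' @param format `"auto"` (by extension), `"edf"` or `"delimited"`.
#' @param config Sidecar config: path to a YAML file or a named list with
#'   any of `rate`, `patient`, `annotations` (list of `{onset,
#'   termination}`), `resected` (channel labels), `excluded` (channel
#'   labels).
#'
#' @return A [new_recording()] object.  If the sidecar defines
#'   `bipolar_pairs`, they are attached as `attr(rec, "bipolar_pairs")`.
#' @export
load_recording <- function(path, format = c("auto", "edf", "delimited"),
                           config = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  cfg <- load_sidecar(path, config)
  if (format == "edf") {
    raw <- read_edf(path)
    samples <- raw$samples
    labels <- raw$channel_labels
    rate <- cfg$rate %||% raw$rate
  } else {
    df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                            check.names = FALSE)
    if (!all(vapply(df, is.numeric, logical(1)))) {
      stop("delimited recording must be all-numeric below the header",
           call. = FALSE)
    }
    samples <- as.matrix(df)
    labels <- colnames(df)
    rate <- cfg$rate
    if (is.null(rate)) {
      stop("delimited recordings need `rate` in the sidecar config",
           call. = FALSE)
    }
  }
  ann <- if (!is.null(cfg$annotations)) {
    dplyr::bind_rows(lapply(cfg$annotations, as.data.frame))
  }
  to_flags <- function(lbls) {
    if (is.null(lbls)) return(NULL)
    unknown <- setdiff(lbls, labels)
    if (length(unknown)) {
      stop("sidecar names unknown channel(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    labels %in% lbls
  }
  rec <- new_recording(samples, rate, labels, annotations = ann,
                       resected = to_flags(cfg$resected),
                       excluded = to_flags(cfg$excluded),
                       patient = cfg$patient %||% NA_character_)
  if (!is.null(cfg$bipolar_pairs)) {
    attr(rec, "bipolar_pairs") <- parse_pairs(cfg$bipolar_pairs)
  }
  rec
}

load_sidecar <- function(path, config) {
  if (is.list(config)) return(config)
  if (is.character(config)) return(yaml::read_yaml(config))
  side <- paste0(path, ".yaml")
  if (file.exists(side)) yaml::read_yaml(side) else list()
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

# Accept pairs as "A2-A1" strings or a two-column data frame.
parse_pairs <- function(pairs) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("anode", "cathode") %in% names(pairs)))
    return(as_tibble(pairs[c("anode", "cathode")]))
  }
  pairs <- unlist(pairs)
  parts <- strsplit(as.character(pairs), "-", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop("cannot parse bipolar pair(s): ", paste(pairs[bad], collapse = ", "),
         call. = FALSE)
  }
  tibble(anode = vapply(parts, `[`, "", 1L),
         cathode = vapply(parts, `[`, "", 2L))
}

#' Bipolar montage
#'
#' Re-references a recording to a bipolar montage: each output channel is
#' the difference anode minus cathode of a contact pair, labeled
#' `"anode-cathode"`.  Any common reference shared by the two contacts
#' cancels.  A bipolar channel is marked resected when either member
#' contact is resected (`resected_rule = "any"`, the default) or only when
#' both are (`"both"`).
#'
#' @param rec A [new_recording()] object (monopolar contacts).
#' @param pairs Contact pairs: a data frame with columns `anode` and
#'   `cathode`, a character vector like `"A2-A1"`, or `NULL` to use
#'   `attr(rec, "bipolar_pairs")` from the sidecar config.
#' @param resected_rule `"any"` or `"both"`.
#'
#' @return A `seeg_recording` in bipolar montage (annotations and patient
#'   carried over; exclusion flags all `FALSE` since excluded contacts may
#'   not enter pairs).
#' @export
to_bipolar <- function(rec, pairs = NULL, resected_rule = c("any", "both")) {
  resected_rule <- match.arg(resected_rule)
  stopifnot(inherits(rec, "seeg_recording"))
  pairs <- parse_pairs(pairs %||% attr(rec, "bipolar_pairs") %||%
                         stop("no bipolar pairs given", call. = FALSE))
  idx <- function(lbl) {
    i <- match(lbl, rec$channel_labels)
    if (anyNA(i)) {
      stop("unknown channel label(s): ",
           paste(lbl[is.na(i)], collapse = ", "), call. = FALSE)
    }
    i
  }
  a <- idx(pairs$anode)
  c_ <- idx(pairs$cathode)
  if (any(rec$excluded[a]) || any(rec$excluded[c_])) {
    stop("bipolar pair references an excluded channel", call. = FALSE)
  }
  out <- rec$samples[, a, drop = FALSE] - rec$samples[, c_, drop = FALSE]
  res <- if (resected_rule == "any") {
    rec$resected[a] | rec$resected[c_]
  } else {
    rec$resected[a] & rec$resected[c_]
  }
  new_recording(out, rec$rate, paste0(pairs$anode, "-", pairs$cathode),
                annotations = rec$annotations, resected = res,
                patient = rec$patient)
}

#' Cut a recording into overlapping analysis windows
#'
#' Slides a fixed-length window across each seizure annotation (or the
#' whole record) with a fixed step, for every channel.  A span of `span`
#' seconds yields `floor((span - window_s) / step_s) + 1` windows per
#' channel.  Each window is extracted with up to `context_s` seconds of
#' symmetric context on each side (for wavelet edge control, trimmed after
#' the transform); where the record ends the context is zero-padded so
#' `pad_left` / `pad_right` always equal `context_s * rate` samples.
#'
#' @param rec A [new_recording()] object.
#' @param window_s Window length in seconds.
#' @param step_s Step between window onsets in seconds (> 0).
#' @param within `"annotations"` cuts windows inside each seizure mark,
#'   `"whole_record"` across the full record.
#' @param context_s Context padding per side in seconds.
#' @param on_short `"error"` (default) fails when a span is shorter than
#'   one window; `"skip"` returns no windows for that span.
#'
#' @return A tibble with columns `window_id`, `patient`, `channel`,
#'   `label` (`"pathological"` iff the channel is resected), `seizure`,
#'   `start_s`, `duration_s`, `samples` (list-column), `pad_left`,
#'   `pad_right`; sampling rate in `attr(, "rate")`.
#' @export
sliding_windows <- function(rec, window_s = 10, step_s = 2,
                            within = c("annotations", "whole_record"),
                            context_s = 2, on_short = c("error", "skip")) {
  within <- match.arg(within)
  on_short <- match.arg(on_short)
  stopifnot(inherits(rec, "seeg_recording"), window_s > 0)
  if (step_s <= 0) stop("step_s must be positive", call. = FALSE)
  rate <- rec$rate
  total_s <- nrow(rec$samples) / rate
  spans <- if (within == "annotations") {
    if (nrow(rec$annotations) == 0) {
      stop("recording has no seizure annotations", call. = FALSE)
    }
    rec$annotations
  } else {
    tibble(onset = 0, termination = total_s)
  }
  short <- spans$termination - spans$onset < window_s - 1e-9
  if (any(short)) {
    if (on_short == "error") {
      stop("seizure span(s) shorter than one window: ",
           paste(which(short), collapse = ", "), call. = FALSE)
    }
    spans <- spans[!short, , drop = FALSE]
  }
  wlen <- round(window_s * rate)
  ctx <- round(context_s * rate)
  n_total <- nrow(rec$samples)
  use <- which(!rec$excluded)
  rows <- list()
  wid <- 0L
  for (si in seq_len(nrow(spans))) {
    span <- spans$termination[si] - spans$onset[si]
    n_win <- floor((span - window_s) / step_s + 1e-9) + 1
    starts <- spans$onset[si] + (seq_len(n_win) - 1) * step_s
    for (ch in use) {
      lab <- if (rec$resected[ch]) "pathological" else "normal"
      for (st in starts) {
        i0 <- round(st * rate) + 1L
        i1 <- i0 + wlen - 1L
        lo <- i0 - ctx
        hi <- i1 + ctx
        x <- numeric(hi - lo + 1L)
        src <- max(lo, 1L):min(hi, n_total)
        x[src - lo + 1L] <- rec$samples[src, ch]
        wid <- wid + 1L
        rows[[wid]] <- tibble(
          window_id = wid, patient = rec$patient,
          channel = rec$channel_labels[ch], label = lab, seizure = si,
          start_s = st, duration_s = window_s,
          samples = list(x), pad_left = ctx, pad_right = ctx)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(window_id = integer(), patient = character(), channel = character(),
           label = character(), seizure = integer(), start_s = numeric(),
           duration_s = numeric(), samples = list(),
           pad_left = integer(), pad_right = integer())
  }
  attr(out, "rate") <- rate
  out
}
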