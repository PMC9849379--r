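# Minimal European Data Format (EDF) support: continuous recordings,
# 16-bit integer samples, identical sampling rate across signals.  Covers
# the plain-EDF subset needed for multichannel EEG exchange; EDF+
# discontinuous records and embedded annotations are out of scope.

edf_field <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", width)))
}

edf_num <- function(con, width) as.numeric(edf_field(con, width))

#' Read a continuous EDF recording
#'
#' Parses a plain EDF file: the fixed 256-byte header, the per-signal
#' header block, and the 16-bit little-endian sample records, which are
#' rescaled to physical units via each signal's digital/physical ranges.
#' All signals must share one sampling rate.
#'
#' @param path Path to the `.edf` file.
#' @return List with `samples` (matrix, samples x channels in physical
#'   units), `rate` (Hz), `channel_labels`, and `meta` (patient / recording
#'   id strings, start date and time).
#' @seealso [write_edf()] for the matching writer, [load_recording()] for
#'   the high-level entry point.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  if (version != "0") stop("not an EDF file (version field '", version, "')",
                           call. = FALSE)
  patient <- edf_field(con, 80)
  recording <- edf_field(con, 80)
  startdate <- edf_field(con, 8)
  starttime <- edf_field(con, 8)
  header_bytes <- edf_num(con, 8)
  reserved <- edf_field(con, 44)
  n_records <- edf_num(con, 8)
  record_dur <- edf_num(con, 8)
  ns <- as.integer(edf_num(con, 4))
  if (is.na(ns) || ns < 1) stop("EDF header declares no signals", call. = FALSE)
  if (is.na(record_dur) || record_dur <= 0) {
    stop("EDF header missing the record duration (needed for the sampling rate)",
         call. = FALSE)
  }
  rd <- function(width) vapply(seq_len(ns), function(i) edf_field(con, width), "")
  labels <- rd(16)
  rd(80)                       # transducer
  rd(8)                        # physical dimension
  phys_min <- as.numeric(rd(8))
  phys_max <- as.numeric(rd(8))
  dig_min <- as.numeric(rd(8))
  dig_max <- as.numeric(rd(8))
  rd(80)                       # prefiltering
  spr <- as.integer(rd(8))     # samples per record, per signal
  rd(32)                       # reserved
  if (length(unique(spr)) != 1L) {
    stop("signals with different sampling rates are not supported",
         call. = FALSE)
  }
  rate <- spr[1] / record_dur
  n_rec <- as.integer(n_records)
  raw <- readBin(con, "integer", n = n_rec * ns * spr[1], size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) != n_rec * ns * spr[1]) {
    stop("EDF data section truncated (channel lengths inconsistent with header)",
         call. = FALSE)
  }
  # records are blocks of [signal1 x spr, signal2 x spr, ...]
  arr <- array(as.double(raw), dim = c(spr[1], ns, n_rec))
  samples <- matrix(0, n_rec * spr[1], ns)
  for (s in seq_len(ns)) samples[, s] <- as.vector(arr[, s, ])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (s in seq_len(ns)) {
    samples[, s] <- (samples[, s] - dig_min[s]) * scale[s] + phys_min[s]
  }
  list(samples = samples, rate = rate, channel_labels = labels,
       meta = list(patient = patient, recording = recording,
                   startdate = startdate, starttime = starttime))
}

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a continuous EDF recording
#'
#' Writes a samples-by-channels matrix as a plain EDF file, quantizing each
#' channel to the 16-bit digital range over its own physical min/max.  The
#' matrix is cut into one-second data records; trailing samples that do not
#' fill a record are dropped (with a warning).
#'
#' @param path Output path.
#' @param samples Numeric matrix, samples x channels.
#' @param rate Sampling rate in Hz (integer samples per one-second record).
#' @param channel_labels One label per channel.
#' @param patient,recording Free-text EDF identification fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, samples, rate, channel_labels,
                      patient = "X", recording = "synthetic") {
  samples <- as.matrix(samples)
  ns <- ncol(samples)
  stopifnot(length(channel_labels) == ns, rate == round(rate), rate >= 1)
  spr <- as.integer(rate)
  n_rec <- nrow(samples) %/% spr
  if (n_rec < 1) stop("recording shorter than one 1 s data record", call. = FALSE)
  if (n_rec * spr != nrow(samples)) {
    warning("dropping ", nrow(samples) - n_rec * spr,
            " trailing samples that do not fill a record")
  }
  phys_min <- apply(samples, 2, min)
  phys_max <- apply(samples, 2, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width) {
    writeBin(charToRaw(pad_field(x, width)), con)
  }
  put("0", 8); put(patient, 80); put(recording, 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(256 + ns * 256, 8); put("", 44)
  put(n_rec, 8); put(1, 8); put(ns, 4)
  for (l in channel_labels) put(l, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (v in phys_min) put(format(signif(v, 7), trim = TRUE), 8)
  for (v in phys_max) put(format(signif(v, 7), trim = TRUE), 8)
  for (i in seq_len(ns)) put(dig_min, 8)
  for (i in seq_len(ns)) put(dig_max, 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(spr, 8)
  for (i in seq_len(ns)) put("", 32)
  # re-read the header's physical ranges exactly as a reader will see them,
  # so the round trip quantizes against the stored (7-digit) values
  pmin_r <- as.numeric(format(signif(phys_min, 7), trim = TRUE))
  pmax_r <- as.numeric(format(signif(phys_max, 7), trim = TRUE))
  dig <- matrix(0L, nrow(samples), ns)
  for (s in seq_len(ns)) {
    d <- (samples[, s] - pmin_r[s]) / (pmax_r[s] - pmin_r[s])
    dig[, s] <- as.integer(round(d * (dig_max - dig_min) + dig_min))
  }
  dig <- pmin(pmax(dig, dig_min), dig_max)
  for (r in seq_len(n_rec)) {
    block <- dig[((r - 1) * spr + 1):(r * spr), , drop = FALSE]
    writeBin(as.integer(as.vector(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}
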