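# Text-based serialization: datasets as long-form CSV + YAML metadata,
# model checkpoints as YAML config + CSV weight tables.  Everything written
# is plain text so artifacts survive source-only transport.

#' Write / read a CV-PAC image dataset
#'
#' `write_cvpac_dataset()` stores a dataset tibble as two plain-text files
#' in `dir`: `images.csv`, one row per pixel (window identifiers, label,
#' frequency-pair centers, real and imaginary part), and `meta.yaml` with
#' the frequency grid.  `read_cvpac_dataset()` reconstructs the tibble with
#' `cvpac_image` objects.
#'
#' @param data Dataset tibble with `window_id`, `patient`, `channel`,
#'   `label` and `image` columns.
#' @param dir Output directory (created if missing).
#' @return `write_cvpac_dataset()` returns `dir` invisibly;
#'   `read_cvpac_dataset()` returns the dataset tibble.
#' @export
write_cvpac_dataset <- function(data, dir) {
  stopifnot(all(c("window_id", "patient", "channel", "label", "image") %in%
                  names(data)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- data$image[[1]]$grid
  long <- purrr::map(seq_len(nrow(data)), function(i) {
    px <- tidy(data$image[[i]])
    px$window_id <- data$window_id[i]
    px$patient <- data$patient[i]
    px$channel <- data$channel[i]
    px$label <- data$label[i]
    px
  })
  long <- dplyr::bind_rows(long)
  utils::write.csv(long[c("window_id", "patient", "channel", "label",
                          "low_center", "high_center", "real", "imag")],
                   file.path(dir, "images.csv"), row.names = FALSE)
  yaml::write_yaml(list(low_edges = as.numeric(g$low_edges),
                        high_edges = as.numeric(g$high_edges),
                        n_bins = g$n_bins),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_cvpac_dataset
#' @export
read_cvpac_dataset <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  n_low <- length(meta$low_edges) - 1L
  n_high <- length(meta$high_edges) - 1L
  g <- frequency_grid(range(meta$low_edges), range(meta$high_edges),
                      n_low, n_high, meta$n_bins)
  long <- utils::read.csv(file.path(dir, "images.csv"))
  out <- long |>
    group_by(.data$window_id, .data$patient, .data$channel, .data$label) |>
    tidyr::nest() |>
    ungroup()
  out$image <- purrr::map(seq_len(nrow(out)), function(i) {
    px <- out$data[[i]]
    ord <- order(match(px$low_center, sort(unique(px$low_center))),
                 match(px$high_center, sort(unique(px$high_center))))
    pixels <- matrix(complex(real = px$real[ord], imaginary = px$imag[ord]),
                     n_high, n_low)
    new_cvpac_image(pixels, g,
                    provenance = list(window_id = as.character(out$window_id[i]),
                                      channel = out$channel[i],
                                      patient = out$patient[i],
                                      label = out$label[i]))
  })
  out$data <- NULL
  out
}

#' Write / read a trained network checkpoint
#'
#' Stores a [cvcnn_train()] model as plain text in `dir`: `config.yaml`
#' (architecture, recipe, seed, class map), `weights.csv` (one row per
#' scalar parameter: parameter name, linear index, value), `bn_states.csv`
#' (batch-normalization running statistics) and `training_log.csv`.
#'
#' @param model A `cvcnn_model`.
#' @param dir Output directory.
#' @return `write_cvcnn()` returns `dir` invisibly; `read_cvcnn()` the
#'   reconstructed model.
#' @export
write_cvcnn <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$cfg
  yaml::write_yaml(c(unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
                     list(input_shape = as.integer(model$input_shape),
                          class_map = model$class_map)),
                   file.path(dir, "config.yaml"))
  pars <- cvcnn_flatten(model)
  wt <- dplyr::bind_rows(purrr::imap(pars, function(v, nm) {
    tibble(param = nm, index = seq_along(v), value = as.vector(v))
  }))
  utils::write.csv(wt, file.path(dir, "weights.csv"), row.names = FALSE)
  bn <- dplyr::bind_rows(purrr::imap(model$bn_states, function(s, l) {
    dplyr::bind_rows(purrr::imap(s, function(v, nm) {
      tibble(layer = l, stat = nm, index = seq_along(v), value = v)
    }))
  }))
  utils::write.csv(bn, file.path(dir, "bn_states.csv"), row.names = FALSE)
  utils::write.csv(model$training_log, file.path(dir, "training_log.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cvcnn
#' @export
read_cvcnn <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  input_shape <- meta$input_shape
  class_map <- meta$class_map
  cfg_args <- meta[setdiff(names(meta), c("input_shape", "class_map",
                                          "field"))]
  cfg <- do.call(cvcnn_config, cfg_args[names(cfg_args) %in%
                                          names(formals(cvcnn_config))])
  old <- get_rng_state()
  model <- init_cvcnn(cfg, input_shape)
  restore_rng_state(old)
  wt <- utils::read.csv(file.path(dir, "weights.csv"))
  pars <- cvcnn_flatten(model)
  for (nm in names(pars)) {
    v <- wt$value[wt$param == nm]
    stopifnot(length(v) == length(pars[[nm]]))
    pars[[nm]][] <- v
  }
  model <- cvcnn_restore(model, pars)
  bn <- utils::read.csv(file.path(dir, "bn_states.csv"))
  for (l in unique(bn$layer)) {
    for (nm in unique(bn$stat[bn$layer == l])) {
      model$bn_states[[l]][[nm]] <-
        bn$value[bn$layer == l & bn$stat == nm]
    }
  }
  log_path <- file.path(dir, "training_log.csv")
  if (file.exists(log_path)) {
    model$training_log <- as_tibble(utils::read.csv(log_path))
  }
  model$class_map <- class_map
  model
}

#' Write a recording as delimited text plus sidecar config
#'
#' Writes the channels of a recording as a CSV (header = labels) and a
#' YAML sidecar (`<path>.yaml`) carrying the sampling rate, annotations,
#' resected/excluded channel lists and any bipolar pairs, so
#' [load_recording()] can reconstruct the full object.
#'
#' @param rec A [new_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "seeg_recording"))
  df <- as.data.frame(rec$samples)
  names(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  cfg <- list(rate = rec$rate, patient = rec$patient)
  if (nrow(rec$annotations)) {
    cfg$annotations <- purrr::map(seq_len(nrow(rec$annotations)), function(i) {
      list(onset = rec$annotations$onset[i],
           termination = rec$annotations$termination[i])
    })
  }
  if (any(rec$resected)) cfg$resected <- rec$channel_labels[rec$resected]
  if (any(rec$excluded)) cfg$excluded <- rec$channel_labels[rec$excluded]
  bp <- attr(rec, "bipolar_pairs")
  if (!is.null(bp)) cfg$bipolar_pairs <- paste0(bp$anode, "-", bp$cathode)
  yaml::write_yaml(cfg, paste0(path, ".yaml"))
  invisible(path)
}
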