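#' Aggregate window predictions into per-channel scores
#'
#' A channel is scored by the fraction of its windows predicted
#' pathological.  With `decision_rule = "argmax"` (default) each window
#' votes by its most probable class (probability > 0.5); `"mean_prob"`
#' instead averages the pathological probability over the channel's
#' windows.
#'
#' @param predictions A tibble with columns `patient`, `channel`, `label`
#'   (window truth) and `prob_pathological` (as returned by
#'   [predict.cvcnn_model()]).
#' @param decision_rule `"argmax"` or `"mean_prob"`.
#' @return A tibble with one row per channel: `patient`, `channel`,
#'   `n_windows`, `pathological_fraction` in `[0, 1]` and `truth`
#'   (logical).
#' @export
channel_scores <- function(predictions, decision_rule = c("argmax", "mean_prob")) {
  decision_rule <- match.arg(decision_rule)
  stopifnot(all(c("patient", "channel", "label", "prob_pathological") %in%
                  names(predictions)))
  predictions |>
    group_by(.data$patient, .data$channel) |>
    summarise(
      n_windows = dplyr::n(),
      pathological_fraction = if (decision_rule == "argmax") {
        mean(.data$prob_pathological > 0.5)
      } else {
        mean(.data$prob_pathological)
      },
      truth = any(.data$label == "pathological"),
      .groups = "drop")
}

#' ROC curve and AUC over channel scores
#'
#' Sweeps a decision threshold over the observed per-channel pathological
#' fractions (a channel is called pathological when its fraction exceeds
#' the threshold), computes sensitivity/specificity at every threshold,
#' the trapezoidal area under the ROC curve, and the optimal threshold by
#' Youden's J (`sensitivity + specificity - 1`, ties resolved toward the
#' lower threshold).
#'
#' @param scores A tibble from [channel_scores()] (needs
#'   `pathological_fraction` and logical `truth`), or any tibble with those
#'   columns.
#' @return An object of class `roc_result`: list with `curve` (tibble:
#'   threshold, sensitivity, specificity), `auc`, `optimal_threshold`,
#'   `sensitivity_at_optimal`, `specificity_at_optimal`, `n_positive`,
#'   `n_negative`.
#' @export
roc_auc <- function(scores) {
  stopifnot(all(c("pathological_fraction", "truth") %in% names(scores)))
  x <- scores$pathological_fraction
  y <- as.logical(scores$truth)
  if (length(unique(y)) < 2) {
    stop("both truth classes must be present to form a ROC curve",
         call. = FALSE)
  }
  thr <- c(-Inf, sort(unique(x)))
  sens <- vapply(thr, function(t) mean(x[y] > t), 0)
  spec <- vapply(thr, function(t) mean(x[!y] <= t), 0)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (head(sens[ord], -1) + tail(sens[ord], -1)) / 2)
  auc <- abs(auc)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]          # thresholds ascend: first = lowest
  structure(list(curve = tibble(threshold = thr, sensitivity = sens,
                                specificity = spec),
                 auc = auc,
                 optimal_threshold = thr[best],
                 sensitivity_at_optimal = sens[best],
                 specificity_at_optimal = spec[best],
                 n_positive = sum(y), n_negative = sum(!y)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC ", round(x$auc, 4), " (", x$n_positive, " pos / ",
      x$n_negative, " neg); optimal threshold ",
      signif(x$optimal_threshold, 3), ": sens ",
      round(x$sensitivity_at_optimal, 3), ", spec ",
      round(x$specificity_at_optimal, 3), "\n", sep = "")
  invisible(x)
}

# ---- classifiers -----------------------------------------------------------

flat_features <- function(images, representation) {
  arr <- to_two_layer_real(images,
                           if (representation == "strength") "strength"
                           else "two_layer")
  d <- dim(arr)
  t(matrix(arr, prod(d[1:3]), d[4]))
}

fit_classifier <- function(train, method, config, svm_params, rf_trees) {
  labels <- factor(train$label, levels = c("normal", "pathological"))
  if (method %in% c("cvcnn", "cnn")) {
    model <- cvcnn_train(train, config)
    return(list(method = method, model = model))
  }
  rep_ <- config$representation
  feats <- flat_features(train$image, rep_)
  if (method == "svm") {
    fit <- e1071::svm(feats, labels, kernel = "radial",
                      cost = svm_params$cost, gamma = svm_params$gamma,
                      probability = TRUE)
    return(list(method = "svm", model = fit, representation = rep_))
  }
  if (method == "rf") {
    fit <- randomForest::randomForest(feats, labels, ntree = rf_trees)
    return(list(method = "rf", model = fit, representation = rep_))
  }
  stop("unknown method: ", method, call. = FALSE)
}

predict_prob <- function(clf, data) {
  if (clf$method %in% c("cvcnn", "cnn")) {
    return(predict(clf$model, data)$prob_pathological)
  }
  feats <- flat_features(data$image, clf$representation)
  if (clf$method == "svm") {
    p <- attr(predict(clf$model, feats, probability = TRUE), "probabilities")
    return(p[, "pathological"])
  }
  predict(clf$model, feats, type = "prob")[, "pathological"]
}

#' Leave-one-patient-out cross-validation
#'
#' Evaluates channel-level classification by leave-one-subject-out
#' rotation: for each patient, a classifier is trained on every other
#' patient's images and the held-out patient's windows are scored; window
#' predictions are aggregated to channel fractions and a per-patient ROC
#' is computed.  The summary AUC is the unweighted mean over patients.
#'
#' Methods: `"cvcnn"` (complex-valued CNN on complex images), `"cnn"`
#' (real CNN on the representation in `config`), `"svm"` and `"rf"`
#' (radial-kernel support vector machine / random forest on flattened
#' per-part features).  A patient whose channels are single-class is
#' reported with `auc = NA` and excluded from the mean, with a warning.
#'
#' @param data Dataset tibble: columns `patient`, `channel`, `label`,
#'   `image` (and `window_id`).
#' @param method `"cvcnn"`, `"cnn"`, `"svm"` or `"rf"`.
#' @param config A [cvcnn_config()]; also supplies the input
#'   representation for `"svm"`/`"rf"` features.
#' @param decision_rule Passed to [channel_scores()].
#' @param svm_params List with `cost` and `gamma` for `"svm"`.
#' @param rf_trees Number of random-forest trees.
#' @param transform_images Optional function `(train_tbl, test_tbl) ->
#'   list(train, test)` applied per round before fitting (used for band
#'   ablation, where replacement statistics must come from the training
#'   split only).
#' @param verbose Print per-round progress.
#' @return An object of class `loocv_result`: list with `by_patient`
#'   (tibble: patient, auc, n_channels, optimal threshold,
#'   sensitivity/specificity), `mean_auc`, `rocs` (per-patient
#'   `roc_result`s), `scores` (all channel scores) and `method`.
#' @export
loocv <- function(data, method = c("cvcnn", "cnn", "svm", "rf"),
                  config = cvcnn_config_small(),
                  decision_rule = c("argmax", "mean_prob"),
                  svm_params = list(cost = 2^18, gamma = 2^2),
                  rf_trees = 100, transform_images = NULL, verbose = FALSE) {
  method <- match.arg(method)
  decision_rule <- match.arg(decision_rule)
  stopifnot(all(c("patient", "channel", "label", "image") %in% names(data)))
  if (method == "cvcnn" && config$representation != "complex") {
    stop("method 'cvcnn' needs representation = 'complex'", call. = FALSE)
  }
  if (method == "cnn" && config$representation == "complex") {
    stop("method 'cnn' needs a real representation ",
         "('two_layer' or 'strength')", call. = FALSE)
  }
  patients <- unique(data$patient)
  if (length(patients) < 2) stop("need at least 2 patients", call. = FALSE)
  rows <- list()
  rocs <- list()
  all_scores <- list()
  for (p in patients) {
    train <- data[data$patient != p, , drop = FALSE]
    test <- data[data$patient == p, , drop = FALSE]
    if (!is.null(transform_images)) {
      tt <- transform_images(train, test)
      train <- tt$train
      test <- tt$test
    }
    clf <- fit_classifier(train, method, config, svm_params, rf_trees)
    test$prob_pathological <- predict_prob(clf, test)
    sc <- channel_scores(test, decision_rule)
    all_scores[[p]] <- sc
    roc <- if (length(unique(sc$truth)) < 2) {
      warning("patient ", p, " has single-class channels; excluded from AUC",
              call. = FALSE)
      NULL
    } else {
      roc_auc(sc)
    }
    rocs[[p]] <- roc
    rows[[p]] <- tibble(
      patient = p,
      n_channels = nrow(sc),
      auc = if (is.null(roc)) NA_real_ else roc$auc,
      optimal_threshold = if (is.null(roc)) NA_real_ else roc$optimal_threshold,
      sensitivity = if (is.null(roc)) NA_real_ else roc$sensitivity_at_optimal,
      specificity = if (is.null(roc)) NA_real_ else roc$specificity_at_optimal)
    if (verbose) {
      message("held-out ", p, ": AUC ",
              if (is.null(roc)) "NA" else round(roc$auc, 4))
    }
  }
  by_patient <- dplyr::bind_rows(rows)
  structure(list(by_patient = by_patient,
                 mean_auc = mean(by_patient$auc, na.rm = TRUE),
                 rocs = rocs, scores = dplyr::bind_rows(all_scores),
                 method = method, decision_rule = decision_rule),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("<loocv_result> method ", x$method, ", ", nrow(x$by_patient),
      " patients, mean AUC ", round(x$mean_auc, 4), "\n", sep = "")
  print(as.data.frame(x$by_patient), row.names = FALSE)
  invisible(x)
}

#' Band-ablation experiment
#'
#' Repeats the leave-one-patient-out evaluation with one frequency band of
#' every image replaced by moment-matched random values, quantifying how
#' much the band contributes to classification.  Within each round the
#' replacement mean/variance are computed from the training split only and
#' applied to both splits (no test leakage).
#'
#' @inheritParams loocv
#' @param band_name A low-frequency band name, see [band_mask()].
#' @param seed Integer seed for the random replacement values.
#' @param reference Optional unablated [loocv()] result to report the AUC
#'   drop against (avoids recomputing it).
#' @param ... Passed to [loocv()].
#' @return A list with `band`, `loocv` (the ablated run), `mean_auc`,
#'   `reference_auc` and `auc_drop` (NA when no reference given).
#' @export
run_ablation_experiment <- function(data, band_name, method = "cvcnn",
                                    config = cvcnn_config_small(),
                                    seed = 1L, reference = NULL, ...) {
  grid <- data$image[[1]]$grid
  mask <- band_mask(grid, band_name)
  transform <- function(train, test) {
    mom <- ablation_moments(train$image, mask)
    seeds <- child_seeds(seed, nrow(train) + nrow(test))
    train$image <- purrr::map(seq_len(nrow(train)), function(i) {
      ablate_band(train$image[[i]], mask, seed = seeds[[i]], moments = mom)
    })
    test$image <- purrr::map(seq_len(nrow(test)), function(i) {
      ablate_band(test$image[[i]], mask, seed = seeds[[nrow(train) + i]],
                  moments = mom)
    })
    list(train = train, test = test)
  }
  res <- loocv(data, method, config, transform_images = transform, ...)
  ref_auc <- if (is.null(reference)) NA_real_ else reference$mean_auc
  list(band = band_name, loocv = res, mean_auc = res$mean_auc,
       reference_auc = ref_auc, auc_drop = ref_auc - res$mean_auc)
}

#' Restrict every image of a dataset to one high-frequency band
#'
#' Applies [restrict_rows()] to each image --- the LFO-gamma / LFO-HFO
#' experiments, in which only part of the amplitude-frequency axis is kept.
#'
#' @param data Dataset tibble with an `image` column.
#' @param band_name `"gamma"` or `"hfo"`.
#' @return The dataset with reduced images.
#' @export
restrict_dataset <- function(data, band_name) {
  mask <- band_mask(data$image[[1]]$grid, band_name)
  data$image <- purrr::map(data$image, restrict_rows, mask = mask)
  data
}

#' Real-valued baseline classifiers
#'
#' Runs the leave-one-patient-out evaluation for the comparison methods:
#' a real-valued CNN on two-layer (real/imaginary) or strength-only
#' images, or an SVM / random forest on the flattened per-part features.
#'
#' @inheritParams loocv
#' @param kind `"real_cnn"`, `"svm"` or `"rf"`.
#' @param representation `"two_layer"` or `"strength"`.
#' @param config Optional [cvcnn_config()] for `"real_cnn"`; defaults to
#'   [cvcnn_config_small()] with the requested representation.
#' @param ... Passed to [loocv()].
#' @return A `loocv_result`.
#' @export
baseline <- function(data, kind = c("real_cnn", "svm", "rf"),
                     representation = c("two_layer", "strength"),
                     config = NULL, ...) {
  kind <- match.arg(kind)
  representation <- match.arg(representation)
  config <- config %||% cvcnn_config_small(representation = representation)
  if (config$representation != representation) {
    config$representation <- representation
    config$field <- "real"
    config$readout <- "real"
  }
  method <- switch(kind, real_cnn = "cnn", svm = "svm", rf = "rf")
  loocv(data, method, config, ...)
}

#' Grid search for the SVM baseline
#'
#' Fits a radial-kernel SVM for every (cost, gamma) pair of the given
#' grids on the training split and returns the pair maximizing the
#' channel-level AUC on the validation split.
#'
#' @param train,validation Dataset tibbles with `image`, `label`,
#'   `channel`, `patient` columns.
#' @param costs,gammas Candidate grids (defaults: powers of two,
#'   `2^2 ... 2^20` by factor 16 and `2^-10 ... 2^10` by factor 4).
#' @param representation `"two_layer"` or `"strength"`.
#' @return A list with `cost`, `gamma`, `auc` of the best pair, and a
#'   tibble `results` with the AUC of every pair.
#' @export
svm_grid_search <- function(train, validation,
                            costs = 2^seq(2, 20, by = 4),
                            gammas = 2^seq(-10, 10, by = 2),
                            representation = c("two_layer", "strength")) {
  representation <- match.arg(representation)
  feats <- flat_features(train$image, representation)
  labels <- factor(train$label, levels = c("normal", "pathological"))
  vfeats <- flat_features(validation$image, representation)
  rows <- list()
  for (cost in costs) {
    for (gamma in gammas) {
      fit <- e1071::svm(feats, labels, kernel = "radial", cost = cost,
                        gamma = gamma, probability = TRUE)
      p <- attr(predict(fit, vfeats, probability = TRUE),
                "probabilities")[, "pathological"]
      v <- validation
      v$prob_pathological <- p
      sc <- channel_scores(v)
      auc <- if (length(unique(sc$truth)) < 2) NA_real_ else roc_auc(sc)$auc
      rows[[length(rows) + 1L]] <- tibble(cost = cost, gamma = gamma,
                                          auc = auc)
    }
  }
  results <- dplyr::bind_rows(rows)
  best <- results[which.max(results$auc), ]
  list(cost = best$cost, gamma = best$gamma, auc = best$auc,
       results = results)
}
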