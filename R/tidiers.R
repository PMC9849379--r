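#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_abline facet_wrap labs scale_fill_viridis_c scale_fill_gradient2
#'   theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Tidy a CV-PAC image into a pixel table
#'
#' One row per comodulogram pixel: the frequency-pair centers, coupling
#' strength, coupled phase, and the real/imaginary parts --- the long form
#' used for CSV export and plotting.
#'
#' @param x A `cvpac_image`.
#' @param ... Unused.
#' @return A tibble with columns `low_center`, `high_center`, `strength`,
#'   `phase`, `real`, `imag`.
#' @export
tidy.cvpac_image <- function(x, ...) {
  g <- x$grid
  tibble(
    low_center = rep(g$low_centers, each = length(g$high_centers)),
    high_center = rep(g$high_centers, times = length(g$low_centers)),
    strength = as.vector(coupling_strengths(x)),
    phase = as.vector(coupling_phases(x)),
    real = as.vector(Re(x$pixels)),
    imag = as.vector(Im(x$pixels)))
}

#' Plot a CV-PAC image
#'
#' Two comodulogram panels: coupling strength (modulus) and coupled phase
#' (argument) over the log-spaced frequency grid.
#'
#' @param object A `cvpac_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cvpac_image <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(d, c("strength", "phase"),
                           names_to = "component", values_to = "value")
  ggplot(d, aes(factor(signif(.data$low_center, 3)),
                factor(signif(.data$high_center, 3)),
                fill = .data$value)) +
    geom_raster() +
    facet_wrap(~component, scales = "free") +
    scale_fill_viridis_c() +
    labs(x = "phase frequency (Hz)", y = "amplitude frequency (Hz)",
         fill = NULL) +
    theme_minimal()
}

#' @rdname roc_auc
#' @param x,object A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_auc
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, optimal_threshold = x$optimal_threshold,
         sensitivity = x$sensitivity_at_optimal,
         specificity = x$specificity_at_optimal,
         n_positive = x$n_positive, n_negative = x$n_negative)
}

#' @rdname roc_auc
#' @export
autoplot.roc_result <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(1 - .data$specificity, .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    geom_point(data = d[which.max(d$sensitivity + d$specificity), ],
               colour = "red") +
    coord_equal() +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' @rdname loocv
#' @param x,object A `loocv_result`.
#' @param ... Unused.
#' @export
tidy.loocv_result <- function(x, ...) x$by_patient

#' @rdname loocv
#' @export
glance.loocv_result <- function(x, ...) {
  tibble(method = x$method, n_patients = nrow(x$by_patient),
         mean_auc = x$mean_auc)
}

#' @rdname cvcnn_train
#' @param x,object A `cvcnn_model`.
#' @param ... Unused.
#' @export
tidy.cvcnn_model <- function(x, ...) x$training_log

#' @rdname cvcnn_train
#' @export
glance.cvcnn_model <- function(x, ...) {
  n_par <- sum(vapply(cvcnn_flatten(x), length, 0L))
  tibble(field = x$cfg$field, representation = x$cfg$representation,
         epochs = max(x$training_log$epoch),
         final_loss = utils::tail(x$training_log$loss, 1),
         n_parameters = n_par)
}

#' @rdname cvcnn_train
#' @export
autoplot.cvcnn_model <- function(object, ...) {
  ggplot(object$training_log, aes(.data$epoch, .data$loss)) +
    geom_line() +
    labs(x = "epoch", y = "training loss") +
    theme_minimal()
}
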