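#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training history
#'
#' Loss and monitored accuracy per epoch for the training and validation
#' splits of one fold, with the best (restored) epoch marked.
#'
#' @param object A trained `pcg_model` (with `$history`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcg_model
#' @export
autoplot.pcg_model <- function(object, ...) {
  if (is.null(object$history)) stop("model has no training history", call. = FALSE)
  h <- object$history |>
    tidyr::pivot_longer(-"epoch", names_to = c("split", "quantity"),
                        names_sep = "_", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training history (dashed line: restored epoch)") +
    ggplot2::theme_minimal()
}

#' Plot an experiment's fusion-mode comparison
#'
#' Mean held-out test metric by fusion mode with +/- 1 sd error bars and
#' the per-fold points overlaid.
#'
#' @param object A `pcg_experiment`.
#' @param metric Which metric column to plot (default `"accuracy"`; use
#'   `"weighted_accuracy"` for the three-class task).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcg_experiment
#' @export
autoplot.pcg_experiment <- function(object, metric = "accuracy", ...) {
  pf <- object$per_fold
  if (!metric %in% names(pf)) stop("unknown metric: ", metric, call. = FALSE)
  agg <- pf |>
    dplyr::group_by(.data$fusion_mode) |>
    dplyr::summarise(mean = mean(.data[[metric]]),
                     sd = stats::sd(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$fusion_mode, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_jitter(data = pf,
                         ggplot2::aes(x = .data$fusion_mode,
                                      y = .data[[metric]]),
                         width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = "fusion mode", y = metric,
                  title = "Held-out test performance by fusion strategy") +
    ggplot2::theme_minimal()
}

#' Plot a feature image
#'
#' The three channels (MFCC, delta, double-delta) of one recording's
#' 64 x 64 x 3 representation as heatmaps.
#'
#' @param image A `frames x coeffs x 3` array from [make_feature_image()].
#' @return A ggplot object.
#' @export
plot_feature_image <- function(image) {
  stopifnot(length(dim(image)) == 3)
  ch_names <- c("MFCC", "delta", "double-delta")
  df <- purrr::map_dfr(1:3, function(c) {
    m <- image[, , c]
    tibble::tibble(frame = rep(seq_len(nrow(m)), ncol(m)),
                   coeff = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(m),
                   channel = factor(ch_names[c], levels = ch_names))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$coeff,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "frame", y = "coefficient", fill = NULL) +
    ggplot2::theme_minimal()
}
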