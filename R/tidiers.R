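#' Tidy the per-epoch training log of a fit
#'
#' @param x An `anatseg_fit`.
#' @param ... Unused.
#' @return Long tibble with columns `epoch, term, estimate` covering the
#'   training loss components and the validation segmentation loss.
#' @export
tidy.anatseg_fit <- function(x, ...) {
  tidyr::pivot_longer(x$log, -"epoch", names_to = "term",
                      values_to = "estimate")
}

#' One-row summary of a fit
#'
#' @param x An `anatseg_fit`.
#' @param ... Unused.
#' @return Tibble with the method, routing mode, lambda, epoch count, best
#'   epoch and best validation segmentation loss.
#' @export
glance.anatseg_fit <- function(x, ...) {
  tibble::tibble(method = x$baseline$method,
                 routing_mode = x$cfg$routing_mode,
                 lambda = x$cfg$lambda,
                 epochs = nrow(x$log),
                 best_epoch = x$best_epoch,
                 best_val_L_SEG = min(x$log$val_L_SEG))
}

#' Plot training curves of a fit
#'
#' @param object An `anatseg_fit`.
#' @param ... Unused.
#' @return A ggplot of the loss components over epochs.
#' @export
autoplot.anatseg_fit <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !is.na(.data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$estimate,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a result table
#'
#' @param object A `result_table` from [run_experiment()] or
#'   [cross_domain_report()].
#' @param ... Unused.
#' @return A ggplot with one panel per metric, methods on the x axis and
#'   mean +/- sd error bars, faceted by evaluation domain.
#' @export
autoplot.result_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$std,
                                        ymax = .data$mean + .data$std),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::facet_grid(metric ~ source_domain + eval_domain,
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
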