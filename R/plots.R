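#' Plot a change-point fit
#'
#' Signal versus measurement index with the fitted block means, a mean
#' +/- one-standard-deviation band per interval, and vertical lines at the
#' change points — the standard QC band view of a segmented series.
#'
#' @param object A `qcseg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qcseg_fit <- function(object, ...) {
  aug <- augment(object)
  aug$.index <- seq_len(nrow(aug))
  iv <- object$intervals
  p <- ggplot2::ggplot(aug, ggplot2::aes(x = .data$.index)) +
    ggplot2::geom_rect(
      data = iv,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    ) +
    ggplot2::geom_step(ggplot2::aes(y = .data$.fitted), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = object$values), size = 0.9) +
    ggplot2::labs(
      x = "measurement index", y = object$value_col,
      title = sprintf("%d change point%s (%s%s)", object$n_changepoints,
                      if (object$n_changepoints == 1) "" else "s",
                      object$score,
                      if (object$auto) ", BIC-selected" else "")
    ) +
    ggplot2::theme_minimal()
  if (object$n_changepoints > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = object$partition$change_points +
                                   0.5,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a BIC selection curve
#'
#' @param object A `qcseg_bic` from [bic_select()].
#' @param ... Unused.
#' @return A ggplot object with BIC versus the number of change points and
#'   the selected minimum marked.
#' @export
autoplot.qcseg_bic <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$m, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$curve[object$curve$m == object$m_hat, ],
                        colour = "firebrick", size = 3) +
    ggplot2::labs(x = "number of change points", y = "BIC") +
    ggplot2::theme_minimal()
}

#' Plot benchmark error curves
#'
#' Mean squared residual versus the number of change points, one curve per
#' method, averaged over the simulated datasets.
#'
#' @param object A `qcseg_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qcseg_benchmark <- function(object, ...) {
  summ <- benchmark_summary(object)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$m, y = .data$error,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of change points",
                  y = "mean squared residual", colour = "method") +
    ggplot2::theme_minimal()
}

#' Plot a simulated series with its ground truth
#'
#' @param object A `qcseg_sim` from [generate_series()].
#' @param ... Unused.
#' @return A ggplot object: simulated points, true segment means, true
#'   change points.
#' @export
autoplot.qcseg_sim <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$true_mean), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$true_change_points + 0.5,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "measurement index", y = "simulated signal") +
    ggplot2::theme_minimal()
}
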