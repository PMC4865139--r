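#' Plot a perturbation profile
#'
#' Signal-intensity track along the UTR with optional called-element
#' shading, in the style of a scanning-signal figure.
#'
#' @param profile A `perturbation_profile` tibble from [scan_utr()].
#' @param elements Optional element tibble from [call_elements()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, elements = NULL) {
  df <- profile[!is.na(profile$signal_scaled), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$signal_scaled)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$seq_id), ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "5'UTR position (nt)", y = "signal intensity (0-100)") +
    ggplot2::theme_minimal()
  if (!is.null(elements) && nrow(elements) > 0L) {
    p <- p +
      ggplot2::geom_rect(
        data = elements,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, alpha = 0.15, fill = "firebrick"
      ) +
      ggplot2::geom_text(
        data = elements,
        ggplot2::aes(x = (.data$start + .data$end) / 2, y = Inf,
                     label = .data$rank_label),
        inherit.aes = FALSE, vjust = 1.2, size = 3
      )
  }
  p
}

#' @export
autoplot.perturbation_profile <- function(object, elements = NULL, ...) {
  plot_profile(object, elements = elements)
}

#' @export
autoplot.efficiency_model <- function(object, ...) {
  xr <- if (!is.null(object$fit_log)) range(object$fit_log$delta_g) else c(-140, 0)
  grid <- tibble(delta_g = seq(xr[1], xr[2], length.out = 200))
  grid$efficiency <- predict_efficiency(object, grid$delta_g)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$delta_g, y = .data$efficiency)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(
      x = expression(Delta * G ~ "(kcal/mol)"),
      y = "relative translation efficiency (% of control)",
      title = sprintf("y = %.4g · exp(%.4g · X)", object$a, object$b)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$fit_log)) {
    pts <- object$fit_log
    pts$efficiency <- exp(pts$log_efficiency)
    p <- p + ggplot2::geom_point(data = pts, size = 2)
  }
  p
}
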