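#' Plot ROI-mean signal decay curves
#'
#' Mean signal per shell and ROI against b, with the rectified noise floor
#' as a dashed line; the layout used to inspect whether the high-b signal
#' sits above the floor (log scale) or decays through zero after debiasing
#' (linear scale).
#'
#' @param analysis An `ste_analysis` from [run_analysis()].
#' @param log_y Logarithmic y-axis (only positive means are drawn).
#' @return A ggplot object.
#' @export
plot_signal_decay <- function(analysis, log_y = FALSE) {
  stopifnot(inherits(analysis, "ste_analysis"))
  df <- analysis$shell_means |>
    dplyr::left_join(
      dplyr::select(analysis$voxel_fits, "voxel", "roi"),
      by = "voxel"
    ) |>
    dplyr::group_by(.data$roi, .data$b, .data$te) |>
    dplyr::summarise(mean = mean(.data$mean), .groups = "drop")
  if (log_y) df <- dplyr::filter(df, .data$mean > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = b_internal_to_si(.data$b), y = .data$mean, colour = .data$roi
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = noise_floor(analysis$sigma),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "b [s/mm²]", y = "signal", colour = "ROI")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.ste_analysis <- function(object, ...) {
  df <- object$voxel_fits |>
    dplyr::filter(!is.na(.data$f1_tilde), !is.na(.data$D1_tilde))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$D1_tilde, y = 100 * .data$f1_tilde, colour = .data$roi
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = expression(tilde(D)[1] ~ "[µm²/ms]"),
      y = expression(tilde(f)[1] ~ "[%]"),
      colour = "ROI"
    )
}

#' @export
autoplot.highb_fit <- function(object, ...) {
  df <- object$data
  est <- object$estimates
  bgrid <- seq(min(df$b), max(df$b), length.out = 100)
  curve <- switch(object$fit_type,
    monoexp = tibble(b = bgrid, fit = est$amplitude * exp(-bgrid * est$D1_tilde)),
    t2_joint = NULL,
    sphere = NULL
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = b_internal_to_si(.data$b), y = .data$mean
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "b [s/mm²]", y = "shell mean signal")
  if (!is.null(curve)) {
    p <- p + ggplot2::geom_line(
      data = curve,
      ggplot2::aes(x = b_internal_to_si(.data$b), y = .data$fit),
      colour = "steelblue"
    )
  }
  p
}
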