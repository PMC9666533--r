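# ggplot2 figure helpers for the main result types.

#' Plot sedimentation curves
#'
#' One line per subject, colored by group, with the cohort mean overlaid.
#'
#' @param curves Long-format curve tibble.
#' @param alpha Line transparency for individual subjects.
#' @return A ggplot object.
#' @examples
#' plot_curves(simulate_curves(10, 2, seed = 1))
#' @export
plot_curves <- function(curves, alpha = 0.3) {
  assert_curves(curves)
  mean_curve <- curves |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(h_ratio = mean(.data$h_ratio), .groups = "drop")
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$time_min, .data$h_ratio)) +
    ggplot2::geom_line(
      ggplot2::aes(
        group = .data$sample_id,
        color = if ("group" %in% names(curves)) .data$group else NULL
      ),
      alpha = alpha
    ) +
    ggplot2::geom_line(data = mean_curve, linetype = "dotted", linewidth = 1) +
    ggplot2::labs(
      x = "time (min)", y = expression(H[E] / H[T]),
      color = "group"
    ) +
    ggplot2::theme_minimal()
  p
}

#' Plot sedimentation velocity
#'
#' Mean instantaneous sedimentation velocity across subjects with a +/- 1 SD
#' ribbon.
#'
#' @param velocity Tibble from [sediment_velocity()].
#' @return A ggplot object.
#' @examples
#' plot_velocity(sediment_velocity(simulate_curves(10, 0, seed = 1)))
#' @export
plot_velocity <- function(velocity) {
  stats_df <- velocity |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(
      mean_v = mean(.data$v_e), sd_v = sd(.data$v_e),
      .groups = "drop"
    )
  ggplot2::ggplot(stats_df, ggplot2::aes(.data$time_min, .data$mean_v)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_v - .data$sd_v,
        ymax = .data$mean_v + .data$sd_v
      ),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = expression(V[E])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.esr_sweep <- function(object, metric = c("mape", "rmse"), ...) {
  metric <- match.arg(metric)
  axis <- attr(object, "axis")
  ycol <- paste0("mean_", metric)
  sdcol <- paste0("sd_", metric)
  ggplot2::ggplot(object, ggplot2::aes(
    .data[[axis]], .data[[ycol]],
    color = .data$model_id, group = .data$model_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data[[ycol]] - .data[[sdcol]],
        ymax = .data[[ycol]] + .data[[sdcol]]
      ),
      width = 0.1
    ) +
    ggplot2::labs(
      x = if (axis == "L") "sequence length (min)" else expression(N[B]),
      y = if (metric == "mape") "mean MAPE (%)" else "mean RMSE",
      color = "model"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.esr_blandaltman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 1) +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "mean of predicted and observed ESR",
      y = "predicted - observed"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.esr_comparison <- function(object, metric = "mape", ...) {
  res <- object[[metric]]
  if (is.null(res)) abort(sprintf("metric '%s' not present in the comparison.", metric))
  df <- tibble::tibble(
    model_id = names(res$friedman$mean_ranks),
    mean_rank = unname(res$friedman$mean_ranks)
  ) |>
    dplyr::arrange(.data$mean_rank) |>
    dplyr::mutate(model_id = factor(.data$model_id, levels = rev(.data$model_id)))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$mean_rank, .data$model_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data$mean_rank)),
      vjust = -1, size = 3
    ) +
    ggplot2::labs(
      x = "mean rank (lower is better)", y = NULL,
      title = sprintf(
        "Friedman p = %.2g%s", res$friedman$p_value,
        if (!is.na(res$cd)) sprintf(", CD = %.2f", res$cd) else ""
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.na(res$cd)) {
    best <- min(df$mean_rank)
    p <- p + ggplot2::geom_vline(xintercept = best + res$cd, linetype = "dashed")
  }
  p
}
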