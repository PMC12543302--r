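#' Plot a connectome as a weight heatmap
#'
#' @param object A `connectome`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectome <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(unclass(object)), from = rownames(object)),
    -dplyr::all_of("from"), names_to = "to", values_to = "weight"
  )
  ids <- rownames(object)
  df$from <- factor(df$from, levels = ids)
  df$to <- factor(df$to, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a normalized rich-club curve
#'
#' @param object A `rich_club_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rich_club_curve <- function(object, ...) {
  df <- object[!is.na(object$phi_norm), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$phi_norm)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "richness level k (degree)",
                  y = "normalized rich-club coefficient") +
    ggplot2::theme_minimal()
}

#' Plot seizure probability across the excitability sweep
#'
#' @param object An `ictogenicity_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ictogenicity_sweep <- function(object, ...) {
  curve <- attr(object, "psz_curve")
  ggplot2::ggplot(object, ggplot2::aes(.data$i0, .data$psz)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = curve) +
    ggplot2::labs(x = expression(I[0]), y = expression(P[sz])) +
    ggplot2::theme_minimal()
}

#' Plot an evoked waveform
#'
#' @param object An `evoked_waveform`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evoked_waveform <- function(object, ...) {
  df <- tibble::as_tibble(object$amplitude)
  df$time_ms <- object$times
  df <- tidyr::pivot_longer(df, -dplyr::all_of("time_ms"),
                            names_to = "channel", values_to = "uv")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$uv,
                                   colour = .data$channel)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "amplitude (uV)") +
    ggplot2::theme_minimal()
}

#' Cell-wise distribution of a cohort metric
#'
#' @param metrics A cohort metrics data frame with `group` and `timepoint`.
#' @param var Metric column name (string).
#' @return A ggplot object.
#' @export
plot_cohort_metric <- function(metrics, var) {
  ggplot2::ggplot(metrics,
                  ggplot2::aes(interaction(.data$group, .data$timepoint),
                               .data[[var]], fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::labs(x = "group x timepoint (months)", y = var) +
    ggplot2::theme_minimal()
}
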