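#' Plot a force trace
#'
#' @param object A [force_trace()].
#' @param ... Unused.
#' @return A ggplot object: force versus time.
#' @method autoplot force_trace
#' @export
autoplot.force_trace <- function(object, ...) {
  meta <- trace_meta(object)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$force_nN)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(
      x = "Time (s)", y = "Force (nN)",
      title = sprintf("%s (%s, %s)", meta$cell_id, meta$phenotype,
                      meta$trap_region)
    ) +
    ggplot2::theme_minimal()
}

#' Plot band-limited signals
#'
#' One panel per frequency band, the time-domain contribution of that band
#' to the beating-force signal.
#'
#' @param object A [band_decompose()] result.
#' @param ... Unused.
#' @return A ggplot object faceted by band.
#' @method autoplot band_signals
#' @export
autoplot.band_signals <- function(object, ...) {
  scheme <- attr(object, "scheme", exact = TRUE)
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_s", scheme$label)],
    cols = dplyr::all_of(scheme$label),
    names_to = "band", values_to = "force_nN"
  )
  long$band <- factor(long$band, levels = scheme$label)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$force_nN)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~band, ncol = 2, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Force (nN)") +
    ggplot2::theme_minimal()
}

#' Plot a group comparison as box plots
#'
#' Box plots of the per-cell band maximum forces per group and band, in
#' the conventional style: the box spans the quartiles, whiskers span the
#' range, a `+` marks the mean and the bar marks the median.
#'
#' @param object A [compare_bands()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot band_comparison
#' @export
autoplot.band_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$band, y = .data$max_force_nN, fill = .data$group)
  ) +
    ggplot2::geom_boxplot(
      position = ggplot2::position_dodge(width = 0.8),
      coef = Inf, outlier.shape = NA, linewidth = 0.3
    ) +
    ggplot2::stat_summary(
      fun = mean, geom = "point", shape = 3, size = 1.5,
      position = ggplot2::position_dodge(width = 0.8)
    ) +
    ggplot2::labs(
      x = "Frequency band", y = "Maximum force (nN)", fill = object$group_by
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
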