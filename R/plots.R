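#' Plot per-fly values by condition
#'
#' Box-plus-jitter panel of one statistic from a comparison report, annotated
#' with the two-sided Mann-Whitney p-value.
#'
#' @param comparison a `hemocyte_comparison` from [run_comparison()].
#' @param statistic name of the statistic to plot.
#' @return a ggplot object.
#' @export
plot_comparison <- function(comparison, statistic = "hemocyte_count") {
  stopifnot(inherits(comparison, "hemocyte_comparison"),
            statistic %in% names(comparison$results))
  res <- comparison$results[[statistic]]
  df <- res$per_fly
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$value,
                                   fill = .data$condition)) +
    ggplot2::geom_boxplot(alpha = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, size = 2, shape = 21) +
    ggplot2::labs(
      title = statistic,
      subtitle = sprintf("two-sided Mann-Whitney U = %g, p = %.3g",
                         res$U, res$p_value),
      x = NULL, y = statistic
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot curve sets with confidence bands
#'
#' Mean curve per condition with the 95% band as a lighter ribbon — the
#' standard view of a replicate-aggregated ECDF or G-function.
#'
#' @param curve_sets named list of `curve_set`s (names = conditions).
#' @param xlab,ylab axis labels.
#' @return a ggplot object.
#' @export
plot_curve_set <- function(curve_sets, xlab = "grid", ylab = "cumulative proportion") {
  stopifnot(length(curve_sets) >= 1)
  df <- do.call(rbind, lapply(names(curve_sets), function(cond) {
    d <- as.data.frame(curve_sets[[cond]])
    d$condition <- cond
    d
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grid_value, y = .data$mean,
                                   color = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_low,
                                      ymax = .data$band_high),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a pooled 2D coordinate histogram
#'
#' Tile map of pooled, unit-disk-normalized hemocyte coordinates; darker
#' tiles mark recurrently occupied locations across replicates.
#'
#' @param hist2d matrix from [coordinate_histogram_2d()].
#' @return a ggplot object.
#' @export
plot_coordinate_histogram <- function(hist2d) {
  edges <- attr(hist2d, "edges")
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  df <- expand.grid(y = mids, x = mids)
  df$count <- as.vector(hist2d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x / Rc", y = "y / Rc", fill = "count") +
    ggplot2::theme_minimal()
}
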