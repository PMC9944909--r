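#' Histogram of bootstrap sample means by land use
#'
#' Overlaid urban/rural histograms of the subsample means produced by
#' [bootstrap_resample()]: closely separated humps indicate a mean
#' difference robust to which reports are sampled.
#'
#' @param boot A `bootstrap_result`.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_bootstrap <- function(boot, bins = 40) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_bootstrap requires the ggplot2 package")
  }
  ggplot2::ggplot(
    boot,
    ggplot2::aes(x = .data$mean_value, fill = .data$land_use)
  ) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::scale_fill_manual(
      values = c(urban = "goldenrod2", rural = "darkgreen")
    ) +
    ggplot2::labs(
      x = sprintf("subsample mean of %s", boot$measure[1]),
      y = "count", fill = "land use"
    ) +
    ggplot2::theme_minimal()
}
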