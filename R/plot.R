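# Figure-style renderings of trajectory grids: age x pair -log10 p heatmaps
# with region separators, one panel per sex.

#' Age-by-pair significance heatmap of a trajectory grid
#'
#' Pairs 1-27 on the y-axis grouped by scalp region (horizontal separators
#' after pairs 10 and 21: anterior / posterior / intrahemispheric), age on
#' the x-axis, fill = -log10 p, faceted by sex. Cells passing the FDR mask
#' are outlined.
#'
#' @param grid A `trajectory_grid`.
#' @param band Band to display (default the first band present).
#' @return A ggplot object.
#' @export
plot_trajectory_heatmap <- function(grid, band = NULL) {
  df <- tibble::as_tibble(grid)
  if (is.null(band)) band <- df$band[1]
  df <- df[df$band == band, , drop = FALSE]
  if (nrow(df) == 0) stop("no grid cells for band '", band, "'",
                          call. = FALSE)
  sig <- df[!is.na(df$significant) & df$significant, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age,
                                        y = factor(.data$pair_id,
                                                   levels = 27:1),
                                        fill = .data$neglog10p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_hline(yintercept = c(27 - 10 + 0.5, 27 - 21 + 0.5),
                        color = "white", linewidth = 0.8) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ p),
                                  na.value = "grey85") +
    ggplot2::labs(x = "Age (years)", y = "Coherence pair",
                  title = paste0("Score association with ", band,
                                 " coherence")) +
    ggplot2::theme_minimal()
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_tile(data = sig, fill = NA, color = "red",
                                linewidth = 0.4)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.trajectory_grid <- function(object, band = NULL, ...) {
  plot_trajectory_heatmap(object, band = band)
}

#' Coherence spectrum plot
#'
#' @param object A `spectral_estimate`.
#' @param ... Unused.
#' @return A ggplot of per-frequency coherence with band shading.
#' @exportS3Method ggplot2::autoplot
autoplot.spectral_estimate <- function(object, ...) {
  coh <- coherence_spectrum(object)
  bands <- eeg_bands(c("theta", "alpha", "beta"))
  ggplot2::ggplot(coh, ggplot2::aes(.data$freq, .data$coherence)) +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = .data$f_lo, xmax = .data$f_hi,
                                    ymin = 0, ymax = 1, fill = .data$band),
                       alpha = 0.12, inherit.aes = FALSE) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Magnitude-squared coherence") +
    ggplot2::theme_minimal()
}
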