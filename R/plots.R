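#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot mean reflectance curves with 95% confidence bands
#'
#' @param spectra long spectra tibble.
#' @return a ggplot object.
#' @export
plot_spectra <- function(spectra) {
  summ <- spectra |>
    dplyr::group_by(.data$species, .data$morph, .data$wavelength) |>
    dplyr::summarise(
      mean = mean(.data$reflectance),
      se = sd(.data$reflectance) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(.data$wavelength, .data$mean,
                                     color = .data$morph,
                                     linetype = .data$species)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                      ymax = .data$mean + 1.96 * .data$se,
                                      fill = .data$morph),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(blue = "#3b6fb6",
                                           orange = "#e08214")) +
    ggplot2::scale_fill_manual(values = c(blue = "#3b6fb6",
                                          orange = "#e08214")) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance (%)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential expression result
#'
#' @param object a `de_result` from [de_exact_test()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      neglog10 = -log10(pmax(.data$fdr, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, .data$neglog10,
                                   color = .data$deg)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "#c51b7d")) +
    ggplot2::labs(x = "log2 fold change (orange vs blue)",
                  y = "-log10 FDR", color = "DEG") +
    ggplot2::theme_minimal()
}

#' Plot climate divergence test results
#'
#' Observed between-species divergence per variable and morph, marking
#' variables significant under the color-randomization null.
#'
#' @param object a `divergence_result` from [mc_divergence()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.divergence_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$variable, .data$observed,
                               fill = .data$morph,
                               alpha = .data$significant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(blue = "#3b6fb6",
                                          orange = "#e08214")) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1)) +
    ggplot2::labs(x = NULL, y = "between-species divergence |diff of means|",
                  alpha = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
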