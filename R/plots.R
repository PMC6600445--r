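#' Stacked-bar plot of fraction percentage profiles
#'
#' @param profiles A profiles tibble (`element`, `fraction`, `percentage`),
#'   per sample or study mean.
#' @return A ggplot object.
#' @export
plot_fraction_profiles <- function(profiles) {
  require_columns(profiles, c("element", "fraction", "percentage"), "profiles table")
  ggplot2::ggplot(
    profiles,
    ggplot2::aes(
      x = .data$element, y = .data$percentage,
      fill = factor(.data$fraction, levels = 5:1, labels = paste0("F", 5:1))
    )
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = NULL, y = "% of extracted content", fill = "Fraction",
      title = "Element distribution across extraction fractions"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sed_risk <- function(object, ...) {
  ggplot2::ggplot(
    object$sites,
    ggplot2::aes(x = stats::reorder(.data$sample_id, .data$ri),
                 y = .data$ri, fill = .data$ri_class)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$scheme$ri_thresholds, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = "Site", y = "Risk index RI", fill = "RI class",
      title = "Total ecological risk index per site"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mc_risk <- function(object, scale = c("ri", "er"), ...) {
  scale <- match.arg(scale)
  if (scale == "ri") {
    curve <- exceedance_curve(object$ri) |>
      dplyr::mutate(element = "RI")
    thresholds <- object$scheme$ri_thresholds
  } else {
    curve <- object$er |>
      dplyr::group_by(.data$element) |>
      dplyr::reframe(exceedance_curve(.data$er))
    thresholds <- object$scheme$er_thresholds
  }
  ggplot2::ggplot(curve, ggplot2::aes(.data$value, .data$exceedance,
                                      colour = .data$element)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = thresholds, linetype = "dashed") +
    ggplot2::labs(
      x = if (scale == "ri") "Risk index RI" else "Single-factor risk Er",
      y = "Exceedance probability", colour = NULL,
      title = "Monte Carlo exceedance probability curves"
    ) +
    ggplot2::theme_minimal()
}
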