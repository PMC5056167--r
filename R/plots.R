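#' Plot a graded thickness profile
#'
#' Relative thickness of the three wall tissues against circumferential
#' position, the standard way the graded architecture is displayed.
#'
#' @param object A [thickness_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot thickness_profile
#' @export
autoplot.thickness_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("X_M", "X_L", "X_T"),
                              names_to = "layer", values_to = "fraction")
  long$layer <- factor(long$layer, levels = c("X_M", "X_L", "X_T"),
                       labels = c("mesocarp parenchyma",
                                  "longitudinal fibers",
                                  "transverse fibers"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s, y = .data$fraction,
                                     colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "position along circumference (from split region)",
                  y = "relative thickness", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a curvature profile
#'
#' @param object A `curvature_profile`.
#' @param normalized Plot `kappa_norm` (default) or raw `kappa`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot curvature_profile
#' @export
autoplot.curvature_profile <- function(object, normalized = TRUE, ...) {
  y <- if (normalized) "kappa_norm" else "kappa"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$s, y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "position along circumference (from split region)",
      y = if (normalized) "normalized longitudinal curvature" else
        "longitudinal curvature (1/length)"
    ) +
    ggplot2::theme_minimal()
}

#' Overlay predicted and measured curvature profiles
#'
#' @param predicted,measured `curvature_profile` tibbles.
#' @return A ggplot object.
#' @export
plot_profile_comparison <- function(predicted, measured) {
  both <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(curvature_profile(predicted)),
                  source = "predicted"),
    dplyr::mutate(tibble::as_tibble(curvature_profile(measured)),
                  source = "measured")
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$s, y = .data$kappa_norm,
                                     colour = .data$source,
                                     shape = .data$source)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$source == "predicted")) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "position along circumference (from split region)",
                  y = "normalized longitudinal curvature",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
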