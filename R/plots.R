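# ggplot2 helpers for the main result types.

#' Plot enzyme stoichiometry vectors
#'
#' Scatter of the relative-activity coordinates `(x, y)` from
#' [enzyme_vectors()] with the 1:1 line (the 45-degree N/P limitation
#' boundary): points above the line sit at angles > 45 degrees, i.e. on the
#' phosphorus-limited side.
#'
#' @param vectors Output of [enzyme_vectors()].
#' @param colour Optional column name (string) to colour points by.
#' @return A ggplot object.
#' @export
plot_enzyme_vectors <- function(vectors, colour = NULL) {
  p <- ggplot2::ggplot(vectors, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(
      if (!is.null(colour)) ggplot2::aes(colour = .data[[colour]])) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "x = (BG+CBH)/(BG+CBH+ALP)",
                  y = "y = (BG+CBH)/(BG+CBH+NAG+LAP)") +
    ggplot2::theme_minimal()
  p
}

#' Plot a rarefaction curve
#'
#' @param curve Output of [rarefaction_curve()].
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$depth,
                                      y = .data$expected_richness)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Subsample depth", y = "Expected richness") +
    ggplot2::theme_minimal()
}

#' Plot a correlation screen as a heat map
#'
#' Tile map of `r` with significance stars, in the style of published
#' soil-property correlation heat maps.
#'
#' @param screen Output of [correlation_screen()].
#' @return A ggplot object.
#' @export
plot_correlation_screen <- function(screen) {
  ggplot2::ggplot(screen, ggplot2::aes(x = .data$var_a, y = .data$var_b,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
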