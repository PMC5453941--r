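#' Plot a 2D free-energy landscape
#'
#' Raster of the free energy (or probability, if [free_energy()] has not
#' been applied) over the two reaction coordinates.
#'
#' @param object A `landscape_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.landscape_grid <- function(object, ...) {
  b <- object$bins
  fill <- if ("f" %in% names(b)) "f" else "p"
  lab <- if (fill == "f") "F (kcal/mol)" else "P"
  ggplot2::ggplot(b, ggplot2::aes(.data[[object$coords[1]]],
                                  .data[[object$coords[2]]],
                                  fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab, option = "turbo") +
    ggplot2::labs(x = sprintf("%s (Å)", object$coords[1]),
                  y = sprintf("%s (Å)", object$coords[2])) +
    ggplot2::theme_minimal()
}

#' Plot stage-wise 1D PMF profiles
#' @param object A `pmf_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$sampled),
                  ggplot2::aes(.data$center, .data$f, colour = .data$region)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = sprintf("%s (Å)", attr(object, "axis")),
                  y = "PMF (kcal/mol)", colour = "stage") +
    ggplot2::theme_minimal()
}

#' Plot an axial density profile
#' @param object An `axial_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.axial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$z, .data$density,
                                       colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (Å)", y = "probability density") +
    ggplot2::theme_minimal()
}

#' Plot a residue-residue contact matrix
#' @param object A `contact_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_matrix <- function(object, ...) {
  d <- tidy(object)
  d$row <- factor(d$row, levels = object$rows$label)
  d$col <- factor(d$col, levels = object$cols$label)
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "cargo residue", y = "pore residue",
                  fill = "contact\nfraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
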