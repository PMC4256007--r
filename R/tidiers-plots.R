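#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PMF profile
#'
#' @param x A `pmf_profile`.
#' @param ... Unused.
#' @return A tibble with `xi`, `G`, `sd` (if bootstrapped), `count`.
#' @export
tidy.pmf_profile <- function(x, ...) {
  as_tibble(x)[, intersect(c("xi", "G", "sd", "count"), names(x))]
}

#' Glance at a PMF profile
#'
#' One-row summary: the interfacial minimum and translocation barrier, plus
#' convergence diagnostics.
#'
#' @inheritParams tidy.pmf_profile
#' @param interface_region Passed to [pmf_features()].
#' @export
glance.pmf_profile <- function(x, interface_region = c(3, 6), ...) {
  ft <- pmf_features(x, interface_region)
  dplyr::bind_cols(ft, tibble(converged = attr(x, "converged"),
                              iterations = attr(x, "iterations")))
}

#' Tidy / glance a diffusion fit
#'
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble(term = "D", estimate = x$D, std.error = x$se,
         conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @rdname tidy.diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(D = x$D, se = x$se, dim = x$dim, n_particles = x$n_particles,
         fit_lo = x$fit_range[1], fit_hi = x$fit_range[2])
}

#' Plot a 2D scalar field (P2 map, density map)
#'
#' @param object A `scalar_field2d`.
#' @param ... Unused.
#' @return A ggplot; empty cells are rendered as missing (white).
#' @export
autoplot.scalar_field2d <- function(object, ...) {
  df <- as_tibble(object)
  df$value[df$n == 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$z, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = paste0(attr(object, "axis_label") %||% "x", " (nm)"),
                  y = "z (nm)", fill = "value") +
    ggplot2::coord_equal()
}

#' Plot a radial profile
#'
#' @param object A `radial_profile` (concentration, RDF, thickness, P2).
#' @param ... Unused.
#' @export
autoplot.radial_profile <- function(object, ...) {
  df <- as_tibble(object)[is.finite(as_tibble(object)$value), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "d from NP centre (nm)", y = "value")
  if ("se" %in% names(df) && any(is.finite(df$se))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$se, ymax = .data$value + .data$se),
      alpha = 0.25)
  }
  p
}

#' Plot a PMF profile
#'
#' @param object A `pmf_profile`.
#' @param ... Unused.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  df <- as_tibble(object)[is.finite(object$G), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$xi, y = .data$G)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(xi ~ "(nm)"), y = "G (kJ/mol)")
  if ("sd" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$G - .data$sd, ymax = .data$G + .data$sd),
      alpha = 0.25)
  }
  p
}

#' Plot an MSD curve
#'
#' @param object An `msd_curve`.
#' @param ... Unused.
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ns)", y = expression(MSD ~ (nm^2)))
}
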