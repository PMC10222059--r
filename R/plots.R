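#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# shared raster -> long tibble helper
raster_tidy <- function(r) {
  dplyr::bind_cols(cell_centers(r$geom), value = raster_values(r))
}

#' Plot a grid raster
#'
#' @param object a `grid_raster` (or subclass).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.grid_raster <- function(object, ...) {
  d <- raster_tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' @rdname autoplot.grid_raster
#' @export
autoplot.suitability_map <- function(object, ...) {
  autoplot.grid_raster(object) +
    ggplot2::labs(fill = "suitability\n(0-1000)", title = object$scenario %||% NULL)
}

#' @rdname autoplot.grid_raster
#' @export
autoplot.vulnerability_surface <- function(object, ...) {
  d <- raster_tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  midpoint = 0, na.value = "grey95") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "CCVI",
                  title = paste("Vulnerability,", object$scenario))
}

#' Plot the scaled size structure of each population
#'
#' One peak-scaled kernel density curve per population, with the pooled
#' species-wide curve overlaid in black for comparison.
#'
#' @param census census tibble (`population`, `stem_length_cm`).
#' @param bandwidth optional kernel bandwidth (cm).
#' @return A ggplot, faceted by population.
#' @export
plot_size_structure <- function(census, bandwidth = NULL) {
  stopifnot(all(c("population", "stem_length_cm") %in% names(census)))
  per_pop <- census |>
    dplyr::group_by(.data$population) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::group_modify(~ size_structure_density(.x$stem_length_cm, bandwidth)) |>
    dplyr::ungroup()
  overall <- size_structure_density(census$stem_length_cm, bandwidth)
  ggplot2::ggplot(per_pop, ggplot2::aes(.data$stem_length_cm, .data$density)) +
    ggplot2::geom_line(data = overall, colour = "black", linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$population), show.legend = FALSE) +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "stem length (cm)", y = "scaled density")
}

#' Plot a demography-vulnerability association
#'
#' Scatter of the fitted data with the regression line; for binomial fits the
#' y axis is the observed proportion.
#'
#' @param object a `regression_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.regression_result <- function(object, ...) {
  f <- object$fit
  if (object$family == "binomial") {
    mf <- stats::model.frame(f)
    resp <- mf[[1]]
    yv <- if (is.matrix(resp)) resp[, 1] / rowSums(resp) else resp
    xv <- mf$xv
  } else {
    yv <- stats::model.frame(f)$yv
    xv <- stats::model.frame(f)$xv
  }
  grid <- data.frame(xv = seq(min(xv), max(xv), length.out = 100))
  grid$fit <- as.numeric(stats::predict(f, grid, type = "response"))
  ggplot2::ggplot(data.frame(x = xv, y = yv), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$xv, .data$fit), colour = "#b2182b") +
    ggplot2::labs(x = object$term, y = object$response,
                  subtitle = sprintf("%s = %.2f, p = %.3g, %s = %.3f",
                                     object$statistic_type, object$statistic,
                                     object$p_value, object$r_squared_type,
                                     object$r_squared))
}
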