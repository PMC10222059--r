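#' Future suitability over the present-distribution footprint
#'
#' Overlays the present binary distribution with a future suitability map and
#' returns the future values at the cells where the species is currently
#' predicted present, in row-major cell order.
#'
#' @param present_binary 0/1 `grid_raster` of the present distribution (e.g.
#'   from [binarize()]).
#' @param future_suitability `suitability_map` for one future scenario, same
#'   geometry.
#' @return Tibble with `cell` (row-major id) and `suitability` at footprint
#'   cells.
#' @export
footprint_overlay <- function(present_binary, future_suitability) {
  stopifnot(inherits(present_binary, "grid_raster"),
            inherits(future_suitability, "grid_raster"))
  if (!geom_equal(present_binary$geom, future_suitability$geom))
    stop("geometry mismatch between present and future grids")
  pres <- raster_values(present_binary)
  fut <- raster_values(future_suitability)
  cells <- which(!is.na(pres) & pres == 1)
  if (!length(cells)) stop("empty footprint")
  tibble::tibble(cell = cells, suitability = fut[cells])
}

# the index itself: negated, centred, sd-scaled suitability
ccvi_values <- function(values, center, sigma = NULL) {
  if (length(values) < 2) stop("need at least 2 footprint cells")
  if (is.null(sigma)) sigma <- stats::sd(values)
  if (!is.finite(sigma) || sigma <= 0) stop("zero variance: vulnerability index undefined")
  -(values - center) / sigma
}

#' Climate-change vulnerability surface for one future scenario
#'
#' Computes the per-cell Climate Change Vulnerability Index (CCVI) over the
#' present-distribution footprint. The footprint's future suitability values
#' are centred on `center`, scaled by their sample standard deviation
#' (`n - 1` denominator) and negated:
#' \deqn{CCVI = -(s - center) / \sigma}
#' so cells whose future suitability sits at the survival minimum score 0,
#' suitable cells score negative (not vulnerable) and unsuitable cells score
#' increasingly positive. With `center = "threshold"` (default) the centre is
#' the ensemble's minimum-suitable-habitat threshold; `center = "mean"` uses
#' the footprint mean, in which case footprint CCVI has mean 0 and sd 1
#' exactly.
#'
#' @inheritParams footprint_overlay
#' @param center `"threshold"`, `"mean"`, or a number on the 0-1000
#'   suitability scale.
#' @param threshold ensemble binarization threshold (required when
#'   `center = "threshold"`).
#' @param scenario label for the future scenario.
#' @return A `vulnerability_surface`: a [grid_raster()] of CCVI values (NA
#'   outside the footprint) with fields `center`, `sigma`, `scenario` and
#'   `footprint_n`.
#' @export
ccvi_surface <- function(present_binary, future_suitability,
                         center = "threshold", threshold = NULL,
                         scenario = future_suitability$scenario %||% "future") {
  fp <- footprint_overlay(present_binary, future_suitability)
  ctr <- if (is.numeric(center)) {
    center
  } else if (identical(center, "mean")) {
    mean(fp$suitability)
  } else if (identical(center, "threshold")) {
    if (is.null(threshold)) stop("center = \"threshold\" needs a threshold value")
    threshold
  } else stop("center must be \"threshold\", \"mean\" or a number")
  sigma <- stats::sd(fp$suitability)
  vals <- ccvi_values(fp$suitability, ctr, sigma)
  g <- present_binary$geom
  out <- rep(NA_real_, g$n_rows * g$n_cols)
  out[fp$cell] <- vals
  r <- grid_raster(matrix(out, g$n_rows, g$n_cols, byrow = TRUE),
                   g$xmin, g$ymin, g$cellsize, g$crs)
  r$center <- ctr
  r$sigma <- sigma
  r$scenario <- scenario
  r$footprint_n <- nrow(fp)
  class(r) <- c("vulnerability_surface", class(r))
  r
}

#' @export
print.vulnerability_surface <- function(x, ...) {
  cat(sprintf("<vulnerability_surface> scenario %s: %d footprint cells, center %.1f, sigma %.2f\n",
              x$scenario, x$footprint_n, x$center, x$sigma))
  invisible(x)
}

#' Extract per-plant CCVI values
#'
#' Each plant takes the CCVI value of its containing cell (no interpolation;
#' half-open cell convention). Plants inside the grid but outside the
#' footprint receive `NA` with a warning; plants outside the grid are an
#' error.
#'
#' @param surface a `vulnerability_surface`.
#' @param plants data frame with columns `x`, `y` (other columns are carried
#'   through).
#' @return The `plants` tibble with a `ccvi` column (and the surface's
#'   scenario in `scenario`).
#' @export
extract_plant_ccvi <- function(surface, plants) {
  stopifnot(inherits(surface, "vulnerability_surface"),
            all(c("x", "y") %in% names(plants)))
  idx <- cell_index(surface$geom, plants$x, plants$y)
  if (anyNA(idx$cell)) stop("plant(s) outside grid bounds")
  vals <- raster_values(surface)[idx$cell]
  if (anyNA(vals))
    warning(sum(is.na(vals)), " plant(s) fall outside the present-distribution footprint")
  out <- tibble::as_tibble(plants)
  out$ccvi <- vals
  out$scenario <- surface$scenario
  out
}

#' Per-population CCVI summaries
#'
#' Mean and sample standard deviation of per-plant CCVI values by population;
#' single-plant populations report `NA` sd.
#'
#' @param values per-plant CCVI values.
#' @param population population labels, same length.
#' @param scenario scenario-set label (e.g. `"all-2055"`, `"SSP5-RCP8.5"`).
#' @return Tibble: `population`, `scenario`, `n`, `mean_ccvi`, `sd_ccvi`.
#' @export
population_ccvi <- function(values, population, scenario = "all-2055") {
  if (length(values) != length(population)) stop("label/value length mismatch")
  tibble::tibble(population = population, ccvi = values) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_ccvi = mean(.data$ccvi),
                     sd_ccvi = ifelse(dplyr::n() > 1, stats::sd(.data$ccvi), NA_real_),
                     .groups = "drop") |>
    dplyr::mutate(scenario = scenario, .after = "population")
}

#' Average per-plant CCVI across scenarios
#'
#' Plain arithmetic mean of each plant's CCVI over the selected scenario
#' subset. Because per-plant extraction is pointwise, averaging after
#' extraction equals extracting from an averaged surface.
#'
#' @param per_plant long tibble with columns `plant_id`, `scenario`, `ccvi`
#'   (one row per plant per scenario), e.g. stacked outputs of
#'   [extract_plant_ccvi()].
#' @param subset `"all"`, or a pattern/vector naming the scenarios to average
#'   (e.g. `"SSP5-RCP8.5"` selects every scenario whose label contains it).
#' @return Tibble `plant_id`, `ccvi` (one row per plant).
#' @export
scenario_average <- function(per_plant, subset = "all") {
  stopifnot(all(c("plant_id", "scenario", "ccvi") %in% names(per_plant)))
  scen <- unique(per_plant$scenario)
  use <- if (identical(subset, "all")) scen
         else if (length(subset) == 1) grep(subset, scen, fixed = TRUE, value = TRUE)
         else intersect(subset, scen)
  if (!length(use)) stop("no scenario matches subset")
  d <- per_plant[per_plant$scenario %in% use, ]
  counts <- table(d$plant_id)
  if (any(counts != length(use)))
    stop("missing scenario value: every plant needs a value in every selected scenario")
  dplyr::summarise(dplyr::group_by(d, .data$plant_id),
                   ccvi = mean(.data$ccvi), .groups = "drop")
}
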