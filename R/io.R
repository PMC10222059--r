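#' Read and write plant censuses
#'
#' The census exchange format is a CSV with header
#' `plant_id,population,x,y,stem_length_cm,status` where `status` is one of
#' `non_reproductive`, `flowering`, `fruiting`. Reading validates records and
#' reports offending row numbers.
#'
#' @param path CSV file path.
#' @return `read_census` returns a validated census tibble; `write_census`
#'   returns `path` invisibly.
#' @export
read_census <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "population", "x", "y", "stem_length_cm", "status")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(d$plant_id))
    stop("duplicate plant id(s): ",
         paste(unique(d$plant_id[duplicated(d$plant_id)]), collapse = ", "))
  bad <- which(!is.finite(d$stem_length_cm) | d$stem_length_cm <= 0)
  if (length(bad))
    stop("non-positive stem length at row(s): ", paste(bad, collapse = ", "))
  bad_xy <- which(!is.finite(d$x) | !is.finite(d$y))
  if (length(bad_xy))
    stop("non-finite coordinates at row(s): ", paste(bad_xy, collapse = ", "))
  ok_status <- c("non_reproductive", "flowering", "fruiting")
  bad_st <- which(!d$status %in% ok_status)
  if (length(bad_st))
    stop("unknown status at row(s): ", paste(bad_st, collapse = ", "))
  tibble::as_tibble(d[need])
}

#' @rdname read_census
#' @param census census tibble with the standard columns.
#' @export
write_census <- function(census, path) {
  need <- c("plant_id", "population", "x", "y", "stem_length_cm", "status")
  stopifnot(all(need %in% names(census)))
  utils::write.csv(as.data.frame(census[need]), path, row.names = FALSE)
  invisible(path)
}

#' Packaged published population-parameter table
#'
#' The 13-population parameter table transcribed verbatim from the source
#' study (counts, stem-length summaries, skewness, distances, areas, densities
#' and per-scenario mean CCVI with sd). It is the deterministic input for
#' [reproduce_paper()] and the association-model checks.
#'
#' @return Tibble with 13 rows and one column per published parameter.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_population_parameters.csv",
                      package = "popvuln", mustWork = TRUE)
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(nrow(d) == 13, all(d$n_young + d$n_adult == d$n_plants))
  d
}

#' Recompute the published summary statistics from the packaged table
#'
#' Recomputes, from the packaged population-parameter table alone, every
#' desk-reproducible quantity the source study prints: census totals, density
#' and distance summaries, occupied area, and the population-level linear and
#' binomial association models (overall and high-emission scenario). Each
#' check carries the published value and a tolerance reflecting the rounding
#' of the published inputs.
#'
#' @param table1 the population-parameter table to check; defaults to the
#'   packaged fixture (overridable for sensitivity analyses).
#' @return Tibble with one row per check: `check`, `value` (recomputed),
#'   `target` (published), `tolerance`, `pass`.
#' @export
reproduce_paper <- function(table1 = table1_fixture()) {
  t1 <- table1
  rows <- list()
  add <- function(check, value, target, tolerance, cmp = "eq") {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      check = check, value = value, target = target, tolerance = tolerance,
      pass = if (cmp == "le") value <= target else abs(value - target) <= tolerance)
  }
  add("total plants", sum(t1$n_plants), 1615, 0)
  add("plants per population (min)", min(t1$n_plants), 4, 0)
  add("plants per population (max)", max(t1$n_plants), 298, 0)
  add("mean plant density (n/ha)", mean(t1$density_total), 792, 0.5)
  add("max plant density (n/ha)", max(t1$density_total), 2383, 1)
  add("mean young-plant density (n/ha)", mean(t1$density_young), 234, 0.5)
  add("mean inter-plant distance (m)", mean(t1$mean_dist_m), 40, 0.5)
  add("total occupied area (ha)", sum(t1$area_ha), 5, 0, cmp = "le")  # published bound

  lm_all <- linear_fit(t1, "mean_stem_cm", "mean_ccvi")
  add("linear F: mean stem ~ CCVI 2055", lm_all$statistic, 5.42, 0.02 * 5.42)
  add("linear R2: mean stem ~ CCVI 2055", lm_all$r_squared, 0.330, 0.01)
  lm_585 <- linear_fit(t1, "mean_stem_cm", "mean_ccvi_ssp585")
  add("linear F: mean stem ~ CCVI SSP5-RCP8.5", lm_585$statistic, 5.79, 0.02 * 5.79)
  add("linear R2: mean stem ~ CCVI SSP5-RCP8.5", lm_585$r_squared, 0.345, 0.01)

  t1b <- dplyr::mutate(t1, total = .data$n_young + .data$n_adult)
  bin_all <- binomial_fit(t1b, "n_young", "total", "mean_ccvi")
  add("binomial Z: young proportion ~ CCVI 2055", bin_all$statistic, 9.15, 0.03 * 9.15)
  add("binomial pseudo-R2: young ~ CCVI 2055", bin_all$r_squared, 0.670, 0.02)
  bin_585 <- binomial_fit(t1b, "n_young", "total", "mean_ccvi_ssp585")
  add("binomial Z: young proportion ~ CCVI SSP5-RCP8.5", bin_585$statistic, 9.68, 0.03 * 9.68)
  add("binomial pseudo-R2: young ~ CCVI SSP5-RCP8.5", bin_585$r_squared, 0.723, 0.02)

  dplyr::bind_rows(rows)
}

#' Serialize an analysis configuration or report to JSON
#'
#' @param x a list (pipeline configuration, selection report, ensemble
#'   description, ...) containing only atomic fields and tibbles.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  drop_fits <- function(v) {
    if (inherits(v, "regression_result")) v <- glance(v)
    if (is.list(v) && !is.data.frame(v))
      v <- lapply(v[!vapply(v, is.function, logical(1))], drop_fits)
    v
  }
  jsonlite::write_json(drop_fits(x), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}
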