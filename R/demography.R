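#' Classify plants into life stages by stem length
#'
#' Plants with stems at or below the threshold are young; longer plants are
#' adults. The 30 cm default reflects the field observation that almost no
#' shorter-stemmed plants flower.
#'
#' @param stem_length_cm positive stem lengths (cm).
#' @param threshold_cm young/adult cutoff (default 30, inclusive for young).
#' @return Factor with levels `young`, `adult`.
#' @export
classify_life_stage <- function(stem_length_cm, threshold_cm = 30) {
  if (any(!is.finite(stem_length_cm)) || any(stem_length_cm <= 0))
    stop("stem lengths must be finite and positive")
  factor(ifelse(stem_length_cm <= threshold_cm, "young", "adult"),
         levels = c("young", "adult"))
}

#' Estimate plant age from stem length
#'
#' Uses the species' roughly constant leaf economy: stems carry about
#' `leaves_per_cm` leaves per cm and add about `leaves_per_year` leaves per
#' year, so `age = stem_length_cm * leaves_per_cm / leaves_per_year`.
#'
#' @param stem_length_cm positive stem length (cm).
#' @param leaves_per_cm leaves per cm of stem (default 0.6).
#' @param leaves_per_year leaves produced per year (default 3).
#' @return Estimated age in years (linear in stem length).
#' @export
estimate_age <- function(stem_length_cm, leaves_per_cm = 0.6, leaves_per_year = 3) {
  if (any(stem_length_cm <= 0) || leaves_per_cm <= 0 || leaves_per_year <= 0)
    stop("all arguments must be positive")
  stem_length_cm * leaves_per_cm / leaves_per_year
}

#' Sample skewness
#'
#' Fisher-Pearson standardized third moment. The default `"g1"` is the plain
#' moment form `m3 / m2^(3/2)`; `"b1"` applies the small-sample adjustment
#' `g1 * sqrt(n (n - 1)) / (n - 2)`.
#'
#' @param values numeric sample, `n >= 3`, non-constant.
#' @param type `"g1"` (moment form) or `"b1"` (adjusted).
#' @return Dimensionless skewness.
#' @export
skewness <- function(values, type = c("g1", "b1")) {
  type <- match.arg(type)
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("degenerate input: zero variance")
  g1 <- mean((values - m)^3) / m2^1.5
  if (type == "g1") g1 else g1 * sqrt(n * (n - 1)) / (n - 2)
}

# shoelace area of a polygon given in order
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

collinear_points <- function(x, y, tol = 1e-9) {
  if (length(x) < 3) return(TRUE)
  dx <- x - x[1]; dy <- y - y[1]
  scale <- max(abs(c(dx, dy)), 1)
  cross <- dx[2] * dy[-(1:2)] - dy[2] * dx[-(1:2)]
  # use the farthest point from p1 as the direction if p2 coincides with p1
  if (all(abs(c(dx[2], dy[2])) < tol * scale)) {
    k <- which.max(dx^2 + dy^2)
    cross <- dx[k] * dy - dy[k] * dx
  }
  all(abs(cross) < tol * scale^2)
}

# Bowyer-Watson Delaunay triangulation; returns matrix of point-index triples
delaunay_triangulation <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3)
  cx <- mean(range(x)); cy <- mean(range(y))
  span <- max(diff(range(x)), diff(range(y)), 1)
  big <- 1e5 * span
  px <- c(x, cx - big, cx + big, cx)
  py <- c(y, cy - big, cy - big, cy + big)
  tris <- list(c(n + 1L, n + 2L, n + 3L))

  circum <- function(t) {
    ax <- px[t[1]]; ay <- py[t[1]]; bx <- px[t[2]]; by <- py[t[2]]
    cxx <- px[t[3]]; cyy <- py[t[3]]
    d <- 2 * (ax * (by - cyy) + bx * (cyy - ay) + cxx * (ay - by))
    if (abs(d) < 1e-12 * span^2) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cyy) + (bx^2 + by^2) * (cyy - ay) +
             (cxx^2 + cyy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cxx - bx) + (bx^2 + by^2) * (ax - cxx) +
             (cxx^2 + cyy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  ccache <- list(circum(tris[[1]]))

  for (p in seq_len(n)) {
    bad <- vapply(seq_along(tris), function(i) {
      cc <- ccache[[i]]
      if (!is.finite(cc[3])) return(TRUE)
      (px[p] - cc[1])^2 + (py[p] - cc[2])^2 < cc[3]^2 * (1 + 1e-12)
    }, logical(1))
    if (!any(bad)) next  # duplicate of an existing vertex on a circle edge; skip
    edges <- do.call(rbind, lapply(tris[bad], function(t)
      rbind(sort(t[1:2]), sort(t[2:3]), sort(t[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad]
    ccache <- ccache[!bad]
    for (e in seq_len(nrow(boundary))) {
      t <- c(boundary[e, ], p)
      tris[[length(tris) + 1]] <- t
      ccache[[length(ccache) + 1]] <- circum(t)
    }
  }
  keep <- vapply(tris, function(t) all(t <= n), logical(1))
  do.call(rbind, tris[keep])
}

#' Area of occupancy around censused plants
#'
#' With `alpha = NULL` the polygon is the convex hull (area by the shoelace
#' formula). With a finite `alpha` (m) it is the alpha-shape: the union of
#' Delaunay triangles whose circumradius is at most `alpha`, which can follow
#' concavities in the point cloud; `alpha = Inf` recovers the convex hull.
#' Coordinates are planar metres; areas are returned in both m2 and hectares.
#'
#' @param points data frame with columns `x`, `y` (m).
#' @param alpha `NULL` for the convex hull, or an alpha radius in metres.
#' @return List: `area_m2`, `area_ha`, `method`, `degenerate` flag, and
#'   `hull` (tibble of hull vertices in order) or `triangles` (kept Delaunay
#'   triangles as an index matrix). Fewer than 3 distinct non-collinear points
#'   give area 0 with `degenerate = TRUE` and a warning.
#' @export
occupancy_area <- function(points, alpha = NULL) {
  stopifnot(all(c("x", "y") %in% names(points)))
  pts <- unique(data.frame(x = points$x, y = points$y))
  if (nrow(pts) < 3 || collinear_points(pts$x, pts$y)) {
    warning("fewer than 3 non-collinear points: degenerate occupancy polygon, area 0")
    return(list(area_m2 = 0, area_ha = 0, method = if (is.null(alpha)) "convex" else "alpha",
                degenerate = TRUE, hull = tibble::as_tibble(pts)))
  }
  if (is.null(alpha)) {
    h <- grDevices::chull(pts$x, pts$y)
    a <- polygon_area(pts$x[h], pts$y[h])
    return(list(area_m2 = a, area_ha = a / 1e4, method = "convex", degenerate = FALSE,
                hull = tibble::tibble(x = pts$x[h], y = pts$y[h])))
  }
  stopifnot(alpha > 0)
  tri <- delaunay_triangulation(pts$x, pts$y)
  radii <- apply(tri, 1, function(t) {
    ax <- pts$x[t[1]]; ay <- pts$y[t[1]]
    bx <- pts$x[t[2]]; by <- pts$y[t[2]]
    cx <- pts$x[t[3]]; cy <- pts$y[t[3]]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(Inf)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) + (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) + (cx^2 + cy^2) * (bx - ax)) / d
    sqrt((ax - ux)^2 + (ay - uy)^2)
  })
  keep <- radii <= alpha
  a <- sum(apply(tri[keep, , drop = FALSE], 1, function(t)
    polygon_area(pts$x[t], pts$y[t])))
  list(area_m2 = a, area_ha = a / 1e4, method = "alpha", degenerate = FALSE,
       triangles = tri[keep, , drop = FALSE], points = tibble::as_tibble(pts))
}

#' Mean distance between plants
#'
#' Default is the mean (and sample sd) over all `n (n - 1) / 2` unordered
#' pairwise Euclidean distances; `method = "nn"` gives the mean
#' nearest-neighbour distance instead.
#'
#' @param points data frame with columns `x`, `y` (m), at least 2 rows.
#' @param method `"pairwise"` or `"nn"`.
#' @return List with `mean`, `sd` (NA when only one distance exists) and `n_pairs`.
#' @export
mean_plant_distance <- function(points, method = c("pairwise", "nn")) {
  method <- match.arg(method)
  stopifnot(all(c("x", "y") %in% names(points)))
  if (nrow(points) < 2) stop("need at least 2 points")
  d <- as.matrix(stats::dist(cbind(points$x, points$y)))
  if (method == "pairwise") {
    v <- d[upper.tri(d)]
  } else {
    diag(d) <- Inf
    v <- apply(d, 1, min)
  }
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       n_pairs = length(v))
}

#' Summarize censuses into per-population parameters
#'
#' Produces, per population: plant count, mean +/- sd stem length, counts of
#' fruiting / young / adult plants, stem-length skewness, occupancy area (ha),
#' mean +/- sd inter-plant distance (m), and total / young / adult densities
#' (plants per ha). Densities are `NA` (not infinite) for degenerate
#' zero-area populations; skewness is `NA` below 3 plants.
#'
#' @param census tibble with columns `population`, `x`, `y`,
#'   `stem_length_cm`, `status` (one or many populations).
#' @param ccvi optional tibble keyed by `population` (e.g. from
#'   [population_ccvi()]) whose remaining columns are joined onto the summary.
#' @param alpha alpha radius for [occupancy_area()]; default `NULL` uses the
#'   convex hull. Use `"auto"` for twice the mean nearest-neighbour distance.
#' @param skewness_type passed to [skewness()].
#' @param distance passed to [mean_plant_distance()].
#' @param young_threshold_cm life-stage cutoff (default 30).
#' @return Tibble, one row per population.
#' @export
summarize_population <- function(census, ccvi = NULL, alpha = NULL,
                                 skewness_type = "g1",
                                 distance = c("pairwise", "nn"),
                                 young_threshold_cm = 30) {
  distance <- match.arg(distance)
  stopifnot(all(c("population", "x", "y", "stem_length_cm", "status") %in% names(census)))
  if (!nrow(census)) stop("empty census")
  one <- function(d) {
    n <- nrow(d)
    stage <- classify_life_stage(d$stem_length_cm, young_threshold_cm)
    a <- if (n >= 3) {
      al <- if (identical(alpha, "auto"))
        2 * mean_plant_distance(d, method = "nn")$mean else alpha
      suppressWarnings(occupancy_area(d, alpha = al))
    } else list(area_ha = 0, degenerate = TRUE)
    dist <- if (n >= 2) mean_plant_distance(d, method = distance) else
      list(mean = NA_real_, sd = NA_real_)
    dens <- function(count) if (a$area_ha > 0) count / a$area_ha else NA_real_
    tibble::tibble(
      n_plants = n,
      mean_stem_cm = mean(d$stem_length_cm),
      sd_stem_cm = if (n > 1) stats::sd(d$stem_length_cm) else NA_real_,
      n_fruiting = sum(d$status == "fruiting"),
      n_young = sum(stage == "young"),
      n_adult = sum(stage == "adult"),
      skewness = if (n >= 3 && stats::sd(d$stem_length_cm) > 0)
        skewness(d$stem_length_cm, skewness_type) else NA_real_,
      area_ha = a$area_ha,
      mean_dist_m = dist$mean, sd_dist_m = dist$sd,
      density_total = dens(n),
      density_young = dens(sum(stage == "young")),
      density_adult = dens(sum(stage == "adult")))
  }
  out <- census |>
    dplyr::group_by(.data$population) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
  if (!is.null(ccvi)) out <- dplyr::left_join(out, ccvi, by = "population")
  out
}

#' Scaled kernel density of the size structure
#'
#' Gaussian kernel density of stem lengths, evaluated from 0 to the sample
#' maximum and rescaled so the curve peaks at 1, which makes populations of
#' very different sizes visually comparable.
#'
#' @param values positive stem lengths (cm), `n >= 2`.
#' @param bandwidth kernel bandwidth (cm); default is Silverman's
#'   rule-of-thumb ([stats::bw.nrd0()]).
#' @param n_grid evaluation grid size.
#' @return Tibble with `stem_length_cm` and `density` (peak-scaled to 1).
#' @export
size_structure_density <- function(values, bandwidth = NULL, n_grid = 512) {
  if (length(values) < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0 && is.null(bandwidth))
    bandwidth <- max(values) / 100  # all-equal sample: fall back to a narrow kernel
  d <- stats::density(values, bw = if (is.null(bandwidth)) "nrd0" else bandwidth,
                      from = 0, to = max(values), n = n_grid)
  tibble::tibble(stem_length_cm = d$x, density = d$y / max(d$y))
}
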