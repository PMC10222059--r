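#' Generate a synthetic climate predictor stack
#'
#' Builds spatially autocorrelated predictor layers as smoothed Gaussian random
#' fields: white noise on a padded grid is convolved with a separable isotropic
#' Gaussian kernel whose standard deviation is `autocorr_range` cells, then
#' cropped and standardized to mean 0, sd 1 over cells. Layers are generated
#' sequentially from one seed, so the stack is fully reproducible.
#'
#' The layers are abstract standardized predictors: they stand in for bioclim
#' variables without emulating any particular variable's semantics.
#'
#' @param n_rows,n_cols grid dimensions (each at least 8).
#' @param layer_names character vector of unique predictor labels.
#' @param autocorr_range Gaussian kernel sd in cells (at least 1); larger
#'   values give smoother fields.
#' @param seed integer RNG seed.
#' @param cellsize cell edge length in metres (default 1000, i.e. a ~1 km
#'   climate grid).
#' @param xmin,ymin lower-left corner (m).
#' @return A [climate_stack()].
#' @examples
#' stk <- generate_climate_stack(32, 32, c("bio03", "bio07"), autocorr_range = 4, seed = 1)
#' sapply(stk$layers, sd)
#' @export
generate_climate_stack <- function(n_rows, n_cols,
                                   layer_names = c("bio03", "bio07", "bio15", "bio19"),
                                   autocorr_range = 4, seed = 1,
                                   cellsize = 1000, xmin = 0, ymin = 0) {
  if (n_rows < 8 || n_cols < 8) stop("degenerate grid: need at least 8 cells per side")
  if (autocorr_range < 1) stop("autocorr_range must be >= 1")
  if (anyDuplicated(layer_names)) stop("layer names must be unique")
  withr::local_seed(as.integer(seed))
  layers <- lapply(layer_names, function(nm) {
    smooth_field(n_rows, n_cols, autocorr_range)
  })
  names(layers) <- layer_names
  climate_stack(layers, xmin = xmin, ymin = ymin, cellsize = cellsize)
}

# smoothed, standardized Gaussian random field
smooth_field <- function(n_rows, n_cols, range) {
  pad <- ceiling(3 * range)
  noise <- matrix(stats::rnorm((n_rows + 2 * pad) * (n_cols + 2 * pad)),
                  n_rows + 2 * pad, n_cols + 2 * pad)
  k <- stats::dnorm(seq(-pad, pad), sd = range)
  k <- k / sum(k)
  sm <- apply(noise, 2, function(col) stats::filter(col, k, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, k, sides = 2)))
  core <- sm[pad + seq_len(n_rows), pad + seq_len(n_cols), drop = FALSE]
  (core - mean(core)) / stats::sd(core)
}

#' Generate a future climate stack from a present stack
#'
#' Future layer = present layer + additive shift (in the stack's standardized
#' units) + optional white noise. Geometry and layer names are preserved.
#'
#' @param present a [climate_stack()].
#' @param shift single number applied to every layer, or a named vector keyed
#'   by layer names (unnamed layers shift by 0).
#' @param noise_sd sd of cellwise white noise added on top of the shift.
#' @param seed integer RNG seed (used only when `noise_sd > 0`).
#' @return A [climate_stack()] with the same geometry.
#' @export
generate_future_stack <- function(present, shift, noise_sd = 0, seed = 1) {
  stopifnot(inherits(present, "climate_stack"))
  nms <- names(present$layers)
  if (is.null(names(shift))) {
    if (length(shift) != 1) stop("unnamed shift must be a single number")
    shift <- stats::setNames(rep(shift, length(nms)), nms)
  } else {
    unknown <- setdiff(names(shift), nms)
    if (length(unknown)) stop("unknown layer name in shift: ", paste(unknown, collapse = ", "))
    full <- stats::setNames(rep(0, length(nms)), nms)
    full[names(shift)] <- shift
    shift <- full
  }
  withr::local_seed(as.integer(seed))
  layers <- lapply(nms, function(nm) {
    l <- present$layers[[nm]] + shift[[nm]]
    if (noise_sd > 0) l <- l + matrix(stats::rnorm(length(l), sd = noise_sd), nrow(l), ncol(l))
    l
  })
  names(layers) <- nms
  g <- present$geom
  climate_stack(layers, xmin = g$xmin, ymin = g$ymin, cellsize = g$cellsize, crs = g$crs)
}

#' Ground truth for a synthetic study system
#'
#' Records every generative parameter of a synthetic dataset so that, given
#' the seed, the dataset is fully determined and planted effects can later be
#' checked against pipeline estimates.
#'
#' The demographic coupling is expressed against a planted per-population
#' vulnerability `v`: population k draws stem lengths from a gamma
#' distribution with mean `mu0 + beta_len * v_k` (cm) whose young fraction
#' (stems <= `young_threshold_cm`) equals `plogis(alpha_young + beta_young *
#' v_k)`. `beta_len < 0` and `beta_young > 0` plant the studied pattern:
#' shorter stems and more young plants where vulnerability is higher. The
#' coupling is realized geographically — populations are placed along a
#' climatic gradient so that more vulnerable populations lose more suitability
#' under a warming shift — so the vulnerability-index stage is genuinely
#' exercised rather than label-matched.
#'
#' @param niche_center niche optimum per predictor in standardized units,
#'   recycled positionally over predictors (named vectors are matched by
#'   layer name). The default puts the optimum at +0.8 spatial sd on the
#'   first predictor — the limiting climatic axis — and at the regional mean
#'   on the others.
#' @param niche_width niche Gaussian width per predictor in spatial-sd units,
#'   recycled positionally. The default is narrow (0.6) along the limiting
#'   axis and broad (1.5) elsewhere: suitability is governed chiefly by one
#'   axis, as for a narrow-range endemic limited by a single climatic
#'   gradient.
#' @param v planted per-population vulnerability scores.
#' @param mu0,beta_len intercept (cm) and slope (cm per vulnerability unit,
#'   negative) of mean stem length on `v`.
#' @param alpha_young,beta_young intercept and slope (positive) of the young
#'   fraction on the logit scale.
#' @param young_threshold_cm stem-length cutoff between young and adult plants.
#' @param p_fruiting,p_flowering reproductive-status probabilities for adult
#'   plants; the remainder are non-reproductive.
#' @param p_young_flowering flowering probability for young plants (kept below
#'   5%, matching field observation that almost no short-stemmed plants flower).
#' @param scatter_sd within-population plant scatter sd (m).
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_truth` (a list of the above).
#' @export
synthetic_truth <- function(niche_center = c(0.8, 0, 0, 0),
                            niche_width = c(0.6, 1.5, 1.5, 1.5),
                            v = seq(0.2, 0.8, length.out = 13),
                            mu0 = 125, beta_len = -100,
                            alpha_young = -2.2, beta_young = 3,
                            young_threshold_cm = 30,
                            p_fruiting = 0.28, p_flowering = 0.2,
                            p_young_flowering = 0.02,
                            scatter_sd = 25, seed = 1) {
  stopifnot(beta_len <= 0, beta_young >= 0, all(niche_width > 0), scatter_sd > 0)
  structure(list(niche_center = niche_center, niche_width = niche_width, v = v,
                 mu0 = mu0, beta_len = beta_len,
                 alpha_young = alpha_young, beta_young = beta_young,
                 young_threshold_cm = young_threshold_cm,
                 p_fruiting = p_fruiting, p_flowering = p_flowering,
                 p_young_flowering = p_young_flowering,
                 scatter_sd = scatter_sd, seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Gaussian-niche suitability over cells, in (0, 1]
niche_suitability <- function(stack, truth) {
  X <- stack_values(stack)
  centers <- rep_len(truth$niche_center, ncol(X))
  if (!is.null(names(truth$niche_center)))
    centers <- truth$niche_center[colnames(X)]
  widths <- rep_len(truth$niche_width, ncol(X))
  q <- sweep(X, 2, centers)
  exp(-rowSums(sweep(q^2, 2, 2 * widths^2, "/")))
}

#' Generate clustered occurrences and per-population censuses
#'
#' Population centres are drawn from cells in the top suitability decile of a
#' Gaussian climatic niche, positioned along the first predictor's axis so
#' that planted vulnerability corresponds to greater suitability loss under a
#' positive (warming/drying) shift. Plants are scattered around each centre;
#' each gets a gamma-distributed stem length whose mean and young fraction
#' follow the truth's demographic coupling, and a reproductive status (only
#' plants above the young threshold fruit; flowering below it is rare).
#'
#' @param stack present-day [climate_stack()].
#' @param truth a [synthetic_truth()].
#' @param n_populations number of populations (>= 2); must match `length(truth$v)`.
#' @param plants_per_population integer vector of census sizes, one per
#'   population. The default is a 13-population census totalling 1615 plants.
#' @param seed integer RNG seed.
#' @return A list with `census` (tibble: `plant_id`, `population`, `x`, `y`,
#'   `stem_length_cm`, `status`), `populations` (tibble of per-population
#'   ground truth: planted `v`, target mean stem, target young fraction,
#'   centre coordinates) and the `truth` object.
#' @export
generate_species_occurrences <- function(stack, truth = synthetic_truth(),
                                         n_populations = length(truth$v),
                                         plants_per_population = c(11, 209, 109, 4, 77, 298, 22,
                                                                   283, 181, 89, 251, 33, 48),
                                         seed = truth$seed) {
  stopifnot(inherits(stack, "climate_stack"), inherits(truth, "synthetic_truth"))
  if (n_populations < 2) stop("need at least 2 populations")
  if (length(plants_per_population) != n_populations)
    stop("plants_per_population length mismatch: expected ", n_populations)
  if (any(plants_per_population < 1)) stop("every population needs at least 1 plant")
  if (length(truth$v) != n_populations) stop("truth$v length must equal n_populations")

  withr::local_seed(as.integer(seed))
  g <- stack$geom
  p <- niche_suitability(stack, truth)
  top <- which(p >= stats::quantile(p, 0.9))
  if (length(top) < n_populations) stop("too few high-suitability cells for the populations")
  centers <- cell_centers(g)

  # place populations along the first predictor within the top decile:
  # higher planted v -> further up the axis -> more suitability lost when the
  # future shifts the predictors upwards. Cells are matched to the target on
  # the coupling axis and to the niche centre on the remaining predictors, so
  # the realized suitability loss tracks the planted gradient.
  X <- stack_values(stack)
  centers_j <- rep_len(truth$niche_center, ncol(X))
  if (!is.null(names(truth$niche_center))) centers_j <- truth$niche_center[colnames(X)]
  w1 <- rep_len(truth$niche_width, 1)
  c1 <- centers_j[1]
  vr <- range(truth$v)
  rel <- if (diff(vr) > 0) (truth$v - vr[1]) / diff(vr) else rep(0.5, n_populations)
  target <- c1 + (-0.3 + 1.3 * rel) * w1
  off_axis <- if (ncol(X) > 1)
    rowSums(sweep(X[, -1, drop = FALSE], 2, centers_j[-1])^2) else rep(0, nrow(X))
  avail <- top
  pop_cell <- integer(n_populations)
  for (k in order(truth$v, decreasing = TRUE)) {
    i <- which.min((X[avail, 1] - target[k])^2 + 0.25 * off_axis[avail])
    pop_cell[k] <- avail[i]
    avail <- avail[-i]
  }

  pop_ids <- sprintf("P%02d", seq_len(n_populations))
  xmax <- g$xmin + g$n_cols * g$cellsize
  ymax <- g$ymin + g$n_rows * g$cellsize
  th <- truth$young_threshold_cm

  pops <- vector("list", n_populations)
  for (k in seq_len(n_populations)) {
    ctr <- centers[centers$cell == pop_cell[k], ]
    cx <- ctr$x + stats::runif(1, -0.2, 0.2) * g$cellsize
    cy <- ctr$y + stats::runif(1, -0.2, 0.2) * g$cellsize
    n_k <- plants_per_population[k]
    mu_k <- truth$mu0 + truth$beta_len * truth$v[k]
    if (mu_k <= th) stop("target mean stem length must exceed the young threshold")
    pi_k <- stats::plogis(truth$alpha_young + truth$beta_young * truth$v[k])
    shp <- gamma_shape_for(mu_k, pi_k, th)
    x <- pmin(pmax(cx + stats::rnorm(n_k, sd = truth$scatter_sd), g$xmin), xmax - 1e-9)
    y <- pmin(pmax(cy + stats::rnorm(n_k, sd = truth$scatter_sd), g$ymin), ymax - 1e-9)
    stem <- stats::rgamma(n_k, shape = shp, scale = mu_k / shp)
    stem <- pmax(stem, 0.1)  # strictly positive
    young <- stem <= th
    u <- stats::runif(n_k)
    status <- ifelse(young,
                     ifelse(u < truth$p_young_flowering, "flowering", "non_reproductive"),
                     ifelse(u < truth$p_fruiting, "fruiting",
                            ifelse(u < truth$p_fruiting + truth$p_flowering,
                                   "flowering", "non_reproductive")))
    pops[[k]] <- tibble::tibble(
      population = pop_ids[k], x = x, y = y,
      stem_length_cm = stem, status = status,
      .v = truth$v[k], .mu = mu_k, .pi = pi_k, .cx = cx, .cy = cy)
  }
  census <- dplyr::bind_rows(pops)
  census$plant_id <- sprintf("%s-%04d", census$population,
                             stats::ave(seq_len(nrow(census)), census$population,
                                        FUN = seq_along))
  populations <- dplyr::distinct(census, .data$population, v = .data$.v,
                                 target_mean_stem = .data$.mu,
                                 target_young_frac = .data$.pi,
                                 center_x = .data$.cx, center_y = .data$.cy)
  census <- dplyr::select(census, "plant_id", "population", "x", "y",
                          "stem_length_cm", "status")
  list(census = census, populations = populations, truth = truth)
}

# gamma shape such that mean = mu and P(X <= threshold) = pi_target
gamma_shape_for <- function(mu, pi_target, threshold = 30) {
  stopifnot(mu > threshold, pi_target > 0, pi_target < 1)
  f <- function(ls) stats::pgamma(threshold, shape = exp(ls), scale = mu / exp(ls)) - pi_target
  lo <- log(0.02); hi <- log(500)
  if (f(lo) < 0 || f(hi) > 0) stop("young fraction ", signif(pi_target, 3),
                                   " unreachable for mean ", signif(mu, 3))
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}
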