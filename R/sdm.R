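#' Rasterize occurrence points to valid occurrences
#'
#' Presence points are collapsed to one "valid occurrence" per occupied grid
#' cell — the unit at which suitability models are fitted. Cell membership
#' follows the half-open convention of [cell_index()].
#'
#' @param points data frame with columns `x`, `y` (m).
#' @param geom grid geometry (or a `grid_raster` / `climate_stack`).
#' @return An `occurrence_set`: list with `presence` (tibble: `cell`, `row`,
#'   `col`, `x`, `y` of the cell centre, `n_points`), the geometry, and
#'   `n_points` (raw point count).
#' @export
rasterize_occurrences <- function(points, geom) {
  geom <- as_geometry(geom)
  stopifnot(all(c("x", "y") %in% names(points)))
  idx <- cell_index(geom, points$x, points$y)
  if (all(is.na(idx$cell))) stop("zero in-grid points")
  if (anyNA(idx$cell)) {
    warning(sum(is.na(idx$cell)), " point(s) outside the grid dropped")
    idx <- idx[!is.na(idx$cell), ]
  }
  counts <- dplyr::count(idx, .data$cell, name = "n_points")
  ctr <- cell_centers(geom)
  presence <- dplyr::inner_join(ctr, counts, by = "cell")
  structure(list(presence = presence, geom = geom, n_points = nrow(idx),
                 absence = tibble::tibble(cell = integer(), pa_scenario = integer())),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d valid occurrences from %d points",
              nrow(x$presence), x$n_points))
  if (nrow(x$absence))
    cat(sprintf("; %d pseudo-absences in %d scenario(s)",
                nrow(x$absence), length(unique(x$absence$pa_scenario))))
  cat("\n")
  invisible(x)
}

#' Sample random pseudo-absence scenarios
#'
#' Draws `n_scenarios` independent sets of `n_pa` cells, uniformly without
#' replacement over cells that hold no presence (optionally restricted to a
#' domain mask). Pseudo-absences stand in for true absences when only
#' presences exist.
#'
#' @param occ an `occurrence_set` from [rasterize_occurrences()].
#' @param n_pa pseudo-absences per scenario; default `max(100, 10 * presences)`
#'   capped at the number of available cells.
#' @param n_scenarios number of independent pseudo-absence draws (default 5).
#' @param seed integer RNG seed; the whole draw is deterministic given it.
#' @param domain optional `grid_raster` mask: cells that are `NA` or 0 are
#'   excluded from sampling.
#' @return The `occurrence_set` with its `absence` tibble filled
#'   (`cell`, `pa_scenario`).
#' @export
sample_pseudo_absences <- function(occ, n_pa = NULL, n_scenarios = 5, seed = 1,
                                   domain = NULL) {
  stopifnot(inherits(occ, "occurrence_set"))
  g <- occ$geom
  all_cells <- seq_len(g$n_rows * g$n_cols)
  if (!is.null(domain)) {
    stopifnot(inherits(domain, "grid_raster"), geom_equal(domain$geom, g))
    dv <- raster_values(domain)
    all_cells <- all_cells[!is.na(dv) & dv != 0]
  }
  avail <- setdiff(all_cells, occ$presence$cell)
  if (is.null(n_pa)) n_pa <- min(max(100, 10 * nrow(occ$presence)), length(avail))
  if (length(avail) < n_pa) stop("domain too small: ", length(avail),
                                 " non-presence cells for n_pa = ", n_pa)
  withr::local_seed(as.integer(seed))
  draws <- lapply(seq_len(n_scenarios), function(s)
    tibble::tibble(cell = sort(sample(avail, n_pa)), pa_scenario = s))
  occ$absence <- dplyr::bind_rows(draws)
  occ
}

#' Assemble a labelled training table for one pseudo-absence scenario
#'
#' @param occ an `occurrence_set` with pseudo-absences.
#' @param stack a [climate_stack()] of predictors.
#' @param pa_scenario which pseudo-absence scenario to use.
#' @return Tibble with `label` (1 presence / 0 pseudo-absence), `cell`, and
#'   one column per predictor.
#' @export
sdm_training_data <- function(occ, stack, pa_scenario = 1) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(stack, "climate_stack"))
  if (!geom_equal(occ$geom, stack$geom)) stop("occurrences and stack geometry mismatch")
  X <- stack_values(stack)
  pa <- occ$absence$cell[occ$absence$pa_scenario == pa_scenario]
  if (!length(pa)) stop("no pseudo-absences for scenario ", pa_scenario)
  cells <- c(occ$presence$cell, pa)
  out <- tibble::as_tibble(X[cells, , drop = FALSE])
  dplyr::bind_cols(tibble::tibble(label = rep(c(1, 0), c(nrow(occ$presence), length(pa))),
                                  cell = cells), out)
}

#' Stratified calibration/test split
#'
#' Splits record indices into calibration and test sets, stratified by class
#' so each class contributes `round(ratio * n_class)` calibration records.
#'
#' @param labels binary class vector (0/1).
#' @param ratio calibration fraction, strictly between 0 and 1 (default 0.7).
#' @param seed integer RNG seed.
#' @return List with integer index vectors `calibration` and `test`
#'   (disjoint, exhaustive).
#' @export
split_calibration <- function(labels, ratio = 0.7, seed = 1) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be strictly between 0 and 1")
  if (length(labels) < 4) stop("need at least 4 records")
  tab <- table(labels)
  if (length(tab) < 2) stop("both classes must be present")
  if (any(tab < 2)) stop("each class needs at least 2 records")
  withr::local_seed(as.integer(seed))
  cal <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    n_cal <- round(ratio * length(idx))
    n_cal <- min(max(n_cal, 1), length(idx) - 1)  # both sides non-empty per class
    cal <- c(cal, sample(idx, n_cal))
  }
  cal <- sort(cal)
  list(calibration = cal, test = setdiff(seq_along(labels), cal))
}

#' Fit one suitability learner
#'
#' The native learner is a logistic regression (binomial likelihood, intercept
#' plus linear terms, fitted by iteratively reweighted least squares via
#' [stats::glm()]; deviance tolerance 1e-8, at most 100 iterations). Any other
#' algorithm attaches through the learner contract: pass a function
#' `fit(X, y)` returning a prediction function `function(X) -> scores in
#' [0, 1]`. `"rf"` uses a randomForest probability adapter when that package
#' is installed. Perfect separation is flagged with a warning; the learner is
#' still returned and its predictions are clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param data training tibble with a binary `label` column and predictor
#'   columns (a `cell` column, if present, is ignored as a predictor).
#' @param algorithm `"glm"` (linear terms), `"glm_quadratic"` (linear plus
#'   squared terms, the customary choice for unimodal climatic niches),
#'   `"maxent"` (maxent-style L1-regularized logistic regression on linear
#'   plus squared features via glmnet, with the penalty chosen by BIC along
#'   the regularization path — the stable choice when presences are few),
#'   `"rf"`, or a `fit(X, y)` function.
#' @return A `fitted_learner`: list with `algorithm`, `predict_fun`,
#'   `predictors`, `separation` flag and (for the GLM) `coefficients`.
#' @export
fit_learner <- function(data, algorithm = "glm") {
  stopifnot("label" %in% names(data))
  y <- data$label
  if (length(unique(y)) < 2) stop("both classes must be present in calibration data")
  predictors <- setdiff(names(data), c("label", "cell"))
  X <- as.matrix(data[predictors])
  clip <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)

  if (is.function(algorithm)) {
    pf <- algorithm(X, y)
    return(structure(list(algorithm = "custom", predict_fun = function(Xn) clip(pf(Xn)),
                          predictors = predictors, separation = FALSE),
                     class = "fitted_learner"))
  }
  algorithm <- match.arg(algorithm, c("glm", "glm_quadratic", "maxent", "rf"))
  if (algorithm == "maxent") {
    Q <- cbind(X, X^2)
    colnames(Q) <- c(predictors, paste0(predictors, "_sq"))
    fit <- glmnet::glmnet(Q, y, family = "binomial", nlambda = 50)
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    bic <- dev + log(length(y)) * fit$df
    lam <- fit$lambda[which.min(bic)]
    pf <- function(Xn) {
      Xn <- as.matrix(Xn[, predictors, drop = FALSE])
      Qn <- cbind(Xn, Xn^2)
      clip(as.numeric(stats::predict(fit, Qn, s = lam, type = "response")))
    }
    return(structure(list(algorithm = "maxent", predict_fun = pf, predictors = predictors,
                          separation = FALSE, lambda = lam), class = "fitted_learner"))
  }
  if (algorithm == "rf") {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("algorithm 'rf' needs the randomForest package")
    fit <- randomForest::randomForest(X, factor(y, levels = c(0, 1)), ntree = 500)
    pf <- function(Xn) clip(stats::predict(fit, Xn, type = "prob")[, "1"])
    return(structure(list(algorithm = "rf", predict_fun = pf, predictors = predictors,
                          separation = FALSE), class = "fitted_learner"))
  }
  quadratic <- algorithm == "glm_quadratic"
  expand <- function(M) {
    if (!quadratic) return(M)
    Q <- M^2
    colnames(Q) <- paste0(colnames(M), "_sq")
    cbind(M, Q)
  }
  df <- as.data.frame(expand(X))
  df$label <- y
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(label ~ ., family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep) warning("possible perfect separation; predictions clipped")
  cf <- stats::coef(fit)
  pf <- function(Xn) {
    Xn <- expand(as.matrix(Xn[, predictors, drop = FALSE]))
    eta <- drop(cbind(1, Xn) %*% cf)
    clip(stats::plogis(eta))
  }
  structure(list(algorithm = algorithm, predict_fun = pf, predictors = predictors,
                 separation = sep, coefficients = cf, model = fit),
            class = "fitted_learner")
}

#' True Skill Statistic at a threshold
#'
#' `TSS = sensitivity + specificity - 1` with presence predicted where
#' `score >= threshold`.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1).
#' @param threshold decision threshold on the score scale.
#' @return TSS in `[-1, 1]`.
#' @export
tss <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pred <- scores >= threshold
  sens <- mean(pred[labels == 1])
  spec <- mean(!pred[labels == 0])
  sens + spec - 1
}

#' Threshold maximizing the True Skill Statistic
#'
#' Scans candidate thresholds at the midpoints of consecutive sorted unique
#' scores (the unique score itself when all scores are equal) and returns the
#' argmax; ties return the lowest threshold.
#'
#' @inheritParams tss
#' @return List with `threshold` and the `tss` achieved there.
#' @export
best_threshold <- function(scores, labels) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) u else (u[-1] + u[-length(u)]) / 2
  vals <- vapply(cand, function(th) tss(scores, labels, th), numeric(1))
  best <- min(which(vals == max(vals)))
  list(threshold = cand[best], tss = vals[best])
}

#' Combine learners into a TSS-weighted ensemble
#'
#' Members whose test TSS exceeds `tss_min` are retained with weights
#' proportional to their TSS (normalized to sum 1); the ensemble score is the
#' weighted mean of member scores, reported on a 0-1000 integer suitability
#' scale.
#'
#' @param members list of `fitted_learner`s, each carrying a `tss_test` field
#'   (as produced inside [fit_sdm_ensemble()]).
#' @param tss_min strict inclusion cutoff on test TSS (default 0.8).
#' @return An `ensemble_model`: list with `learners` (included members),
#'   `weights`, `members` (tibble of all candidates with `included` flag), and
#'   `predictors`.
#' @export
build_ensemble <- function(members, tss_min = 0.8) {
  stopifnot(length(members) >= 1)
  scores <- vapply(members, function(m) m$tss_test, numeric(1))
  keep <- scores > tss_min
  if (!any(keep))
    stop(sprintf("no member exceeds tss_min = %g (best achieved TSS = %.3f)",
                 tss_min, max(scores)))
  learners <- members[keep]
  w <- scores[keep] / sum(scores[keep])
  tab <- tibble::tibble(
    algorithm = vapply(members, function(m) m$algorithm, character(1)),
    pa_scenario = vapply(members, function(m) m$pa_scenario %||% NA_integer_, numeric(1)),
    repetition = vapply(members, function(m) m$repetition %||% NA_integer_, numeric(1)),
    tss = scores, included = keep)
  structure(list(learners = learners, weights = w, members = tab,
                 tss_min = tss_min, predictors = members[[1]]$predictors),
            class = "ensemble_model")
}

# weighted-mean ensemble prediction in [0, 1]
predict_ensemble <- function(model, X) {
  preds <- vapply(model$learners, function(m) m$predict_fun(X), numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  drop(preds %*% model$weights)
}

#' Fit the full pseudo-absence x repetition ensemble protocol
#'
#' Runs the complete protocol: for each pseudo-absence scenario and each
#' repetition, the labelled data are split 70/30 (stratified), each algorithm
#' is fitted on the calibration part and evaluated on the test part at its own
#' TSS-maximizing threshold. Members with test TSS above `tss_min` enter the
#' TSS-weighted ensemble. The ensemble's own binarization threshold is the
#' TSS-maximizing threshold of the ensemble score over all labelled cells,
#' reported on the 0-1000 scale. The default protocol (1 algorithm x 5
#' pseudo-absence scenarios x 15 repetitions) evaluates 75 members; with three
#' algorithms it is the classic 225-combination design.
#'
#' @param occ an `occurrence_set` (pseudo-absences are sampled here if absent).
#' @param stack predictor [climate_stack()].
#' @param algorithms character vector / list of algorithms for [fit_learner()].
#' @param n_pa_scenarios,n_reps protocol size (defaults 5 and 15).
#' @param split_ratio calibration fraction (default 0.7).
#' @param tss_min ensemble inclusion cutoff (default 0.8).
#' @param n_pa pseudo-absences per scenario (default as in
#'   [sample_pseudo_absences()]).
#' @param seed integer RNG seed driving pseudo-absence draws and splits.
#' @return An `ensemble_model` with, additionally, `threshold` (0-1000 integer
#'   binarization threshold), `tss` (ensemble TSS over all labelled cells at
#'   that threshold) and the training `geom`.
#' @export
fit_sdm_ensemble <- function(occ, stack, algorithms = "glm",
                             n_pa_scenarios = 5, n_reps = 15,
                             split_ratio = 0.7, tss_min = 0.8,
                             n_pa = NULL, seed = 1) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(stack, "climate_stack"))
  if (!nrow(occ$absence))
    occ <- sample_pseudo_absences(occ, n_pa = n_pa, n_scenarios = n_pa_scenarios,
                                  seed = seed)
  members <- list()
  for (s in seq_len(n_pa_scenarios)) {
    dat <- sdm_training_data(occ, stack, pa_scenario = s)
    for (r in seq_len(n_reps)) {
      split_seed <- (as.integer(seed) + 7919L * s + 104729L * r) %% .Machine$integer.max
      sp <- split_calibration(dat$label, ratio = split_ratio, seed = split_seed)
      cal <- dat[sp$calibration, ]
      tst <- dat[sp$test, ]
      for (alg in algorithms) {
        m <- suppressWarnings(fit_learner(cal, algorithm = alg))
        sc <- m$predict_fun(tst[m$predictors])
        bt <- best_threshold(sc, tst$label)
        m$tss_test <- bt$tss
        m$threshold_test <- bt$threshold
        m$pa_scenario <- s
        m$repetition <- r
        members[[length(members) + 1]] <- m
      }
    }
  }
  model <- build_ensemble(members, tss_min = tss_min)
  # ensemble threshold: TSS-maximizing cut of the ensemble score over all
  # labelled cells (presences + every pseudo-absence scenario)
  pooled <- dplyr::bind_rows(lapply(seq_len(n_pa_scenarios), function(s)
    sdm_training_data(occ, stack, pa_scenario = s)))
  pooled <- dplyr::distinct(pooled, .data$cell, .keep_all = TRUE)
  sc <- predict_ensemble(model, as.matrix(pooled[model$predictors]))
  bt <- best_threshold(sc, pooled$label)
  model$threshold <- as.integer(round(1000 * bt$threshold))
  model$tss <- bt$tss
  model$geom <- occ$geom
  model$occurrences <- occ
  model
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d/%d members (TSS > %g)",
              length(x$learners), nrow(x$members), x$tss_min))
  if (!is.null(x$threshold))
    cat(sprintf("; ensemble TSS %.3f, threshold %d/1000", x$tss, x$threshold))
  cat("\n")
  invisible(x)
}

#' Project an ensemble onto a climate stack
#'
#' Cellwise TSS-weighted ensemble suitability on the 0-1000 integer scale;
#' cells with any missing predictor propagate missing.
#'
#' @param model an `ensemble_model`.
#' @param stack a [climate_stack()] whose layers include the model predictors.
#' @param scenario label attached to the output map.
#' @return A `suitability_map` (a [grid_raster()] with integer values in
#'   `[0, 1000]` and a `scenario` field).
#' @export
project_ensemble <- function(model, stack, scenario = "present") {
  stopifnot(inherits(model, "ensemble_model"), inherits(stack, "climate_stack"))
  missing_layers <- setdiff(model$predictors, names(stack$layers))
  if (length(missing_layers))
    stop("missing predictor layer(s): ", paste(missing_layers, collapse = ", "))
  X <- stack_values(stack)[, model$predictors, drop = FALSE]
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (any(ok)) out[ok] <- round(1000 * predict_ensemble(model, X[ok, , drop = FALSE]))
  g <- stack$geom
  r <- grid_raster(matrix(out, g$n_rows, g$n_cols, byrow = TRUE),
                   g$xmin, g$ymin, g$cellsize, g$crs)
  r$scenario <- scenario
  class(r) <- c("suitability_map", class(r))
  r
}

#' Binarize a suitability map
#'
#' @param map a `suitability_map` (or any `grid_raster`).
#' @param threshold cut on the 0-1000 scale; cells at or above it become 1.
#' @return A `grid_raster` of 0/1 (NA propagates).
#' @export
binarize <- function(map, threshold) {
  stopifnot(inherits(map, "grid_raster"), threshold >= 0, threshold <= 1000)
  r <- grid_raster(ifelse(map$values >= threshold, 1, 0),
                   map$geom$xmin, map$geom$ymin, map$geom$cellsize, map$geom$crs)
  r
}
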