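test_that("rasterization collapses points to one valid occurrence per cell", {
  g <- grid_geometry(0, 0, 10, n_rows = 10, n_cols = 10)
  withr::local_seed(20)
  # 1615 points placed into exactly 14 distinct cells
  cells <- cell_centers(g)[sample.int(100, 14), ]
  pts <- cells[sample.int(14, 1615, replace = TRUE), c("x", "y")]
  pts$x <- pts$x + runif(1615, -4.9, 4.9)
  pts$y <- pts$y + runif(1615, -4.9, 4.9)
  occ <- rasterize_occurrences(pts, g)
  expect_equal(nrow(occ$presence), 14)
  expect_equal(occ$n_points, 1615)
  # all points in one cell -> one occurrence
  one <- rasterize_occurrences(data.frame(x = c(1, 2, 3), y = c(1, 2, 3)), g)
  expect_equal(nrow(one$presence), 1)
  # boundary points follow the half-open floor convention
  edge <- data.frame(x = c(10, 20), y = c(5, 5))
  occ_e <- rasterize_occurrences(edge, g)
  oracle <- unique((10 - 1 - floor(c(5, 5) / 10)) * 10 + floor(c(10, 20) / 10) + 1)
  expect_setequal(occ_e$presence$cell, oracle)
  expect_error(rasterize_occurrences(data.frame(x = -5, y = -5), g), "zero in-grid")
})

test_that("pseudo-absence draws are uniform, disjoint from presences, seed-stable", {
  g <- grid_geometry(0, 0, 1, n_rows = 10, n_cols = 10)
  occ <- rasterize_occurrences(data.frame(x = 0.5, y = 9.5), g)  # cell 1
  # n_pa = all available cells -> every non-presence cell selected
  all_pa <- sample_pseudo_absences(occ, n_pa = 99, n_scenarios = 1, seed = 1)
  expect_setequal(all_pa$absence$cell, setdiff(1:100, occ$presence$cell))
  # determinism and scenario independence
  a <- sample_pseudo_absences(occ, n_pa = 10, n_scenarios = 2, seed = 5)
  b <- sample_pseudo_absences(occ, n_pa = 10, n_scenarios = 2, seed = 5)
  expect_identical(a$absence, b$absence)
  expect_false(identical(a$absence$cell[a$absence$pa_scenario == 1],
                         a$absence$cell[a$absence$pa_scenario == 2]))
  expect_error(sample_pseudo_absences(occ, n_pa = 100), "domain too small")
  # chi-square uniformity over many draws on a 100-cell domain
  many <- sample_pseudo_absences(occ, n_pa = 10, n_scenarios = 1000, seed = 99)
  counts <- table(factor(many$absence$cell, levels = setdiff(1:100, occ$presence$cell)))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.001)
})

test_that("calibration split is stratified, disjoint and exhaustive", {
  labels <- rep(c(1, 0), c(10, 10))
  sp <- split_calibration(labels, ratio = 0.7, seed = 1)
  expect_length(sp$calibration, 14)
  expect_equal(sum(labels[sp$calibration]), 7)
  expect_setequal(c(sp$calibration, sp$test), 1:20)
  expect_length(intersect(sp$calibration, sp$test), 0)
  expect_error(split_calibration(labels, ratio = 1), "strictly between")
  expect_error(split_calibration(c(1, 0, 0, 0), ratio = 0.7), "at least 2")
})

test_that("logistic learner matches a brute-force likelihood grid", {
  d <- tibble::tibble(p1 = c(-1.5, -1, -0.5, -0.2, 0.2, 0.5, 1, 1.5),
                      label = c(0, 0, 1, 0, 1, 0, 1, 1))
  m <- fit_learner(d, "glm")
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * d$p1
    sum(d$label * eta - log1p(exp(eta)))
  }
  # two-stage grid refinement around the optimum
  b0g <- seq(-3, 3, length.out = 61); b1g <- seq(-1, 6, length.out = 71)
  for (pass in 1:3) {
    ll <- outer(b0g, b1g, Vectorize(loglik))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    c0 <- b0g[best[1]]; c1 <- b1g[best[2]]
    h0 <- diff(b0g[1:2]); h1 <- diff(b1g[1:2])
    b0g <- seq(c0 - 2 * h0, c0 + 2 * h0, length.out = 41)
    b1g <- seq(c1 - 2 * h1, c1 + 2 * h1, length.out = 41)
  }
  expect_equal(unname(m$coefficients[1]), c0, tolerance = 1e-3)
  expect_equal(unname(m$coefficients[2]), c1, tolerance = 1e-3)
  # duplicating every row leaves the MLE unchanged
  m2 <- fit_learner(dplyr::bind_rows(d, d), "glm")
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-8)
})

test_that("learner contract accepts custom fit functions and flags separation", {
  d <- tibble::tibble(p1 = c(-2, -1, 1, 2), label = c(0, 0, 1, 1))
  expect_warning(m <- fit_learner(d, "glm"), "separation")
  expect_true(m$separation)
  p <- m$predict_fun(tibble::tibble(p1 = c(-10, 10)))
  expect_true(all(p >= 1e-6 & p <= 1 - 1e-6))
  custom <- fit_learner(d, function(X, y) function(Xn) rep(0.5, nrow(Xn)))
  expect_equal(custom$predict_fun(tibble::tibble(p1 = 1:3)), rep(0.5, 3))
})

test_that("TSS equals sensitivity + specificity - 1", {
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 3), rep(0.1, 7))
  labels <- rep(c(1, 0), c(10, 10))
  expect_equal(tss(scores, labels, 0.5), 0.5)  # sens 0.8 + spec 0.7 - 1
  expect_equal(tss(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.5), 1)
  withr::local_seed(21)
  big <- tss(runif(4000), rep(c(0, 1), 2000), 0.5)
  expect_lt(abs(big), 0.05)
  expect_error(tss(1:3, c(1, 1, 1), 0.5), "both classes")
})

test_that("best_threshold matches an exhaustive midpoint scan", {
  bt <- best_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(bt$threshold, 0.5)
  expect_equal(bt$tss, 1)
  expect_equal(best_threshold(rep(0.4, 6), rep(c(0, 1), 3))$tss, 0)
  withr::local_seed(22)
  for (i in 1:5) {
    sc <- round(runif(20), 2)
    lb <- rbinom(20, 1, 0.5)
    if (length(unique(lb)) < 2) next
    u <- sort(unique(sc))
    cand <- if (length(u) == 1) u else (u[-1] + u[-length(u)]) / 2
    oracle_tss <- vapply(cand, function(th) {
      pred <- sc >= th
      mean(pred[lb == 1]) + mean(!pred[lb == 0]) - 1
    }, numeric(1))
    bt <- best_threshold(sc, lb)
    expect_equal(bt$tss, max(oracle_tss))
    expect_equal(bt$threshold, cand[min(which(oracle_tss == max(oracle_tss)))])
  }
})

stub_learner <- function(score, tss) {
  structure(list(algorithm = "stub", predictors = "p1", separation = FALSE,
                 predict_fun = function(X) rep(score, nrow(X)), tss_test = tss),
            class = "fitted_learner")
}

test_that("ensembles weight members by TSS and apply the strict inclusion cut", {
  X <- matrix(0, 1, 1, dimnames = list(NULL, "p1"))
  eq <- build_ensemble(list(stub_learner(0.2, 0.9), stub_learner(0.8, 0.9)))
  expect_equal(popvuln:::predict_ensemble(eq, X), 0.5)
  cut <- build_ensemble(list(stub_learner(0.2, 0.79), stub_learner(0.8, 0.81)))
  expect_length(cut$learners, 1)
  expect_equal(popvuln:::predict_ensemble(cut, X), 0.8)
  tri <- build_ensemble(list(stub_learner(0.2, 0.9), stub_learner(0.6, 0.85),
                             stub_learner(1.0, 0.82)))
  hand <- sum(c(0.9, 0.85, 0.82) / sum(c(0.9, 0.85, 0.82)) * c(0.2, 0.6, 1.0))
  expect_equal(popvuln:::predict_ensemble(tri, X), hand)
  expect_error(build_ensemble(list(stub_learner(0.5, 0.7))), "0.700")
})

test_that("projection is bounded by member scores and monotone for one predictor", {
  stk <- small_stack(12, "p1", seed = 23)
  withr::local_seed(23)
  d <- tibble::tibble(p1 = seq(-2, 2, length.out = 40),
                      label = rbinom(40, 1, plogis(3 * seq(-2, 2, length.out = 40))))
  m <- suppressWarnings(fit_learner(d, "glm"))
  m$tss_test <- 0.9
  ens <- build_ensemble(list(m))
  map <- project_ensemble(ens, stk)
  expect_true(all(map$values >= 0 & map$values <= 1000))
  ord <- order(as.vector(t(stk$layers$p1)))
  suit <- as.vector(t(map$values))[ord]
  expect_true(all(diff(suit) >= 0))  # logistic in one increasing predictor
  # constant stack -> constant map
  cstk <- climate_stack(list(p1 = matrix(0.3, 12, 12)))
  cmap <- project_ensemble(ens, cstk)
  expect_equal(length(unique(as.vector(cmap$values))), 1)
  expect_error(project_ensemble(ens, small_stack(12, "zz", seed = 1)),
               "missing predictor")
  # convex combination: ensemble bounded by member extremes at every cell
  m2 <- suppressWarnings(fit_learner(tibble::tibble(p1 = d$p1, label = rev(d$label)), "glm"))
  m2$tss_test <- 0.85
  ens2 <- build_ensemble(list(m, m2))
  X <- stack_values(stk)
  p1v <- m$predict_fun(X); p2v <- m2$predict_fun(X)
  pe <- popvuln:::predict_ensemble(ens2, X)
  expect_true(all(pe >= pmin(p1v, p2v) - 1e-12 & pe <= pmax(p1v, p2v) + 1e-12))
})

test_that("binarize cuts at the threshold inclusively", {
  vals <- matrix(c(740, 747, 750, 0, 1000, 746, 748, 747.5, 746.9), 3, 3, byrow = TRUE)
  map <- grid_raster(vals)
  b <- binarize(map, 747)
  expect_equal(b$values, (vals >= 747) * 1)
  expect_true(all(binarize(map, 0)$values == 1))
  expect_equal(sum(binarize(map, 1000)$values), 1)
})

test_that("the full protocol enumerates every combination and passes the TSS bar", {
  stk <- generate_climate_stack(48, 48, seed = 30)
  truth <- synthetic_truth(seed = 30)
  syn <- generate_species_occurrences(stk, truth, seed = 30)
  occ <- rasterize_occurrences(syn$census, stk)
  model <- fit_sdm_ensemble(occ, stk, algorithms = c("glm", "glm_quadratic", "maxent"),
                            n_pa_scenarios = 5, n_reps = 15, seed = 30)
  expect_equal(nrow(model$members), 225)  # 3 algorithms x 5 PA scenarios x 15 reps
  expect_gt(model$tss, 0.8)
  expect_true(model$threshold >= 0 && model$threshold <= 1000)
  expect_true(all(abs(model$weights - model$members$tss[model$members$included] /
                        sum(model$members$tss[model$members$included])) < 1e-12))
})
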