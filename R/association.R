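#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# resolve a column given as bare name or string
pull_col <- function(data, quo, what) {
  v <- rlang::eval_tidy(quo, data)
  if (is.character(v) && length(v) == 1 && v %in% names(data)) v <- data[[v]]
  if (!is.numeric(v)) stop(what, " must resolve to a numeric column")
  v
}

label_of <- function(data, quo) {
  v <- tryCatch(rlang::eval_tidy(quo, data), error = function(e) NULL)
  if (is.character(v) && length(v) == 1 && v %in% names(data)) v else rlang::as_label(quo)
}

new_regression_result <- function(...) {
  structure(list(...), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s: %s ~ %s (n = %d)\n",
              x$family, x$response, x$term, x$n))
  cat(sprintf("  slope %.4g [%.4g, %.4g], %s = %.3f, p = %.4g, %s = %.3f\n",
              x$slope, x$ci_lower, x$ci_upper, x$statistic_type, x$statistic,
              x$p_value, x$r_squared_type, x$r_squared))
  if (!is.null(x$shapiro_w) && is.finite(x$shapiro_w))
    cat(sprintf("  residual normality: W = %.3f, p = %.4g\n", x$shapiro_w, x$shapiro_p))
  invisible(x)
}

#' @rdname linear_fit
#' @param x a `regression_result`.
#' @param ... unused.
#' @export
tidy.regression_result <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$term),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    statistic = c(x$intercept_stat, x$slope_stat),
    p.value = c(x$intercept_p, x$p_value))
}

#' @rdname linear_fit
#' @export
glance.regression_result <- function(x, ...) {
  tibble::tibble(family = x$family, slope = x$slope,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 statistic = x$statistic, statistic_type = x$statistic_type,
                 p.value = x$p_value, r.squared = x$r_squared,
                 r.squared_type = x$r_squared_type, n = x$n,
                 shapiro_w = x$shapiro_w %||% NA_real_,
                 shapiro_p = x$shapiro_p %||% NA_real_)
}

#' Linear association between a population parameter and vulnerability
#'
#' Ordinary least squares of a population-level parameter on mean CCVI.
#' Reports the overall regression F with (1, n-2) df (equal to the squared
#' slope t for a single predictor), its two-sided p-value, R-squared, the 95%
#' slope confidence interval and a Shapiro-Wilk normality check on residuals.
#'
#' @param data data frame with one row per population.
#' @param y,x response and predictor columns (bare names or strings).
#' @return A `regression_result`; see also [tidy()] and [glance()] methods.
#' @export
linear_fit <- function(data, y, x) {
  yv <- pull_col(data, rlang::enquo(y), "y")
  xv <- pull_col(data, rlang::enquo(x), "x")
  n <- length(yv)
  if (n < 3) stop("need at least 3 observations")
  if (stats::var(xv) == 0) stop("zero variance in x")
  fit <- stats::lm(yv ~ xv)
  s <- summary(fit)
  co <- s$coefficients
  fstat <- unname(s$fstatistic[1])
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  ci <- stats::confint(fit)["xv", ]
  sw <- tryCatch(shapiro_wilk(stats::residuals(fit)),
                 error = function(e) list(W = NA_real_, p = NA_real_))
  new_regression_result(
    family = "linear", response = label_of(data, rlang::enquo(y)),
    term = label_of(data, rlang::enquo(x)),
    slope = co["xv", 1], slope_se = co["xv", 2], slope_stat = co["xv", 3],
    intercept = co[1, 1], intercept_se = co[1, 2], intercept_stat = co[1, 3],
    intercept_p = co[1, 4],
    statistic = fstat, statistic_type = "F", p_value = p,
    r_squared = s$r.squared, r_squared_type = "R2",
    ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
    n = n, shapiro_w = sw$W, shapiro_p = sw$p, converged = TRUE, fit = fit)
}

#' Binomial association between a proportion and vulnerability
#'
#' Logit-link binomial GLM of aggregated per-population counts (successes out
#' of totals) on mean CCVI. The default count weighting is equivalent to
#' weighting proportions by population size; `weighted = FALSE` instead treats
#' each population's proportion as a single observation. The slope's Wald Z
#' and two-sided p-value are reported along with a pseudo-R-squared:
#' `r2_form = "deviance"` (default) is `1 - D_model / D_null`, which for
#' ungrouped data coincides with McFadden's measure and is the customary
#' "McFadden approximation" on aggregated counts; `r2_form = "loglik"` is the
#' strict McFadden ratio `1 - l_model / l_null` on the aggregated likelihood.
#'
#' @param data data frame with one row per population.
#' @param successes,totals count columns (bare names or strings), with
#'   `0 <= successes <= totals`.
#' @param x predictor column.
#' @param weighted count-weighted fit (default) or per-population proportions.
#' @param r2_form `"deviance"` or `"loglik"`.
#' @return A `regression_result`.
#' @export
binomial_fit <- function(data, successes, totals, x, weighted = TRUE,
                         r2_form = c("deviance", "loglik")) {
  r2_form <- match.arg(r2_form)
  sv <- pull_col(data, rlang::enquo(successes), "successes")
  tv <- pull_col(data, rlang::enquo(totals), "totals")
  xv <- pull_col(data, rlang::enquo(x), "x")
  n <- length(sv)
  if (n < 3) stop("need at least 3 populations")
  if (any(sv < 0) || any(sv > tv)) stop("need 0 <= successes <= totals")
  if (all(sv == 0) || all(sv == tv)) stop("degenerate likelihood: all-zero or all-total successes")
  if (weighted) {
    fit <- stats::glm(cbind(sv, tv - sv) ~ xv, family = stats::binomial())
    fit0 <- stats::glm(cbind(sv, tv - sv) ~ 1, family = stats::binomial())
  } else {
    pv <- sv / tv
    fit <- suppressWarnings(stats::glm(pv ~ xv, family = stats::binomial()))
    fit0 <- suppressWarnings(stats::glm(pv ~ 1, family = stats::binomial()))
  }
  co <- summary(fit)$coefficients
  z <- co["xv", 3]
  p <- 2 * stats::pnorm(-abs(z))
  r2 <- if (r2_form == "deviance") {
    if (fit$null.deviance < 1e-12) 0 else 1 - fit$deviance / fit$null.deviance
  } else {
    1 - as.numeric(stats::logLik(fit)) / as.numeric(stats::logLik(fit0))
  }
  ci <- co["xv", 1] + c(-1, 1) * stats::qnorm(0.975) * co["xv", 2]
  new_regression_result(
    family = "binomial", response = label_of(data, rlang::enquo(successes)),
    term = label_of(data, rlang::enquo(x)),
    slope = co["xv", 1], slope_se = co["xv", 2], slope_stat = z,
    intercept = co[1, 1], intercept_se = co[1, 2], intercept_stat = co[1, 3],
    intercept_p = co[1, 4],
    statistic = z, statistic_type = "Z", p_value = p,
    r_squared = r2,
    r_squared_type = if (r2_form == "deviance") "McFadden (deviance form)" else "McFadden",
    ci_lower = ci[1], ci_upper = ci[2], n = n,
    shapiro_w = NA_real_, shapiro_p = NA_real_, converged = fit$converged, fit = fit)
}

#' Robust linear association at the individual-plant level
#'
#' MM-type robust regression (high-breakdown S-estimate initialization
#' followed by M-refinement with the Tukey bisquare psi at 95% Gaussian
#' efficiency, via [MASS::rlm()]): a linear regression insensitive to
#' outliers, suited to noisy per-plant measurements. The robust Wald test of
#' the slope is reported as `F = t^2` with (1, n-2) df, together with a
#' weighted robust R-squared computed from the final IRLS weights.
#'
#' @param data data frame, one row per plant.
#' @param y,x response and predictor columns (bare names or strings).
#' @param maxit maximum IRLS iterations.
#' @param seed RNG seed for the S-estimate's subsampling, making the fit
#'   reproducible.
#' @return A `regression_result`; `converged = FALSE` flags non-convergence.
#' @export
robust_linear_fit <- function(data, y, x, maxit = 100, seed = 1) {
  yv <- pull_col(data, rlang::enquo(y), "y")
  xv <- pull_col(data, rlang::enquo(x), "x")
  n <- length(yv)
  if (n < 5) stop("need at least 5 observations")
  withr::local_seed(as.integer(seed))
  fit <- MASS::rlm(yv ~ xv, method = "MM", psi = MASS::psi.bisquare,
                   maxit = maxit)
  if (!fit$converged) warning("robust fit did not converge within ", maxit, " iterations")
  co <- summary(fit)$coefficients
  tval <- co["xv", 3]
  fstat <- tval^2
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  ci <- co["xv", 1] + c(-1, 1) * stats::qt(0.975, n - 2) * co["xv", 2]
  w <- fit$w
  wm <- stats::weighted.mean(yv, w)
  r2 <- 1 - sum(w * stats::residuals(fit)^2) / sum(w * (yv - wm)^2)
  new_regression_result(
    family = "robust_linear", response = label_of(data, rlang::enquo(y)),
    term = label_of(data, rlang::enquo(x)),
    slope = co["xv", 1], slope_se = co["xv", 2], slope_stat = tval,
    intercept = co[1, 1], intercept_se = co[1, 2], intercept_stat = co[1, 3],
    intercept_p = NA_real_,
    statistic = fstat, statistic_type = "F", p_value = p,
    r_squared = r2, r_squared_type = "robust R2",
    ci_lower = ci[1], ci_upper = ci[2], n = n,
    shapiro_w = NA_real_, shapiro_p = NA_real_,
    converged = fit$converged, fit = fit)
}

#' Shapiro-Wilk normality check
#'
#' @param residuals numeric vector, `3 <= n <= 5000`, non-constant.
#' @return List with `W` and the two-sided `p` for the normality null.
#' @export
shapiro_wilk <- function(residuals) {
  n <- length(residuals)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk needs 3 <= n <= 5000")
  if (stats::sd(residuals) == 0) stop("zero variance: normality test undefined")
  t <- stats::shapiro.test(residuals)
  list(W = unname(t$statistic), p = t$p.value)
}

#' Compare two slopes by confidence-interval overlap
#'
#' Reports whether the 95% slope confidence intervals of two fitted models
#' are disjoint (closed-interval convention: touching endpoints overlap) and
#' how the slopes order.
#'
#' @param result_a,result_b `regression_result`s carrying confidence
#'   intervals.
#' @return List with `disjoint` (logical), `ordering` (`"a < b"`, `"a > b"`
#'   or `"overlap"`), and both intervals.
#' @export
slope_ci_compare <- function(result_a, result_b) {
  for (r in list(result_a, result_b))
    if (is.null(r$ci_lower) || !is.finite(r$ci_lower)) stop("missing confidence interval")
  a <- c(result_a$ci_lower, result_a$ci_upper)
  b <- c(result_b$ci_lower, result_b$ci_upper)
  disjoint <- a[2] < b[1] || b[2] < a[1]
  ordering <- if (!disjoint) "overlap" else if (a[2] < b[1]) "a < b" else "a > b"
  list(disjoint = disjoint, ordering = ordering, ci_a = a, ci_b = b,
       slope_a = result_a$slope, slope_b = result_b$slope)
}

#' Fit the standard suite of demography-vulnerability models
#'
#' Convenience wrapper producing a results table in the layout of the study's
#' statistics table: linear models of mean stem length on mean CCVI (overall
#' and high-emission scenario), count-weighted binomial models of the young
#' proportion on the same, and (when a per-plant table is supplied) robust
#' linear models of fruiting-plant stem length on per-plant CCVI.
#'
#' @param summaries per-population tibble with columns `mean_stem_cm`,
#'   `n_young`, `n_adult` and the CCVI columns named in `scenarios`.
#' @param scenarios named character vector mapping a scenario label to the
#'   CCVI column holding the per-population means.
#' @param plants optional per-plant tibble with `stem_length_cm`, `status`
#'   and per-plant CCVI columns named in `plant_scenarios`.
#' @param plant_scenarios like `scenarios`, for the per-plant table.
#' @return Tibble with one row per fitted model: response, scenario, family,
#'   statistic, p-value, fit measure, n, Shapiro-Wilk W and p.
#' @export
association_table <- function(summaries,
                              scenarios = c("CCVI 2055" = "mean_ccvi",
                                            "CCVI 2055 SSP5-RCP8.5" = "mean_ccvi_ssp585"),
                              plants = NULL, plant_scenarios = scenarios) {
  rows <- list()
  as_row <- function(res, response, scenario) {
    g <- glance(res)
    tibble::tibble(response = response, scenario = scenario, family = g$family,
                   statistic_type = g$statistic_type, statistic = g$statistic,
                   p_value = g$p.value, r_squared = g$r.squared,
                   r_squared_type = g$r.squared_type, n = g$n,
                   shapiro_w = g$shapiro_w, shapiro_p = g$shapiro_p)
  }
  for (i in seq_along(scenarios)) {
    xcol <- scenarios[[i]]
    lab <- names(scenarios)[i]
    rows[[length(rows) + 1]] <- as_row(
      linear_fit(summaries, "mean_stem_cm", xcol), "Mean stem length (cm)", lab)
    d <- dplyr::mutate(summaries, .tot = .data$n_young + .data$n_adult)
    rows[[length(rows) + 1]] <- as_row(
      binomial_fit(d, "n_young", ".tot", xcol), "Proportion of young plants (%)", lab)
  }
  if (!is.null(plants)) {
    fr <- plants[plants$status == "fruiting", ]
    for (i in seq_along(plant_scenarios)) {
      xcol <- plant_scenarios[[i]]
      rows[[length(rows) + 1]] <- as_row(
        robust_linear_fit(fr, "stem_length_cm", xcol),
        "Stem length (cm) (Fruiting plants)", names(plant_scenarios)[i])
    }
  }
  dplyr::bind_rows(rows)
}
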