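#' Pairwise Pearson correlation among stack layers
#'
#' Correlations are computed over cells, using pairwise-complete observations
#' when layers carry missing cells. A layer that is constant over its
#' non-missing cells has no defined correlation and is reported as an error.
#'
#' @param stack a [climate_stack()].
#' @param sample_cells optional number of cells to subsample (deterministic:
#'   an evenly spaced systematic sample); default uses all cells.
#' @return Symmetric numeric matrix of Pearson r with unit diagonal.
#' @export
correlation_matrix <- function(stack, sample_cells = NULL) {
  X <- stack_values(stack)
  if (ncol(X) < 2) stop("need at least 2 layers")
  if (!is.null(sample_cells) && sample_cells < nrow(X)) {
    idx <- round(seq(1, nrow(X), length.out = sample_cells))
    X <- X[idx, , drop = FALSE]
  }
  if (sum(stats::complete.cases(X)) < 3) stop("need at least 3 non-missing shared cells")
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds)))
    stop("constant layer(s): ", paste(colnames(X)[sds == 0 | is.na(sds)], collapse = ", "))
  r <- stats::cor(X, use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the least-squares
#' regression of predictor j on all the others plus an intercept. Exact
#' collinearity yields an `Inf` sentinel rather than an error. Rows with any
#' missing value are dropped (listwise).
#'
#' @param values_matrix numeric matrix, cells by predictors (or a
#'   [climate_stack()]).
#' @return Named numeric vector of VIFs (all >= 1, possibly `Inf`).
#' @export
vif <- function(values_matrix) {
  X <- if (inherits(values_matrix, "climate_stack")) stack_values(values_matrix) else
    as.matrix(values_matrix)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  p <- ncol(X)
  if (p < 2) return(stats::setNames(rep(1, p), colnames(X)))
  if (nrow(X) < p + 2) stop("need at least predictors + 2 complete rows")
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    if (sst == 0) return(Inf)
    r2 <- 1 - ssr / sst
    if (r2 > 1 - 1e-12) Inf else max(1, 1 / (1 - r2))
  }, numeric(1))
  stats::setNames(out, colnames(X))
}

#' Reduce a predictor stack to a low-collinearity subset
#'
#' Two-phase filter. Phase 1 (correlation): while any pair of kept layers has
#' `|r| > r_max`, take the highest-|r| pair and drop the member with the larger
#' mean |r| against all other kept layers (ties drop the layer later in input
#' order). Phase 2 (VIF): while any kept layer has `VIF >= vif_max`, drop the
#' highest-VIF layer (same tie-break). Both phases are deterministic.
#'
#' @param stack a [climate_stack()].
#' @param r_max maximum allowed pairwise |Pearson r| (default 0.7).
#' @param vif_max VIF bound; kept layers satisfy `VIF < vif_max` (default 10).
#' @return A `selection_report`: list with `kept` (character), `dropped`
#'   (tibble: `name`, `reason` in `correlation`/`vif`, `value` at removal),
#'   and the thresholds used.
#' @export
select_predictors <- function(stack, r_max = 0.7, vif_max = 10) {
  stopifnot(inherits(stack, "climate_stack"), r_max > 0, vif_max > 1)
  nms <- names(stack$layers)
  if (length(nms) < 2) stop("need at least 2 layers")
  X <- stack_values(stack)
  kept <- nms
  dropped <- list()

  drop_of_pair <- function(r, i, j) {
    # larger mean |r| to all others loses; tie -> later input position
    mi <- mean(abs(r[i, -i])); mj <- mean(abs(r[j, -j]))
    if (mi > mj) i else if (mj > mi) j else max(i, j)
  }

  repeat {
    if (length(kept) < 2) break
    r <- suppressWarnings(stats::cor(X[, kept, drop = FALSE], use = "pairwise.complete.obs"))
    a <- abs(r); diag(a) <- 0
    if (max(a, na.rm = TRUE) <= r_max) break
    idx <- which(a == max(a, na.rm = TRUE), arr.ind = TRUE)[1, ]
    d <- drop_of_pair(r, idx[1], idx[2])
    dropped[[length(dropped) + 1]] <- tibble::tibble(
      name = kept[d], reason = "correlation", value = a[idx[1], idx[2]])
    kept <- kept[-d]
  }
  if (length(kept) == 1)
    warning("all layers mutually collinear beyond r_max; keeping one layer")

  repeat {
    if (length(kept) < 2) break
    v <- vif(X[, kept, drop = FALSE])
    if (max(v) < vif_max) break
    d <- max(which(v == max(v)))  # tie -> later input order
    dropped[[length(dropped) + 1]] <- tibble::tibble(
      name = kept[d], reason = "vif", value = unname(v[d]))
    kept <- kept[-d]
  }

  structure(list(kept = kept,
                 dropped = if (length(dropped)) dplyr::bind_rows(dropped) else
                   tibble::tibble(name = character(), reason = character(), value = numeric()),
                 r_max = r_max, vif_max = vif_max),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> kept %d layer(s): %s\n",
              length(x$kept), paste(x$kept, collapse = ", ")))
  if (nrow(x$dropped)) {
    cat(sprintf("  dropped %d (r_max = %g, vif_max = %g):\n",
                nrow(x$dropped), x$r_max, x$vif_max))
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("   - %s (%s = %.3f)\n", x$dropped$name[i],
                  x$dropped$reason[i], x$dropped$value[i]))
  }
  invisible(x)
}

#' Keep only selected layers of a stack
#'
#' @param stack a [climate_stack()].
#' @param report a `selection_report` (or a character vector of layer names).
#' @return A [climate_stack()] restricted to the kept layers.
#' @export
apply_selection <- function(stack, report) {
  keep <- if (inherits(report, "selection_report")) report$kept else report
  g <- stack$geom
  climate_stack(stack$layers[keep], xmin = g$xmin, ymin = g$ymin,
                cellsize = g$cellsize, crs = g$crs)
}
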