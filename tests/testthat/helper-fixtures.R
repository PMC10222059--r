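# small in-code fixtures shared across test files

# climate stack from explicit matrices on a unit grid
stack_from <- function(..., cellsize = 1, xmin = 0, ymin = 0) {
  climate_stack(list(...), xmin = xmin, ymin = ymin, cellsize = cellsize)
}

# a tiny reproducible smooth stack
small_stack <- function(n = 24, layers = c("bio03", "bio07", "bio15"), seed = 42,
                        range = 3) {
  generate_climate_stack(n, n, layers, autocorr_range = range, seed = seed,
                         cellsize = 1)
}

# direct rook-neighbour Moran's I, written independently of the package
moran_i_oracle <- function(m) {
  n_r <- nrow(m); n_c <- ncol(m)
  z <- m - mean(m)
  num <- 0; w_sum <- 0
  for (i in seq_len(n_r)) {
    for (j in seq_len(n_c)) {
      for (d in list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= n_r && jj >= 1 && jj <= n_c) {
          num <- num + z[i, j] * z[ii, jj]
          w_sum <- w_sum + 1
        }
      }
    }
  }
  (length(m) / w_sum) * num / sum(z^2)
}

# brute-force convex hull area: a point is a hull vertex iff some line through
# it keeps all other points on one side; area from the ordered vertex set
hull_area_oracle <- function(x, y) {
  n <- length(x)
  on_hull <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      side <- sign((x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i]))
      if (all(side >= 0) || all(side <= 0)) on_hull[i] <- TRUE
    }
  }
  hx <- x[on_hull]; hy <- y[on_hull]
  o <- order(atan2(hy - mean(hy), hx - mean(hx)))
  hx <- hx[o]; hy <- hy[o]
  j <- c(length(hx), seq_len(length(hx) - 1))
  abs(sum(hx[j] * hy - hx * hy[j])) / 2
}

# standard small census used by demography/io tests
toy_census <- function(seed = 7, n_pop = 3, n_each = 25) {
  withr::local_seed(seed)
  purrr::map_dfr(seq_len(n_pop), function(k) {
    tibble::tibble(
      population = sprintf("T%02d", k),
      x = runif(n_each, 0, 100) + 500 * k,
      y = runif(n_each, 0, 100),
      stem_length_cm = rgamma(n_each, shape = 2, scale = 25) + 0.5,
      status = sample(c("non_reproductive", "flowering", "fruiting"), n_each,
                      replace = TRUE))
  }) |>
    dplyr::mutate(plant_id = sprintf("%s-%03d", population,
                                     stats::ave(seq_along(population), population,
                                                FUN = seq_along)),
                  .before = 1)
}
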