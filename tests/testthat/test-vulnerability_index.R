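# convenience: suitability map from a matrix
suit_map <- function(vals, scenario = "future", cellsize = 1) {
  r <- grid_raster(vals, cellsize = cellsize)
  r$scenario <- scenario
  class(r) <- c("suitability_map", class(r))
  r
}

test_that("footprint overlay returns exactly the present cells, row-major", {
  fut <- suit_map(matrix(1:9, 3, 3, byrow = TRUE))
  all1 <- grid_raster(matrix(1, 3, 3))
  expect_equal(footprint_overlay(all1, fut)$suitability, 1:9)
  all0 <- grid_raster(matrix(0, 3, 3))
  expect_error(footprint_overlay(all0, fut), "empty footprint")
  corners <- grid_raster(matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  ov <- footprint_overlay(corners, fut)
  expect_equal(ov$cell, c(1L, 9L))
  expect_equal(ov$suitability, c(1, 9))
  expect_error(footprint_overlay(grid_raster(matrix(1, 2, 2)), fut), "geometry")
})

test_that("the index is the negated, centred, sd-scaled suitability", {
  vals <- c(700, 740, 760, 800)
  sig <- sd(vals)
  cc <- popvuln:::ccvi_values(vals, 747)
  oracle <- -(vals - 747) / sig
  expect_equal(cc, oracle)
  expect_equal(sign(cc), c(1, 1, -1, -1))
  # forced sign and unit-scale conventions
  expect_equal(popvuln:::ccvi_values(c(0, 10), 5)[1],
               -(0 - 5) / sd(c(0, 10)))
  some <- c(3, 5, 9, 11)
  s <- sd(some)
  expect_equal(popvuln:::ccvi_values(c(some, mean(some)), mean(some),
                                     sigma = s)[5], 0)
  pm <- popvuln:::ccvi_values(mean(some) + c(s, -s), mean(some), sigma = s)
  expect_equal(pm, c(-1, 1))
  expect_error(popvuln:::ccvi_values(rep(5, 4), 5), "zero variance")
})

test_that("vulnerability surfaces centre on the threshold or the footprint mean", {
  fut <- suit_map(matrix(c(700, 740, 760, 800), 2, 2, byrow = TRUE))
  pres <- grid_raster(matrix(1, 2, 2))
  surf <- ccvi_surface(pres, fut, center = "threshold", threshold = 747)
  expect_equal(as.vector(t(surf$values)), -(c(700, 740, 760, 800) - 747) / sd(c(700, 740, 760, 800)))
  expect_equal(surf$footprint_n, 4)
  m <- ccvi_surface(pres, fut, center = "mean")
  expect_equal(mean(m$values), 0)
  expect_equal(sd(as.vector(m$values)), 1)
  expect_error(ccvi_surface(pres, fut, center = "threshold"), "needs a threshold")
})

test_that("per-plant extraction uses the containing cell without interpolation", {
  fut <- suit_map(matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE), cellsize = 10)
  pres <- grid_raster(matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE), cellsize = 10)
  surf <- ccvi_surface(pres, fut, center = "mean")
  two <- extract_plant_ccvi(surf, data.frame(x = c(2, 8), y = c(15, 12)))
  expect_equal(two$ccvi[1], two$ccvi[2])  # same cell
  ctr <- extract_plant_ccvi(surf, data.frame(x = 5, y = 15))
  expect_equal(ctr$ccvi, as.vector(surf$values[1, 1]))
  # boundary point goes to the right-hand cell (half-open convention)
  edge <- extract_plant_ccvi(surf, data.frame(x = 10, y = 15))
  expect_equal(edge$ccvi, as.vector(surf$values[1, 2]))
  expect_warning(out <- extract_plant_ccvi(surf, data.frame(x = 15, y = 2)),
                 "outside the present-distribution footprint")
  expect_true(is.na(out$ccvi))
  expect_error(extract_plant_ccvi(surf, data.frame(x = 50, y = 5)), "outside grid")
})

test_that("population summaries and scenario averages follow plain arithmetic", {
  p <- population_ccvi(c(1.0, 1.2, 0.5), c("A", "A", "B"), "all-2055")
  expect_equal(p$mean_ccvi[p$population == "A"], 1.1)
  expect_equal(p$sd_ccvi[p$population == "A"], sd(c(1, 1.2)))
  expect_true(is.na(p$sd_ccvi[p$population == "B"]))
  expect_error(population_ccvi(1:3, c("A", "B")), "length mismatch")
  const <- population_ccvi(rep(2.5, 4), rep("A", 4))
  expect_equal(const$mean_ccvi, 2.5)
  expect_equal(const$sd_ccvi, 0)

  long <- tidyr::expand_grid(plant_id = c("p1", "p2"),
                             scenario = c("g1 SSP1-RCP2.6", "g1 SSP5-RCP8.5"))
  long$ccvi <- c(1, -1, 2, 4)
  expect_equal(scenario_average(long, "SSP1-RCP2.6")$ccvi,
               long$ccvi[long$scenario == "g1 SSP1-RCP2.6"])
  expect_equal(scenario_average(long, "all")$ccvi, c(0, 3))
  expect_error(scenario_average(long[-1, ], "all"), "missing scenario")
  expect_error(scenario_average(long, "SSP9"), "no scenario matches")
})

test_that("averaging all scenarios equals the mean of the per-pathway means", {
  withr::local_seed(31)
  long <- tidyr::expand_grid(
    plant_id = sprintf("p%02d", 1:6),
    scenario = c(outer(sprintf("gcm%d ", 1:5),
                       c("SSP1-RCP2.6", "SSP5-RCP8.5"), paste0)))
  long$ccvi <- rnorm(nrow(long))
  lo <- scenario_average(long, "SSP1-RCP2.6")
  hi <- scenario_average(long, "SSP5-RCP8.5")
  all <- scenario_average(long, "all")
  expect_equal(all$ccvi, (lo$ccvi + hi$ccvi) / 2)
})

test_that("the index is antitone in suitability and affine-invariant", {
  withr::local_seed(32)
  vals <- runif(30, 200, 900)
  sig <- sd(vals)
  cc <- popvuln:::ccvi_values(vals, 600, sigma = sig)
  # raising any one cell's suitability never raises its index (fixed scaling)
  for (i in c(1, 10, 30)) {
    v2 <- vals; v2[i] <- v2[i] + 50
    cc2 <- popvuln:::ccvi_values(v2, 600, sigma = sig)
    expect_lt(cc2[i], cc[i])
    expect_equal(cc2[-i], cc[-i])
  }
  # consistent positive affine rescaling of values and centre leaves it unchanged
  a <- 3.7; b <- -125
  expect_equal(popvuln:::ccvi_values(a * vals + b, a * 600 + b),
               popvuln:::ccvi_values(vals, 600))
})
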