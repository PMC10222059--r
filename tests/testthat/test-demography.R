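test_that("life-stage classification uses the inclusive 30 cm cutoff", {
  expect_equal(as.character(classify_life_stage(c(30, 30.1, 0.5))),
               c("young", "adult", "young"))
  expect_error(classify_life_stage(c(10, 0)), "positive")
  expect_error(classify_life_stage(-1), "positive")
})

test_that("age estimation is the linear leaf-economy proxy", {
  expect_equal(estimate_age(30), 6)  # 30 cm * 0.6 leaves/cm / 3 leaves/yr
  expect_equal(estimate_age(1e-6), 2e-7)
  expect_equal(estimate_age(c(20, 40)), c(4, 8))  # linearity: doubling doubles
  expect_error(estimate_age(0), "positive")
  expect_error(estimate_age(10, leaves_per_year = 0), "positive")
})

test_that("skewness matches the direct moment formula", {
  expect_equal(skewness(c(1, 2, 3)), 0)
  expect_gt(skewness(c(1, 1, 1, 10)), 0)
  withr::local_seed(40)
  x <- rgamma(20, shape = 2)
  m <- mean(x)
  oracle <- mean((x - m)^3) / mean((x - m)^2)^1.5
  expect_equal(skewness(x), oracle, tolerance = 1e-12)
  n <- length(x)
  expect_equal(skewness(x, "b1"), oracle * sqrt(n * (n - 1)) / (n - 2),
               tolerance = 1e-12)
  expect_error(skewness(c(1, 2)), "at least 3")
  expect_error(skewness(rep(4, 5)), "zero variance")
})

test_that("convex-hull occupancy area matches the shoelace result and units", {
  sq <- data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  a <- occupancy_area(sq)
  expect_equal(a$area_m2, 100)
  expect_equal(a$area_ha, 0.01)
  expect_false(a$degenerate)
  expect_warning(col <- occupancy_area(data.frame(x = 1:5, y = 2 * (1:5) + 1)),
                 "degenerate")
  expect_equal(col$area_ha, 0)
  expect_true(col$degenerate)
  expect_warning(two <- occupancy_area(data.frame(x = 1:2, y = 1:2)), "degenerate")
  expect_equal(two$area_ha, 0)
})

test_that("occupancy area is translation- and rotation-invariant", {
  withr::local_seed(41)
  pts <- data.frame(x = runif(20, 0, 50), y = runif(20, 0, 50))
  a0 <- occupancy_area(pts)$area_m2
  shifted <- data.frame(x = pts$x + 1234, y = pts$y - 987)
  expect_equal(occupancy_area(shifted)$area_m2, a0, tolerance = 1e-9)
  th <- 0.7
  rot <- data.frame(x = cos(th) * pts$x - sin(th) * pts$y,
                    y = sin(th) * pts$x + cos(th) * pts$y)
  expect_equal(occupancy_area(rot)$area_m2, a0, tolerance = 1e-9)
})

test_that("alpha-shape area recovers the hull at alpha = Inf and shrinks below it", {
  withr::local_seed(42)
  pts <- data.frame(x = runif(12, 0, 100), y = runif(12, 0, 100))
  inf_shape <- occupancy_area(pts, alpha = Inf)
  expect_equal(inf_shape$area_m2, hull_area_oracle(pts$x, pts$y), tolerance = 1e-9)
  expect_equal(inf_shape$area_m2, occupancy_area(pts)$area_m2, tolerance = 1e-9)
  # a C-shaped cloud: a small alpha follows the concavity, so area drops
  t <- seq(0.3, 2 * pi - 0.3, length.out = 40)
  cshape <- data.frame(x = 50 + c(30 * cos(t), 20 * cos(rev(t))),
                       y = 50 + c(30 * sin(t), 20 * sin(rev(t))))
  full <- occupancy_area(cshape, alpha = Inf)$area_m2
  tight <- occupancy_area(cshape, alpha = 8)$area_m2
  expect_lt(tight, 0.8 * full)
  expect_gt(tight, 0)
})

test_that("mean plant distance matches a double-loop oracle", {
  two <- mean_plant_distance(data.frame(x = c(0, 7), y = c(0, 0)))
  expect_equal(two$mean, 7)
  expect_true(is.na(two$sd))
  tri <- mean_plant_distance(data.frame(x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2)))
  expect_equal(tri$mean, 1)
  expect_equal(tri$sd, 0)
  withr::local_seed(43)
  pts <- data.frame(x = runif(10), y = runif(10))
  got <- mean_plant_distance(pts)
  ds <- c()
  for (i in 1:9) for (j in (i + 1):10)
    ds <- c(ds, sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2))
  expect_equal(got$mean, mean(ds), tolerance = 1e-12)
  expect_equal(got$sd, sd(ds), tolerance = 1e-12)
  # nearest-neighbour option
  nn <- mean_plant_distance(pts, method = "nn")
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  expect_equal(nn$mean, mean(apply(d, 1, min)), tolerance = 1e-12)
  expect_error(mean_plant_distance(data.frame(x = 1, y = 1)), "at least 2")
})

test_that("population summaries recompute every field consistently", {
  census <- toy_census(seed = 44)
  s <- summarize_population(census)
  expect_equal(nrow(s), 3)
  expect_equal(s$n_young + s$n_adult, s$n_plants)
  one <- census[census$population == "T01", ]
  row <- s[s$population == "T01", ]
  expect_equal(row$mean_stem_cm, mean(one$stem_length_cm))
  expect_equal(row$sd_stem_cm, sd(one$stem_length_cm))
  expect_equal(row$n_fruiting, sum(one$status == "fruiting"))
  expect_equal(row$n_young, sum(one$stem_length_cm <= 30))
  expect_equal(row$skewness, skewness(one$stem_length_cm))
  expect_equal(row$area_ha, occupancy_area(one)$area_ha)
  expect_equal(row$mean_dist_m, mean_plant_distance(one)$mean)
  expect_equal(row$density_total, row$n_plants / row$area_ha)
  expect_equal(row$density_young, row$n_young / row$area_ha)
  # ccvi join
  cc <- tibble::tibble(population = c("T01", "T02", "T03"), mean_ccvi = c(1, 2, 3))
  s2 <- summarize_population(census, ccvi = cc)
  expect_equal(s2$mean_ccvi, c(1, 2, 3))
})

test_that("degenerate censuses get NA sentinels, never infinities", {
  single <- tibble::tibble(plant_id = "a", population = "S", x = 1, y = 1,
                           stem_length_cm = 42, status = "non_reproductive")
  s <- summarize_population(single)
  expect_equal(s$mean_stem_cm, 42)
  expect_true(is.na(s$sd_stem_cm))
  expect_true(is.na(s$density_total))
  expect_true(is.na(s$skewness))
  expect_equal(s$area_ha, 0)
})

test_that("scaled kernel densities peak at 1 and resolve separated modes", {
  d <- size_structure_density(c(20, 20.0001), bandwidth = 2)
  expect_equal(max(d$density), 1)
  expect_lt(abs(d$stem_length_cm[which.max(d$density)] - 20), 2)
  withr::local_seed(45)
  mix <- c(rnorm(400, 20, 3), rnorm(400, 80, 3))
  bw <- 4
  k <- size_structure_density(mix, bandwidth = bw)
  # modes of the bimodal curve within one bandwidth of the true means
  lower <- k[k$stem_length_cm < 50, ]
  upper <- k[k$stem_length_cm >= 50, ]
  expect_lt(abs(lower$stem_length_cm[which.max(lower$density)] - 20), bw)
  expect_lt(abs(upper$stem_length_cm[which.max(upper$density)] - 80), bw)
  expect_error(size_structure_density(5), "at least 2")
})
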