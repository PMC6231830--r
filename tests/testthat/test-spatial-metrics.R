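test_that("nearest-neighbour index matches closed forms", {
  corners <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  r <- nearest_neighbor_index(corners, area = 1)
  expect_equal(r$d_obs, 1)
  expect_equal(r$d_exp, 0.25)
  expect_equal(r$nni, 4)
  expect_identical(r$typology, "regular")

  two <- cbind(c(0, 2), c(0, 0))
  r2 <- nearest_neighbor_index(two, area = 4)
  expect_equal(r2$d_obs, 2)
  expect_equal(r2$d_exp, 0.5 / sqrt(0.5))
  expect_equal(r2$nni, 2 * sqrt(0.5) / 0.5, tolerance = 1e-12)

  expect_error(nearest_neighbor_index(corners[1, , drop = FALSE]),
               "fewer than 2")
  expect_error(nearest_neighbor_index(two, area = 0), "positive")
})

test_that("the index is invariant to a consistent rescaling", {
  set.seed(5)
  pts <- cbind(runif(80, 0, 100), runif(80, 0, 100))
  a <- nearest_neighbor_index(pts, area = 1e4)$nni
  b <- nearest_neighbor_index(pts * 3.7, area = 1e4 * 3.7^2)$nni
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("settlement typology follows the rounded one-decimal bands", {
  expect_identical(classify_settlement(0.4), "highly_clustered")
  expect_identical(classify_settlement(1.0), "random")
  expect_identical(classify_settlement(0.54), "highly_clustered")
  expect_identical(classify_settlement(0.55), "clustered")
  expect_identical(classify_settlement(0.94), "clustered")
  expect_identical(classify_settlement(0.95), "random")
  expect_identical(classify_settlement(1.05), "regular")
  expect_error(classify_settlement(-0.1), "non-negative")
})

test_that("sector waste density applies the qualifying threshold", {
  expect_equal(sector_waste_density(numeric(0), 120), 0)
  expect_equal(sector_waste_density(rep(2, 5), 250), 2)
  expect_equal(sector_waste_density(c(0.8, 1.0, 1.5), 100), 2)
  expect_error(sector_waste_density(1, 0), "undefined")
  # invariant to sub-threshold spots
  set.seed(1)
  big <- runif(10, 1, 3)
  expect_equal(sector_waste_density(big, 400),
               sector_waste_density(c(big, runif(50, 0.1, 0.99)), 400))
})

test_that("nearest-waste distance is exact and site-wide", {
  hh <- data.frame(x = 0, y = 0)
  spots <- data.frame(x = c(3, 6), y = c(4, 8), diameter = c(1.2, 2))
  expect_equal(nearest_waste_distance(hh, spots), 5)
  expect_equal(nearest_waste_distance(data.frame(x = 3, y = 4), spots), 0)
  expect_error(nearest_waste_distance(hh,
    data.frame(x = 1, y = 1, diameter = 0.5)), "qualifying")
})

test_that("grid index equals the brute-force scan", {
  set.seed(11)
  hh <- data.frame(x = runif(400, 0, 2000), y = runif(400, 0, 2000))
  spots <- data.frame(x = runif(150, 0, 2000), y = runif(150, 0, 2000),
                      diameter = runif(150, 0.5, 2))
  expect_equal(nearest_waste_distance(hh, spots),
               brute_force_nearest(hh, spots))
})

test_that("adding spots never increases the nearest distance", {
  set.seed(2)
  hh <- data.frame(x = runif(50, 0, 500), y = runif(50, 0, 500))
  s1 <- data.frame(x = runif(20, 0, 500), y = runif(20, 0, 500),
                   diameter = 1.5)
  s2 <- rbind(s1, data.frame(x = runif(10, 0, 500),
                             y = runif(10, 0, 500), diameter = 1.5))
  expect_true(all(nearest_waste_distance(hh, s2) <=
                    nearest_waste_distance(hh, s1) + 1e-12))
})

test_that("built-up concentration covers tight clusters fully", {
  site <- mini_site()
  r <- builtup_concentration(site)
  expect_equal(r$parcels_in_core_share_pct, 100)
  expect_true(r$core_area_ha < site$total_area_ha)

  # two compact clusters in different villages: summed hulls stay far
  # below the bounding box spanning both
  g <- mini_site(seed = 7)
  hull_area <- builtup_concentration(g)$core_area_ha
  p <- g$parcels
  bbox_ha <- diff(range(p$x)) * diff(range(p$y)) / 1e4
  expect_lt(hull_area, bbox_ha)
})

test_that("road density is length over area with optional typology filter", {
  roads <- data.frame(length_m = c(707.2, 473.9, 82.3) * 1000,
                      typology = c("village_road", "public_lane",
                                   "private_lane"))
  expect_equal(road_density(roads, 251.7), 5.02, tolerance = 0.002)
  expect_equal(road_density(roads[0, ], 10), 0)
  expect_equal(road_density(data.frame(length_m = 1000,
                                       typology = "village_road"), 1), 1)
  expect_equal(road_density(roads, 251.7, typologies = "village_road"),
               707.2 / 251.7, tolerance = 1e-10)
})
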