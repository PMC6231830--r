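test_that("point patterns realise their typology class", {
  frame <- c(0, 100, 0, 100)
  set.seed(1)
  pts <- generate_parcel_centroids("regular", 100, frame,
                                   list(spacing = 10, jitter = 0))
  r <- nearest_neighbor_index(pts, area = 100 * 100)
  expect_equal(r$nni, 2, tolerance = 1e-12)

  # Thomas clustering with tight offspring spread is highly clustered
  km <- c(0, 1000, 0, 1000)
  nnis <- vapply(1:10, function(s) {
    set.seed(s)
    p <- generate_parcel_centroids("clustered", 500, km,
                                   list(n_parents = 5, sigma = 5))
    nearest_neighbor_index(p, area = 1e6)$nni
  }, numeric(1))
  expect_true(all(nnis < 0.5))

  expect_error(generate_parcel_centroids("clustered", 1, frame), "2 points")
  set.seed(2)
  for (pat in c("linear", "circular", "regular")) {
    p <- generate_parcel_centroids(pat, 250, frame)
    expect_identical(nrow(p), 250L)
    expect_true(all(p[, 1] >= 0 & p[, 1] <= 100 &
                      p[, 2] >= 0 & p[, 2] <= 100))
  }
})

test_that("villages partition parcels into bounded sectors", {
  cfg <- synth_config()
  set.seed(30)
  vil <- generate_village(cfg, 1, n_parcels = 300)
  p <- vil$parcels
  expect_identical(nrow(p), 300L)
  expect_true(all(table(p$sector_num) <= cfg$sector_tiling$core_max))
  expect_identical(anyDuplicated(p$uid), 0L)
  # every parcel in exactly one sector, sector codes alphabetic
  expect_true(all(p$sector_num %in% vil$sectors$sector_num))
  expect_true(all(grepl("^[A-Z]+$", vil$sectors$sector_code)))
})

test_that("use-class mix reproduces the configured shares", {
  cfg <- synth_config(sector_tiling = list(core_target = 200L,
                                           core_max = 500L,
                                           outer_max = 50L))
  set.seed(77)
  vil <- generate_village(cfg, 1, n_parcels = 10000)
  share <- mean(vil$parcels$use_class == "residential") * 100
  expect_lt(abs(share - 56.08), 2)
})

test_that("site generation is deterministic under a fixed seed", {
  a <- mini_site(seed = 5)
  b <- mini_site(seed = 5)
  expect_identical(a$parcels, b$parcels)
  expect_identical(a$households, b$households)
  expect_identical(a$waste_spots, b$waste_spots)
  c_ <- mini_site(seed = 6)
  expect_false(identical(a$parcels$x, c_$parcels$x))
})

test_that("infinite segregation concentration collapses to site shares", {
  cfg <- mini_config(caste_segregation = Inf)
  set.seed(8)
  vil <- generate_village(cfg, 1, n_parcels = 200)
  vil <- assign_households(vil, cfg)
  for (s in seq_len(nrow(vil$caste_profiles)))
    expect_equal(unname(vil$caste_profiles[s, ]),
                 unname(cfg$caste_site_shares))
})

test_that("low concentration produces widespread sector dominance", {
  for (s in 1:3) {
    site <- generate_site(mini_config(caste_segregation = 0.5), seed = s,
                          individuals = FALSE)
    d <- dominance_summary(dominance_labels(site))
    expect_gte(d$caste_dominant_pct, 50)
  }
})

test_that("a null caste-SES link yields independence", {
  cfg <- mini_config(
    ses_given_caste = list(shift = c(General = 0, OBC = 0, SCST = 0),
                           cutpoints = c(-0.3, 1.2)),
    ses_sector_sd = 0)
  site <- generate_site(cfg, seed = 12, individuals = FALSE)
  hh <- site$households
  p <- suppressWarnings(chisq.test(table(hh$caste, hh$ses)))$p.value
  expect_gt(p, 0.01)
})

test_that("waste placement responds to sector composition as configured", {
  # null coefficients: density unrelated to SC/ST share
  cfg0 <- mini_config(waste_model = list(gamma0 = log(15), gamma1 = 0,
                                         gamma2 = 0, diameter_meanlog = 0.3146,
                                         diameter_sdlog = 0.6, p_solid = 0.14))
  site0 <- generate_site(cfg0, seed = 21, individuals = FALSE)
  sec <- site0$sectors
  hh <- site0$households
  scst <- tapply(hh$caste == "SCST", paste(hh$village_code, hh$sector_num),
                 mean)
  w <- site0$waste_spots
  cnt <- table(factor(paste(w$village_code, w$sector_num),
                      levels = paste(sec$village_code, sec$sector_num)))
  rate <- as.numeric(cnt) / sec$area_ha
  share <- as.numeric(scst[paste(sec$village_code, sec$sector_num)])
  fit <- summary(lm(rate ~ share))
  expect_gt(coef(fit)[2, 4], 0.01)

  # positive SC/ST coefficient: SC/ST-dominant sectors denser than
  # General-dominant ones
  site1 <- generate_site(mini_config(), seed = 22, individuals = FALSE)
  cmp <- compare_by_dominance(site1, "waste_density", "caste")
  expect_gt(cmp$medians[["SCST"]], 0)

  # zero intensity: no spots at all
  cfgz <- mini_config(waste_model = list(gamma0 = -Inf, gamma1 = 0.6,
                                         gamma2 = 0.9, diameter_meanlog = 0.3,
                                         diameter_sdlog = 0.6, p_solid = 0.14))
  sitez <- generate_site(cfgz, seed = 23, individuals = FALSE)
  expect_identical(nrow(sitez$waste_spots), 0L)
})

test_that("the manifest records the exact structural parameters", {
  site <- mini_site(seed = 31)
  cfg <- mini_config()
  expect_equal(site$manifest$waste_model$gamma1, cfg$waste_model$gamma1)
  expect_equal(site$manifest$waste_model$gamma2, cfg$waste_model$gamma2)
  expect_equal(site$manifest$caste_segregation, cfg$caste_segregation)
  expect_identical(site$manifest$seed, 31)
})

test_that("an all-clustered mix is classified clustered downstream", {
  cfg <- mini_config(pattern_mix = c(clustered = 1, linear = 0,
                                     circular = 0, regular = 0),
                     n_villages = 8)
  site <- generate_site(cfg, seed = 14, individuals = FALSE)
  typ <- vapply(unique(site$parcels$village_code), function(vc) {
    p <- site$parcels[site$parcels$village_code == vc, ]
    nearest_neighbor_index(cbind(p$x, p$y))$typology
  }, character(1))
  expect_gte(mean(typ %in% c("highly_clustered", "clustered")), 0.9)
})
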