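spec_sim <- path_model_spec(outcome = "log_nearest_waste",
                            exposure = "scst",
                            mediators = "waste_density",
                            covariates = "toilet")

test_that("path coefficients recover the structural truth", {
  set.seed(50)
  d <- simulate_path_data(n_sectors = 400, hh_per_sector = 15,
                          a = 0.5, b = -0.4, c_direct = -0.1)
  fit <- fit_path_model(d, spec_sim)
  # tolerances are ~4 cluster-level standard errors of each path
  expect_lt(abs(fit$a["waste_density", "scst"] - 0.5), 0.2)
  expect_lt(abs(fit$b[["waste_density"]] - (-0.4)), 0.1)
  expect_lt(abs(fit$indirect["waste_density", "scst"] - (-0.2)), 0.1)
})

test_that("total = direct + indirect exactly for linear paths", {
  set.seed(51)
  d <- simulate_path_data(n_sectors = 60)
  fit <- fit_path_model(d, spec_sim)
  expect_equal(fit$total[["scst"]],
               fit$direct[["scst"]] + sum(fit$indirect[, "scst"]),
               tolerance = 1e-8)
  # and on a full synthetic-site dataset with a factor exposure
  site <- generate_site(mini_config(n_villages = 6), seed = 52,
                        individuals = FALSE)
  ds <- exposure_dataset(site)
  sp <- path_model_spec(outcome = "log_nearest_waste", exposure = "caste",
                        mediators = "waste_density",
                        covariates = c("toilet", "water_source"))
  f2 <- fit_path_model(ds, sp)
  for (term in colnames(f2$indirect))
    expect_equal(f2$total[[term]],
                 f2$direct[[term]] + sum(f2$indirect[, term]),
                 tolerance = 1e-8)
})

test_that("a permuted outcome kills the outcome-model paths", {
  set.seed(53)
  hits <- 0L; trials <- 0L
  for (s in 1:10) {
    d <- simulate_path_data(n_sectors = 150, hh_per_sector = 10)
    d$log_nearest_waste <- sample(d$log_nearest_waste)
    fit <- fit_path_model(d, spec_sim)
    z_b <- abs(fit$b[["waste_density"]] / fit$b_se[["waste_density"]])
    z_d <- abs(fit$direct[["scst"]] / fit$direct_se[["scst"]])
    hits <- hits + sum(c(z_b, z_d) > 1.96)
    trials <- trials + 2L
  }
  expect_lte(hits / trials, 0.2)
})

test_that("degenerate designs raise informative singularity errors", {
  set.seed(54)
  d <- simulate_path_data(n_sectors = 40)
  d$waste_density <- 1          # zero-variance mediator
  expect_error(fit_path_model(d, spec_sim), "zero-variance")
  d2 <- simulate_path_data(n_sectors = 40)
  d2$toilet <- d2$scst          # collinear covariate
  expect_error(fit_path_model(d2, spec_sim), "collinear")
})

test_that("bootstrap intervals are seed-stable and centred sensibly", {
  set.seed(55)
  d <- simulate_path_data(n_sectors = 120, hh_per_sector = 10)
  r1 <- indirect_effect_bootstrap(d, spec_sim, B = 200, seed = 7)
  r2 <- indirect_effect_bootstrap(d, spec_sim, B = 200, seed = 7)
  expect_identical(r1$ci_indirect, r2$ci_indirect)
  expect_lt(r1$ci_indirect["waste_density", "scst", "lower"],
            r1$estimates$indirect["waste_density", "scst"])
  expect_gt(r1$ci_indirect["waste_density", "scst", "upper"],
            r1$estimates$indirect["waste_density", "scst"])
  expect_warning(indirect_effect_bootstrap(d, spec_sim, B = 50, seed = 1),
                 "B < 100")
})

test_that("a null exposure-mediator path gives intervals covering zero", {
  set.seed(56)
  d <- simulate_path_data(n_sectors = 200, hh_per_sector = 10, a = 0)
  r <- indirect_effect_bootstrap(d, spec_sim, B = 300, seed = 11)
  expect_lte(r$ci_indirect["waste_density", "scst", "lower"], 0)
  expect_gte(r$ci_indirect["waste_density", "scst", "upper"], 0)
})

test_that("binary sector mediators run through the logistic path", {
  site <- generate_site(mini_config(n_villages = 6), seed = 57,
                        individuals = FALSE)
  ds <- exposure_dataset(site)
  sp <- path_model_spec(outcome = "log_nearest_waste", exposure = "caste",
                        mediators = c("waste_density", "dom_ses_poor"),
                        covariates = "toilet")
  fit <- fit_path_model(ds, sp)
  expect_identical(rownames(fit$a), c("waste_density", "dom_ses_poor"))
  expect_true(all(is.finite(fit$b)))
  r <- indirect_effect_bootstrap(ds, sp, B = 120, seed = 3)
  expect_true(r$B_used <= 120 && r$B_used > 100)
})

test_that("the full generator yields a negative indirect caste effect", {
  # strong SC/ST waste loading: households in SC/ST-heavy sectors sit
  # closer to waste, so the density-mediated indirect effect on distance
  # is negative
  cfg <- mini_config(n_villages = 8,
    waste_model = list(gamma0 = log(15), gamma1 = 0.6, gamma2 = 3,
                       diameter_meanlog = 0.3146, diameter_sdlog = 0.6,
                       p_solid = 0.14))
  site <- generate_site(cfg, seed = 58, individuals = FALSE)
  ds <- exposure_dataset(site)
  sp <- path_model_spec(outcome = "log_nearest_waste", exposure = "caste",
                        mediators = "waste_density",
                        covariates = c("toilet", "water_source"))
  fit <- fit_path_model(ds, sp)
  expect_lt(fit$indirect["waste_density", "casteSCST"], 0)
})
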