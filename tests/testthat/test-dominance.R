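test_that("site prevalence is household-weighted and normalised", {
  hh <- data.frame(caste = rep(c("General", "OBC", "SCST"), c(60, 30, 10)))
  expect_equal(unname(site_prevalence(hh, "caste")), c(0.6, 0.3, 0.1))
  hh1 <- data.frame(ses = rep("poor", 5))
  expect_equal(unname(site_prevalence(hh1, "ses")), c(0, 0, 1))
  expect_error(site_prevalence(hh[0, , drop = FALSE], "caste"),
               "no households")
  set.seed(4)
  for (i in 1:20) {
    h <- data.frame(caste = sample(c("General", "OBC", "SCST"),
                                   sample(5:200, 1), TRUE))
    expect_equal(sum(site_prevalence(h, "caste")), 1)
  }
})

test_that("the 1.5x rule has an inclusive boundary and max-ratio winner", {
  prev <- c(General = 0.5, OBC = 0.3, SCST = 0.2)
  sec <- data.frame(caste = rep(c("General", "OBC", "SCST"),
                                c(40, 30, 30)))   # SCST 30% = 1.5 x 20%
  lab <- classify_sector_dominance(sec, prev, "caste")
  expect_identical(lab$dominant_class, "SCST")
  expect_equal(unname(lab$ratio["SCST"]), 1.5)

  same <- data.frame(caste = rep(c("General", "OBC", "SCST"),
                                 c(50, 30, 20)))
  expect_identical(classify_sector_dominance(same, prev,
                                             "caste")$dominant_class, "none")

  empty <- classify_sector_dominance(same[0, , drop = FALSE], prev, "caste")
  expect_true(empty$excluded)
  expect_true(is.na(empty$dominant_class))
})

test_that("uniform composition yields no dominance at any threshold > 1", {
  prev <- c(General = 0.5, OBC = 0.3, SCST = 0.2)
  sec <- data.frame(caste = rep(c("General", "OBC", "SCST"), c(50, 30, 20)))
  for (th in c(1.01, 1.2, 1.5, 3))
    expect_identical(
      classify_sector_dominance(sec, prev, "caste", th)$dominant_class,
      "none")
})

test_that("raising the threshold never adds dominant sectors", {
  site <- mini_site(seed = 17)
  counts <- vapply(c(1.2, 1.5, 1.8, 2.5), function(th) {
    d <- dominance_summary(dominance_labels(site, th))
    d$caste_dominant_n + d$ses_dominant_n
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("every dominant sector's ratio meets the threshold", {
  site <- mini_site(seed = 19)
  lab <- dominance_labels(site, 1.5)
  dom <- lab[lab$inhabited & lab$dominant_caste != "none", ]
  expect_true(all(dom$caste_ratio >= 1.5))
  doms <- lab[lab$inhabited & lab$dominant_ses != "none", ]
  expect_true(all(doms$ses_ratio >= 1.5))
})

test_that("dominance frequency matches an independent composition oracle", {
  # Oracle: simulate the sector composition model alone (Dirichlet profile,
  # multinomial households at the average sector size), no geometry.
  cfg <- mini_config()
  site <- generate_site(cfg, seed = 23, individuals = FALSE)
  lab <- dominance_labels(site)
  obs <- dominance_summary(lab)$caste_dominant_pct

  hh <- site$households
  prev <- site_prevalence(hh, "caste")
  sizes <- as.numeric(table(paste(hh$village_code, hh$sector_num)))
  set.seed(99)
  oracle <- mean(vapply(1:20000, function(i) {
    g <- rgamma(3, cfg$caste_segregation * cfg$caste_site_shares)
    prof <- g / sum(g)
    n <- sample(sizes, 1)
    counts <- as.numeric(rmultinom(1, n, prof))
    any(counts / n >= 1.5 * prev)
  }, logical(1))) * 100
  expect_lt(abs(obs - oracle), 7)
})

test_that("summary percentages use half-up one-decimal reporting", {
  lab <- data.frame(village_code = 1, sector_num = 1:8,
                    sector_code = "A", inhabited = c(rep(TRUE, 6), FALSE,
                                                     FALSE),
                    dominant_caste = c("SCST", "SCST", "none", "General",
                                       "none", "none", NA, NA),
                    caste_ratio = NA, ses_ratio = NA,
                    dominant_ses = c("poor", rep("none", 5), NA, NA))
  d <- dominance_summary(lab)
  expect_identical(d$n_inhabited, 6L)
  expect_equal(d$caste_dominant_pct, ratio_report(3, 6, 1))
  expect_equal(d$ses_dominant_pct, ratio_report(1, 6, 1))
  lab$dominant_caste[lab$inhabited] <- "none"
  lab$dominant_ses[lab$inhabited] <- "none"
  d0 <- dominance_summary(lab)
  expect_equal(d0$caste_dominant_pct, 0)
})
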