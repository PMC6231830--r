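pilot_villages <- function() {
  data.frame(village_code = 1:10,
             size_class = rep(c("large", "small"), each = 5),
             pattern = c("linear", "linear", "circular", "circular",
                         "clustered", "linear", "circular", "circular",
                         "clustered", "regular"))
}

test_that("pilot selection draws the 2-2-1-1 stratified pattern", {
  v <- pilot_villages()
  set.seed(61)
  sel <- select_pilot_villages(v)
  expect_identical(nrow(sel), 6L)
  tab <- table(sel$size_class, sel$pattern)
  expect_identical(unname(tab["large", "linear"]), 2L)
  expect_identical(unname(tab["large", "circular"]), 2L)
  expect_identical(unname(tab["small", "linear"]), 1L)
  expect_identical(unname(tab["small", "circular"]), 1L)
  set.seed(61)
  expect_identical(select_pilot_villages(v), sel)

  v2 <- v[v$pattern != "linear" | v$size_class != "large", ]
  expect_error(select_pilot_villages(v2), "large-linear")
})

test_that("audit sample sizes follow the rate/minimum/cap rule", {
  plan <- sampling_plan()
  expect_identical(audit_sample_size(400, plan), 30L)
  expect_identical(audit_sample_size(3000, plan), 153L)
  expect_identical(audit_sample_size(20, plan), 20L)
  n <- 1:10000
  s <- audit_sample_size(n, plan)
  expect_true(all(s <= n))
  expect_true(all(s >= pmin(n, 30)))
  expect_true(all(s >= ceiling(0.051 * n) | s == n))
})

test_that("parcel audit samples are stratified and reproducible", {
  set.seed(62)
  parcels <- data.frame(uid = sprintf("p%04d", 1:400),
                        use_class = rep(c("residential", "nonresidential",
                                          "mixed"), c(240, 140, 20)))
  set.seed(63)
  s <- sample_parcels_for_audit(parcels)
  expect_identical(nrow(s), 30L)
  expect_identical(anyDuplicated(s$uid), 0L)
  tab <- table(s$use_class)
  expect_equal(unname(tab[["residential"]]), 18, tolerance = 1)
  set.seed(63)
  expect_identical(sample_parcels_for_audit(parcels), s)
})

test_that("field checks sample ceiling(fraction) per stratum", {
  parcels <- data.frame(uid = 1:100,
                        use_class = rep(c("a", "b"), c(95, 5)))
  set.seed(64)
  one <- field_check_sample(parcels, strata = rep("all", 100))
  expect_identical(nrow(one), 10L)
  set.seed(64)
  two <- field_check_sample(parcels)
  expect_identical(nrow(two), 11L)   # 10 + 1
  expect_identical(nrow(field_check_sample(parcels, fraction = 1)), 100L)
})

test_that("LQAS decisions follow the defect threshold", {
  plan <- lqas_plan(sample_n = 30, decision_d = 2)
  expect_identical(lqas_decision(3, plan), "reject")
  expect_identical(lqas_decision(2, plan), "accept")
  expect_error(lqas_decision(31, plan), "exceed")
  expect_error(lqas_plan(sample_n = 10, decision_d = 10), "smaller")
})

test_that("derived LQAS plans respect both binomial risk bounds", {
  plan <- lqas_plan(aql = 0.05, rql = 0.20, alpha = 0.10, beta = 0.10)
  expect_gte(lqas_oc(plan, 0.05), 0.90)   # producer protected
  expect_lte(lqas_oc(plan, 0.20), 0.10)   # consumer protected
  # minimality: no smaller n admits a conforming d
  n <- plan$sample_n
  smaller_ok <- any(vapply(0:(n - 2), function(d)
    pbinom(d, n - 1, 0.05) >= 0.90 && pbinom(d, n - 1, 0.20) <= 0.10,
    logical(1)))
  expect_false(smaller_ok)
  expect_error(lqas_plan(aql = 0.3, rql = 0.2), "infeasible")
})

test_that("error-rate reporting reproduces printed-style percentages", {
  n <- 47007L
  audits <- data.frame(
    size_error = rep(c(TRUE, FALSE), c(141, n - 141)),
    shape_error = rep(c(FALSE, TRUE, FALSE), c(141, 47, n - 188)),
    location_error = rep(c(FALSE, TRUE, FALSE), c(188, 2115, n - 2303)),
    attribute_error = FALSE,
    vacant_missing = FALSE,
    temporal_change = rep(c("new_construction", "other", "none"),
                          c(4640, 1047, n - 5687)))
  r <- error_rate_report(audits, n)
  expect_equal(r$any_positional_pct, 4.90)
  expect_equal(r$new_construction_pct, 81.6)
  expect_equal(unname(r$pct[["size_error"]]), ratio_report(141, n, 2))

  zero <- error_rate_report(data.frame(size_error = rep(FALSE, 10),
                                       shape_error = FALSE,
                                       location_error = FALSE,
                                       attribute_error = FALSE), 10)
  expect_true(all(zero$pct == 0))
  expect_error(error_rate_report(data.frame(size_error = rep(TRUE, 10)), 5),
               "denominator")
})
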