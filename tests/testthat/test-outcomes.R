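# ICER algebra, classification, life-days and impact scaling.

test_that("the ICER is the cost difference over the QALY difference", {
  pop <- fake_result(qaly = 10.01, ly = 10.02, payer = 1207, societal = 2207)
  fh <- fake_result(qaly = 10.00, ly = 10.00, payer = 1000, societal = 2212)
  r <- compute_icer(pop, fh, "payer")
  expect_equal(r$delta_cost, 207, tolerance = 1e-9)
  expect_equal(r$icer, 207 / 0.01, tolerance = 1e-6)
  # societal: cheaper and better -> cost-saving with a negative ICER
  s <- compute_icer(pop, fh, "societal")
  expect_lt(s$icer, 0)
  expect_identical(s$classification, "cost-saving")
})

test_that("ICERs are antisymmetric under arm exchange", {
  uk <- country_fixture("UK")
  ev <- evaluate_strategies(uk)
  fwd <- compute_icer(ev$pop, ev$fh, "payer", uk$profile)
  rev <- compute_icer(ev$fh, ev$pop, "payer", uk$profile)
  expect_equal(fwd$delta_cost, -rev$delta_cost, tolerance = 1e-12)
  expect_equal(fwd$delta_effect, -rev$delta_effect, tolerance = 1e-12)
})

test_that("degenerate and inconsistent comparisons are handled", {
  a <- fake_result(10, 10, 1100, 2100)
  b <- fake_result(10, 10, 1000, 2000)
  r <- compute_icer(a, b, "payer")
  expect_true(is.na(r$icer))
  expect_identical(r$classification, "dominated")
  mixed <- fake_result(10, 10, 1000, 2000, rates = list(cost = 0, effect = 0))
  expect_error(compute_icer(a, mixed, "payer"), "different discount rates")
})

test_that("classification thresholds are inclusive and ordered", {
  prof <- country_fixture("UK")$profile
  mk <- function(icer) {
    pop <- fake_result(qaly = 2, ly = 2, payer = icer + 100,
                       societal = icer + 100)
    fh <- fake_result(qaly = 1, ly = 1, payer = 100, societal = 100)
    compute_icer(pop, fh, "payer", prof)$classification
  }
  expect_identical(mk(prof$wtp_1gdp), "highly-cost-effective")  # at 1xGDP
  expect_identical(mk(prof$wtp_1gdp + 1), "cost-effective")
  expect_identical(mk(prof$wtp_3gdp), "cost-effective")         # at 3xGDP
  expect_identical(mk(prof$wtp_3gdp + 1), "not-cost-effective")
})

test_that("life-days gained converts discounted life-years at 365.25", {
  a <- fake_result(1, 10.01, 0, 0)
  b <- fake_result(1, 10.00, 0, 0)
  expect_equal(life_days_gained(a, b), 3.6525, tolerance = 1e-9)
  expect_identical(life_days_gained(b, b), 0)
})

test_that("impact scaling reproduces the published national rows", {
  # UK breast-cancer row
  uk <- scale_impact(112014, 114666, 21760299)
  expect_identical(uk$difference_per_million, -2652)
  expect_identical(uk$actual, -57708)
  # China breast-cancer row
  cn <- scale_impact(27062, 29546, 422831894)
  expect_identical(cn$difference_per_million, -2484)
  expect_identical(cn$actual, -1050314)
  expect_identical(scale_impact(5, 5, 1e6)$actual, 0)
  expect_error(scale_impact(1, 2, -5), "population")
})

test_that("impact scaling is linear in population and difference", {
  base <- scale_impact(1000, 600, 10e6)
  expect_identical(scale_impact(1000, 600, 20e6)$actual, 2 * base$actual)
  expect_identical(scale_impact(1400, 600, 10e6)$actual, 2 * base$actual)
  # rounding is half away from zero, within 1 of the exact product
  r <- scale_impact(0, 3, 500001)
  expect_lte(abs(r$actual - (-3 * 0.500001)), 1)
  expect_identical(r$actual, -2)   # -1.500003 rounds away from zero
})
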