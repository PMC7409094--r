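# Discounting, accrual and the human-capital productivity-loss model.

test_that("discount factors follow (1+r)^-t", {
  expect_identical(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(0.03, 1), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(0.035, 2), 1 / 1.035^2, tolerance = 1e-12)
  expect_equal(discount_factor(0.035, 2), 0.933511, tolerance = 1e-6)
  expect_error(discount_factor(0.03, -1), "cycle")
  expect_error(discount_factor(-0.01, 1), "rate")
})

test_that("accrual over a permanently healthy cohort equals the geometric sum", {
  p <- null_hazard_params(cycles = 30L)
  arm <- make_population_arm(p)
  ct <- run_cohort(arm, p)

  r0 <- accrue(ct, arm, p, rates = list(cost = 0, effect = 0))
  expect_equal(r0$ly, 30, tolerance = 1e-9)
  expect_equal(r0$qaly, 30, tolerance = 1e-9)

  r3 <- accrue(ct, arm, p, rates = list(cost = 0.03, effect = 0.03))
  expect_equal(r3$ly, sum(1.03^-(0:29)), tolerance = 1e-9)
  expect_equal(r3$qaly, r3$ly, tolerance = 1e-9)
  # discounted totals shrink as the rate grows
  r5 <- accrue(ct, arm, p, rates = list(cost = 0.05, effect = 0.05))
  expect_true(r0$ly > r3$ly && r3$ly > r5$ly)
})

test_that("a cohort dead at entry accrues nothing", {
  uk <- country_fixture("UK")
  arm <- make_population_arm(uk)
  arm$init[] <- 0
  arm$init["death_other"] <- 1
  res <- accrue(run_cohort(arm, uk), arm, uk,
                rates = list(cost = 0.03, effect = 0.03))
  expect_identical(res$ly, 0)
  expect_identical(res$qaly, 0)
})

test_that("productivity losses have the stated closed forms", {
  uk <- country_fixture("UK")
  prof <- uk$profile
  prof$retirement_age <- 60
  prof$labour_participation <- 0.5
  flat <- prof
  flat$wage_schedule <- data.frame(age = 16:110, wage = 30000)
  # death at 55, retirement 60, flat wage, r = 0: five years of earnings
  expect_equal(productivity_loss("death", 55, "bc", flat, uk$productivity, 0),
               5 * 30000 * 0.5, tolerance = 1e-9)
  # no loss at or past retirement; none with zero participation
  expect_identical(productivity_loss("death", 60, "bc", flat,
                                     uk$productivity, 0.03), 0)
  zerop <- flat
  zerop$labour_participation <- 0
  expect_identical(productivity_loss("death", 45, "bc", zerop,
                                     uk$productivity, 0.03), 0)
  # diagnosis adds temporary absence on top of the permanent-reduction stream
  pp <- uk$productivity
  eff <- pp$departure_fraction + (1 - pp$departure_fraction) * pp$hours_reduction
  expected <- 30000 * 0.5 * pp$absence_days / pp$workdays_per_year +
    5 * 30000 * 0.5 * eff
  expect_equal(productivity_loss("diagnosis", 55, "bc", flat,
                                 uk$productivity, 0),
               expected, tolerance = 1e-9)
})

test_that("societal cost equals payer cost plus productivity loss, and QALY <= LY", {
  for (country in c("UK", "China")) {
    p <- country_fixture(country)
    ev <- evaluate_strategies(p)
    for (res in list(ev$pop, ev$fh)) {
      expect_equal(res$cost_societal - res$cost_payer, res$productivity_loss,
                   tolerance = 1e-9)
      expect_gte(res$productivity_loss, 0)
      expect_lte(res$qaly, res$ly)
      expect_true(all(res$per_million >= 0))
    }
  }
})

test_that("higher labour participation increases societal incremental savings", {
  ind <- country_fixture("India")
  inc_societal <- function(q) {
    ind$profile$labour_participation <- q
    ev <- evaluate_strategies(ind)
    ev$icer_societal$delta_cost
  }
  dc <- vapply(c(0.2745, 0.40, 0.5677), inc_societal, numeric(1))
  # prevention averts productivity losses, so the incremental societal cost
  # falls monotonically as participation rises toward the UK level
  expect_true(all(diff(dc) < 0))
})
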