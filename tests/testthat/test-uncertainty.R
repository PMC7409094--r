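# Scenarios, one-way analysis, PSA, CEAC and the test-cost threshold.

test_that("scenario overrides move cases and deaths in the expected directions", {
  uk <- country_fixture("UK")
  base <- evaluate_strategies(uk)
  run <- function(nm) run_scenario(scenario_catalog()[[nm]], uk)

  # removing RRSO's breast-cancer protection cannot reduce breast cancers
  expect_gte(run("no_rrso_bc_benefit")$pop$per_million[["bc_cases"]],
             base$pop$per_million[["bc_cases"]])
  # no HRT leaves more RRSO women exposed to excess fatal heart disease
  expect_gte(run("no_hrt")$pop$per_million[["chd_deaths"]],
             base$pop$per_million[["chd_deaths"]])
  # halving surgical uptake raises the corresponding cancer burden
  expect_gte(run("half_rrso")$pop$per_million[["oc_cases"]],
             base$pop$per_million[["oc_cases"]])
  expect_gte(run("half_rrm")$pop$per_million[["bc_cases"]],
             base$pop$per_million[["bc_cases"]])
  # a cheaper test strictly lowers the payer ICER
  expect_lt(run("test_cost_100")$icer_payer$icer, base$icer_payer$icer)
  # overrides outside support are rejected
  expect_error(run_scenario(list(overrides = list(p2 = 1.5)), uk),
               "out of \\[0, 1\\]")
  expect_error(run_scenario(list(overrides = list(zzz = 1)), uk),
               "unknown parameter")
})

test_that("one-way analysis is deterministic and utilities do not move counts", {
  uk <- country_fixture("UK")
  ow <- one_way("p2", 0.47, 0.47, uk, "payer")
  expect_identical(ow$icer_low, ow$icer_high)
  expect_identical(ow$spread, 0)

  low_u <- run_scenario(list(overrides = list(u_bc_early = 0.639)), uk)
  base <- evaluate_strategies(uk)
  expect_identical(low_u$pop$per_million, base$pop$per_million)
  expect_false(identical(low_u$icer_payer$icer, base$icer_payer$icer))
})

test_that("the testing cost dominates the tornado", {
  uk <- country_fixture("UK")
  tor <- tornado(uk, "payer")
  expect_identical(tor$param[1], "brca_test")
  expect_true(all(tor$spread >= 0))
})

test_that("the PSA is seed-reproducible and degenerates to the point estimate", {
  uk <- country_fixture("UK")
  s1 <- run_psa(25, seed = 42, params = uk)
  s2 <- run_psa(25, seed = 42, params = uk)
  expect_identical(s1, s2)
  s3 <- run_psa(25, seed = 43, params = uk)
  expect_false(identical(s1$icer_payer, s3$icer_payer))

  cat0 <- brcacea:::psa_catalog(uk)
  for (nm in names(cat0)) cat0[[nm]]$sd <- 0
  det <- evaluate_strategies(uk)
  s0 <- run_psa(3, seed = 1, params = uk, catalog = cat0)
  expect_true(all(s0$icer_payer == det$icer_payer$icer))
  expect_true(all(s0$icer_societal == det$icer_societal$icer))
})

test_that("PSA mean ICERs are internally consistent across run sizes", {
  uk <- country_fixture("UK")
  small <- run_psa(40, seed = 7, params = uk)
  large <- run_psa(160, seed = 8, params = uk)
  se <- stats::sd(large$icer_payer) / sqrt(nrow(small))
  expect_lt(abs(mean(small$icer_payer) - mean(large$icer_payer)), 3 * se)
})

test_that("CEACs follow the net-benefit rule and are monotone", {
  uk <- country_fixture("UK")
  s <- run_psa(40, seed = 5, params = uk)
  grid <- seq(0, 150000, by = 10000)
  curve <- ceac(s, grid, "payer")
  p <- curve$proportion_cost_effective
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(s$delta_qaly > 0))       # fixture draws all gain QALYs
  expect_true(all(diff(p) >= 0))           # hence monotone in WTP
  expect_equal(p[1], mean(s$delta_cost_payer <= 0), tolerance = 1e-12)
  expect_equal(p[length(p)],
               mean(150000 * s$delta_qaly >= s$delta_cost_payer),
               tolerance = 1e-12)
  expect_error(ceac(s, numeric(0)), "empty WTP grid")
  expect_error(ceac(s[0, ], grid), "no PSA samples")
})

test_that("the threshold search inverts the ICER at the willingness-to-pay", {
  uk <- country_fixture("UK")
  th <- threshold_test_cost(uk$profile$wtp_1gdp, uk, "payer")
  expect_lte(abs(th$icer - uk$profile$wtp_1gdp), 1)
  expect_gt(th$test_cost, 0)
  # the ICER is increasing in the test cost, so the maximum affordable test
  # price exceeds $200 exactly when the $200 base case is under the threshold
  base <- evaluate_strategies(uk)$icer_payer$icer
  if (base < uk$profile$wtp_1gdp) expect_gt(th$test_cost, 200)
  nev <- threshold_test_cost(-1e9, uk, "payer")
  expect_true(is.na(nev$test_cost))
  expect_identical(nev$message, "never cost-effective")
})
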