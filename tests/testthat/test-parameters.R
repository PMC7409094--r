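# Parameter containers, defaults, validation and distribution fitting.

test_that("published probability defaults are frozen", {
  pt <- probability_table()
  expected <- c(p1 = 0.0067, p2 = 0.47, p3 = 0.96, p4 = 0.0098, p5 = 0.1,
                p6 = 0.0058, p7 = 0.91, p8 = 0.55, p9 = 0.49, p10 = 0.95,
                p11 = 0.0072, p12 = 0.0303, p13 = 0.8, p14 = 0.71,
                p15 = 0.163, test_uptake = 0.70, vus_prevalence = 0.02)
  for (nm in names(expected)) {
    expect_identical(prob(pt, nm), unname(expected[nm]))
  }
  ut <- utility_table()
  expect_identical(ut$bc, c(0.71, 0.65, 0.45, 0.16))
  expect_identical(ut$oc, c(0.81, 0.55, 0.61, 0.16))
  expect_identical(c(ut$rrm, ut$rrm_sd, ut$rrso, ut$rrso_sd),
                   c(0.88, 0.22, 0.95, 0.10))
  expect_identical(cost_schedule()$brca_test, 200)
})

test_that("probability table validates support, intervals and names", {
  expect_error(probability_table(p2 = 1.2), "out of \\[0, 1\\]")
  expect_error(probability_table(p9 = -0.1), "hazard ratios")
  expect_error(probability_table(nonsense = 0.5), "unknown probability")
  # point outside the stored interval is rejected
  expect_error(probability_table(p2 = 0.9), "bracket")
  # overriding through the setter widens the interval instead
  uk <- country_fixture("UK")
  p <- set_model_param(uk, "p9", 1)
  expect_identical(prob(p$probs, "p9"), 1)
})

test_that("country profiles load with published constants and validate", {
  uk <- load_country_profile("UK")
  expect_identical(uk$cycles, 53L)
  expect_identical(uk$labour_participation, 0.5677)
  expect_identical(uk$female_population_over_30, 21760299)
  expect_identical(uk$discount_cost_rate, 0.035)
  ind <- load_country_profile("India")
  expect_identical(ind$cycles, 38L)
  expect_identical(ind$retirement_age, 60)
  nl <- load_country_profile("Netherlands")
  expect_identical(c(nl$discount_cost_rate, nl$discount_effect_rate),
                   c(0.04, 0.015))
  cyc <- vapply(all_countries(),
                function(x) load_country_profile(x)$cycles, integer(1))
  expect_identical(unname(cyc), c(53L, 52L, 53L, 48L, 49L, 38L))

  expect_error(load_country_profile("Atlantis"), "unknown country")
  bad <- unclass(uk)
  bad$cycles <- 0L
  expect_error(load_country_profile(bad), "cycles must be >= 1")
  bad$cycles <- NULL
  expect_error(load_country_profile(bad), "missing field")
})

test_that("distribution fitting matches requested moments", {
  d <- fit_uncertainty_distribution(0.47, "beta", low = 0.34, high = 0.56)
  expect_equal(d$sd, (0.56 - 0.34) / (2 * 1.96))
  expect_equal(d$sd, 0.0561, tolerance = 1e-3)
  m <- d$shape1 / (d$shape1 + d$shape2)
  v <- d$shape1 * d$shape2 /
    ((d$shape1 + d$shape2)^2 * (d$shape1 + d$shape2 + 1))
  expect_equal(m, 0.47, tolerance = 1e-9)
  expect_equal(sqrt(v), d$sd, tolerance = 1e-9)

  g <- fit_uncertainty_distribution(150, "gamma", sd = 30)
  expect_equal(g$shape / g$rate, 150)
  expect_equal(sqrt(g$shape) / g$rate, 30)

  ln <- fit_uncertainty_distribution(0.88, "lognormal", sd = 0.22)
  m_ln <- exp(ln$meanlog + ln$sdlog^2 / 2)
  sd_ln <- m_ln * sqrt(exp(ln$sdlog^2) - 1)
  expect_equal(m_ln, 0.88, tolerance = 1e-12)
  expect_equal(sd_ln, 0.22, tolerance = 1e-12)
})

test_that("fitted distributions recover moments under sampling", {
  n <- 1e6
  set.seed(101)
  for (spec in list(
    fit_uncertainty_distribution(0.47, "beta", low = 0.34, high = 0.56),
    fit_uncertainty_distribution(0.88, "lognormal", sd = 0.22),
    fit_uncertainty_distribution(200, "gamma", sd = 200 * 0.3 / 1.96)
  )) {
    x <- sample_distribution(spec, n)
    se <- spec$sd / sqrt(n)
    expect_lt(abs(mean(x) - spec$mean), 3 * se)
    expect_equal(stats::sd(x), spec$sd, tolerance = 0.02)
  }
})

test_that("degenerate and invalid fits are handled", {
  pm <- fit_uncertainty_distribution(7, "gamma", sd = 0)
  expect_identical(pm$family, "point")
  expect_identical(sample_distribution(pm, 5), rep(7, 5))
  pm2 <- fit_uncertainty_distribution(0.3, "beta", low = 0.3, high = 0.3)
  expect_identical(pm2$family, "point")
  expect_error(fit_uncertainty_distribution(1.5, "beta", sd = 0.1),
               "in \\[0, 1\\]")
  expect_error(fit_uncertainty_distribution(0.5, "beta", sd = 0.6),
               "sd too large")
})

test_that("profiles, life tables and incidence schedules round-trip", {
  uk <- country_fixture("UK")
  tmp <- withr::local_tempdir()

  yml <- file.path(tmp, "uk.yaml")
  write_country_profile(uk$profile, yml)
  back <- load_country_profile(yml)
  for (f in setdiff(names(unclass(uk$profile)), "wage_schedule")) {
    expect_equal(back[[f]], uk$profile[[f]], info = f)
  }
  expect_equal(back$wage_schedule$wage, uk$profile$wage_schedule$wage)

  csv <- file.path(tmp, "lt.csv")
  write_life_table(uk$life_table, csv)
  expect_equal(read_life_table(csv), uk$life_table)

  icsv <- file.path(tmp, "inc.csv")
  write_incidence(uk$incidence, icsv)
  inc <- read_incidence(icsv)
  expect_equal(inc$incidence, uk$incidence$incidence)
})

test_that("life table and incidence validation rejects bad inputs", {
  expect_error(life_table(30:31, c(0.5, 1.2)), "\\[0, 1\\]")
  bad <- country_fixture("UK")$incidence
  i <- which(bad$group == "carrier" & bad$cancer == "bc")[1]
  bad$incidence[i] <- 0
  expect_error(brcacea:::validate_incidence(bad), "carrier incidence")
})
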