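# State space, transition matrices and the cohort trace.

test_that("both arms share one enumerable state space", {
  S <- build_state_space("population")
  expect_identical(S, build_state_space("fh"))
  expect_false(anyDuplicated(S) > 0)
  # 9 healthy (incl. 7 detected-carrier intervention states), 4 cancer
  # pathways x 6 stages, 4 absorbing deaths
  expect_length(S, 9 + 4 * 6 + 4)
  expect_true(all(c("carrier_undetected", "carrier_rrm_rrso_nohrt",
                    "sporadic_oc_survivor", "death_chd") %in% S))
})

test_that("intervention hazard modifiers match the published risk reductions", {
  pt <- probability_table()
  cases <- list(
    list("carrier_rrso_hrt", "oc", 0.04),
    list("carrier_rrso_nohrt", "oc", 0.04),
    list("carrier_none", "bc", 1.0),
    list("carrier_none", "oc", 1.0),
    list("carrier_rrm", "bc", 0.09),
    list("carrier_rrm", "oc", 1.0),
    list("carrier_rrm_rrso_hrt", "bc", 0.05),
    list("carrier_rrso_hrt", "bc", 0.49),
    list("carrier_chemoprev", "bc", 0.71),
    list("carrier_undetected", "bc", 1.0)
  )
  for (cs in cases) {
    expect_equal(carrier_hazard_modifier(cs[[1]], cs[[2]], 45, pt), cs[[3]],
                 tolerance = 1e-12, info = paste(cs[[1]], cs[[2]]))
  }
  expect_error(carrier_hazard_modifier("brca_bc_y1", "bc", 45, pt),
               "unknown intervention state")
})

test_that("transition rows are stochastic at every age", {
  uk <- country_fixture("UK")
  for (age in c(30, 37, 40, 55, 82)) {
    M <- transition_matrix(age, "population", uk)
    expect_true(all(M >= 0 & M <= 1))
    expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
    for (d in c("death_bc", "death_oc", "death_chd", "death_other")) {
      expect_identical(M[d, d], 1)   # absorbing
    }
  }
  expect_error(transition_matrix(20, "population", uk), "outside the modelled")
})

test_that("null hazards give the identity on healthy states", {
  p <- set_model_param(null_hazard_params(), "p11", 0)
  M <- transition_matrix(45, "population", p)
  for (h in c("healthy_noncarrier", "carrier_undetected", "carrier_none",
              "carrier_rrso_nohrt")) {
    expect_identical(M[h, h], 1)
  }
})

test_that("five-cycle survival after diagnosis equals the survival fraction", {
  p <- country_fixture("UK")
  p$life_table$qx[] <- 0   # isolate cancer-specific mortality
  v <- stats::setNames(numeric(length(build_state_space())),
                       build_state_space())
  v["brca_bc_y1"] <- 1
  for (age in 45:49) v <- drop(v %*% transition_matrix(age, "population", p))
  alive <- 1 - sum(v[c("death_bc", "death_oc", "death_chd", "death_other")])
  expect_equal(alive, p$survival$bc_5yr, tolerance = 1e-12)
  expect_equal(unname(v[["brca_bc_survivor"]]), p$survival$bc_5yr,
               tolerance = 1e-12)
})

test_that("cohort traces conserve mass and death is monotone", {
  uk <- country_fixture("UK")
  arm <- make_population_arm(uk)
  ct <- run_cohort(arm, uk)
  expect_identical(nrow(ct$trace), 54L)   # 53 cycles + initial row
  expect_lt(max(abs(rowSums(ct$trace) - 1)), 1e-10)
  dead <- rowSums(ct$trace[, c("death_bc", "death_oc", "death_chd",
                               "death_other")])
  expect_true(all(diff(dead) >= -1e-12))
  bad <- arm
  bad$init["healthy_noncarrier"] <- bad$init["healthy_noncarrier"] + 0.5
  expect_error(run_cohort(bad, uk), "sum to 1")
})

test_that("a fully dead cohort stays constant", {
  uk <- country_fixture("UK")
  arm <- make_population_arm(uk)
  arm$init[] <- 0
  arm$init["death_other"] <- 1
  ct <- run_cohort(arm, uk)
  expect_true(all(ct$trace[, "death_other"] == 1))
  expect_identical(sum(ct$events$new_bc), 0)
})

test_that("with zero intervention uptake the arms have identical dynamics", {
  uk <- country_fixture("UK")
  for (nm in c("p2", "p8", "p15")) uk <- set_model_param(uk, nm, 0)
  ct_pop <- run_cohort(make_population_arm(uk), uk)
  ct_fh <- run_cohort(make_fh_arm(uk), uk)
  # detected and undetected carriers face identical hazards, so the traces
  # agree once those two columns are pooled
  pool <- function(ct) {
    tr <- ct$trace
    tr[, "carrier_undetected"] <- tr[, "carrier_undetected"] +
      tr[, "carrier_none"]
    tr[, colnames(tr) != "carrier_none"]
  }
  expect_equal(pool(ct_pop), pool(ct_fh), tolerance = 1e-12)
  expect_equal(ct_pop$events$new_bc, ct_fh$events$new_bc, tolerance = 1e-12)
})

test_that("stronger risk reduction never increases lifetime cancer burden", {
  uk <- country_fixture("UK")
  lifetime <- function(params, what) {
    ct <- run_cohort(make_population_arm(params), params)
    sum(ct$events[[what]])
  }
  # p3 up (better RRSO protection) cannot raise ovarian-cancer cases
  expect_lte(lifetime(uk, "new_oc"),
             lifetime(set_model_param(uk, "p3", 0.80), "new_oc"))
  # p7 up (better RRM protection) cannot raise breast-cancer cases
  expect_lte(lifetime(uk, "new_bc"),
             lifetime(set_model_param(uk, "p7", 0.62), "new_bc"))
})

test_that("the cohort trace matches a seeded microsimulation (small n smoke)", {
  uk <- country_fixture("UK")
  arm <- make_population_arm(uk)
  ct <- run_cohort(arm, uk)
  ms <- microsim_cohort(arm, uk, n = 20000, seed = 11)
  n <- 20000
  se <- sqrt(ct$trace * (1 - ct$trace) / n)
  expect_true(all(abs(ms - ct$trace) <= 3 * se + 5e-4))
})
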