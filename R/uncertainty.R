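# Scenario, one-way and probabilistic sensitivity analyses, CEAC, and the
# test-cost threshold search.

#' Set a single model parameter by name
#'
#' Parameter names: the pathway probabilities (`"p1"` .. `"p15"`,
#' `"test_uptake"`, `"vus_prevalence"`), utilities (`"u_bc_early"`,
#' `"u_bc_advanced"`, `"u_bc_recurrent"`, `"u_bc_end"`, the `u_oc_*`
#' equivalents, `"u_rrm"`, `"u_rrso"`), scalar costs (`"brca_test"`,
#' `"pretest_counselling"`, `"posttest_counselling_carrier"`,
#' `"posttest_counselling_vus"`, `"rrm_procedure"`, `"rrso_procedure"`,
#' `"hrt_annual"`, `"bone_monitoring_annual"`, `"chd_treatment"`,
#' `"screening_annual"`, `"chemoprevention_course"`) and the stage-cost
#' multipliers (`"bc_treatment_scale"`, `"oc_treatment_scale"`, applied to
#' the default stage vectors). Overriding a probability outside its stored
#' uncertainty interval widens the interval to keep it bracketing.
#'
#' @param params a `brca_model_params` bundle.
#' @param name parameter name.
#' @param value new value (must lie within the parameter's support).
#' @return the modified bundle.
#' @export
set_model_param <- function(params, name, value) {
  set_many_params(params, stats::setNames(list(value), name))
}

# Batch setter: rebuilds each parameter component (probability table,
# utilities, costs) at most once, however many values change.
set_many_params <- function(params, values) {
  prob_names <- c(paste0("p", 1:15), "test_uptake", "vus_prevalence")
  util_names <- c(paste0("u_bc_", c("early", "advanced", "recurrent", "end")),
                  paste0("u_oc_", c("early", "advanced", "recurrent", "end")),
                  "u_rrm", "u_rrso")
  scalar_costs <- c("brca_test", "pretest_counselling",
                    "posttest_counselling_carrier", "posttest_counselling_vus",
                    "rrm_procedure", "rrso_procedure", "hrt_annual",
                    "bone_monitoring_annual", "chd_treatment",
                    "screening_annual", "chemoprevention_course")
  unknown <- setdiff(names(values),
                     c(prob_names, util_names, scalar_costs,
                       "bc_treatment_scale", "oc_treatment_scale"))
  if (length(unknown) > 0) {
    stop("unknown parameter: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pn <- intersect(names(values), prob_names)
  if (length(pn) > 0) {
    vals <- as.list(stats::setNames(
      vapply(prob_names, function(p) prob(params$probs, p), numeric(1)),
      prob_names))
    iv <- attr(params$probs, "intervals")
    for (name in pn) {
      vals[[name]] <- values[[name]]
      row <- iv$parameter == name
      if (any(row)) {
        iv$low[row] <- min(iv$low[row], values[[name]])
        iv$high[row] <- max(iv$high[row], values[[name]])
      }
    }
    params$probs <- do.call(probability_table, c(vals, list(intervals = iv)))
  }
  un <- intersect(names(values), util_names)
  if (length(un) > 0) {
    ut <- params$utilities
    stage_idx <- c(early = 1, advanced = 2, recurrent = 3, end = 4)
    bc <- ut$bc; oc <- ut$oc; rrm <- ut$rrm; rrso <- ut$rrso
    for (name in un) {
      v <- values[[name]]
      if (name == "u_rrm") {
        rrm <- v
      } else if (name == "u_rrso") {
        rrso <- v
      } else {
        k <- stage_idx[[sub("^u_(bc|oc)_", "", name)]]
        if (grepl("^u_bc_", name)) bc[k] <- v else oc[k] <- v
      }
    }
    params$utilities <- utility_table(bc, oc, rrm, ut$rrm_sd, rrso,
                                      ut$rrso_sd, ut$healthy)
  }
  cn <- intersect(names(values),
                  c(scalar_costs, "bc_treatment_scale", "oc_treatment_scale"))
  if (length(cn) > 0) {
    cs <- unclass(params$costs)
    for (name in cn) {
      if (name %in% scalar_costs) {
        cs[[name]] <- values[[name]]
      } else {
        key <- sub("_scale$", "_stage", name)
        cs[[key]] <- cs[[key]] * values[[name]]
      }
    }
    params$costs <- do.call(cost_schedule, cs)
  }
  params
}

#' Scenario specification and catalogue
#'
#' The published scenarios: (1) no breast-cancer risk reduction from RRSO
#' (`p9 = 1`); (2) no HRT compliance (`p13 = 0`); (3) half RRM uptake
#' (`p2 = 0.235`); (4) half RRSO uptake (`p8 = 0.275`); (5) a $100 test.
#'
#' @return a named list of scenario specs (label + parameter overrides).
#' @export
scenario_catalog <- function() {
  list(
    no_rrso_bc_benefit = list(label = "No reduction in breast cancer risk from RRSO (P9 = 1)",
                              overrides = list(p9 = 1)),
    no_hrt = list(label = "No compliance with HRT (P13 = 0)",
                  overrides = list(p13 = 0)),
    half_rrm = list(label = "Half RRM uptake (p2 = 0.235)",
                    overrides = list(p2 = 0.235)),
    half_rrso = list(label = "Half RRSO uptake (p8 = 0.275)",
                     overrides = list(p8 = 0.275)),
    test_cost_100 = list(label = "Genetic testing cost of $100",
                         overrides = list(brca_test = 100))
  )
}

#' Run one scenario
#'
#' @param spec a scenario spec (element of [scenario_catalog()], or any list
#'   with an `overrides` element of named parameter values).
#' @param params base `brca_model_params`.
#' @param discount_mode passed to [evaluate_strategies()].
#' @return a `brca_evaluation` under the overridden parameters.
#' @export
run_scenario <- function(spec, params, discount_mode = "who") {
  for (nm in names(spec$overrides)) {
    params <- set_model_param(params, nm, spec$overrides[[nm]])
  }
  evaluate_strategies(params, discount_mode)
}

#' One-way sensitivity analysis for a single parameter
#'
#' @param param parameter name (see [set_model_param()]).
#' @param low,high the two values to evaluate (`low <= high`).
#' @param params base bundle.
#' @param perspective `"payer"` or `"societal"`.
#' @param discount_mode discounting mode.
#' @return list with `icer_low`, `icer_high` and the absolute `spread`.
#' @export
one_way <- function(param, low, high, params,
                    perspective = c("societal", "payer"),
                    discount_mode = "who") {
  perspective <- match.arg(perspective)
  if (low > high) stop("low must be <= high", call. = FALSE)
  icer_of <- function(v) {
    ev <- evaluate_strategies(set_model_param(params, param, v), discount_mode)
    if (perspective == "payer") ev$icer_payer$icer else ev$icer_societal$icer
  }
  il <- icer_of(low); ih <- icer_of(high)
  list(param = param, icer_low = il, icer_high = ih, spread = abs(ih - il))
}

# Catalogue of uncertain parameters for the one-way and probabilistic
# analyses: probabilities take Beta distributions with SDs from their 95%
# intervals (+-10% where no interval is published), utilities take truncated
# log-normals (+-10%, or the published SDs for the surgery utilities), costs
# take Gammas varied +-30%. Ranges are clipped to each parameter's support.
psa_catalog <- function(params) {
  pr <- params$probs
  iv <- attr(pr, "intervals")
  entries <- list()
  add <- function(name, family, point, sd, low, high, upper = NULL) {
    entries[[name]] <<- list(name = name, family = family, point = point,
                             sd = sd, low = low, high = high, upper = upper)
  }
  for (p in c(paste0("p", 1:15), "test_uptake", "vus_prevalence")) {
    point <- prob(pr, p)
    row <- iv[iv$parameter == p, ]
    if (nrow(row) == 1) {
      lo <- row$low; hi <- row$high
    } else {
      lo <- max(0, 0.9 * point); hi <- min(1, 1.1 * point)
    }
    sd <- (hi - lo) / (2 * 1.96)
    if (p %in% c("p9", "p14")) {
      # hazard ratios: keep the Beta support (both are well inside (0,1))
      add(p, "beta", point, sd, lo, hi)
    } else {
      add(p, "beta", point, sd, max(0, lo), min(1, hi))
    }
  }
  ut <- params$utilities
  stage_names <- c("early", "advanced", "recurrent", "end")
  for (i in 1:4) {
    for (cc in c("bc", "oc")) {
      point <- ut[[cc]][i]
      nm <- paste0("u_", cc, "_", stage_names[i])
      add(nm, "lognormal", point, 0.1 * point / 1.96,
          0.9 * point, min(1, 1.1 * point), upper = 1)
    }
  }
  add("u_rrm", "lognormal", ut$rrm, ut$rrm_sd,
      max(0, ut$rrm - 1.96 * ut$rrm_sd), min(1, ut$rrm + 1.96 * ut$rrm_sd),
      upper = 1)
  add("u_rrso", "lognormal", ut$rrso, ut$rrso_sd,
      max(0, ut$rrso - 1.96 * ut$rrso_sd), min(1, ut$rrso + 1.96 * ut$rrso_sd),
      upper = 1)
  cs <- params$costs
  scalar_costs <- c("brca_test", "pretest_counselling",
                    "posttest_counselling_carrier", "posttest_counselling_vus",
                    "rrm_procedure", "rrso_procedure", "hrt_annual",
                    "bone_monitoring_annual", "chd_treatment",
                    "screening_annual", "chemoprevention_course")
  for (nm in scalar_costs) {
    point <- cs[[nm]]
    add(nm, "gamma", point, 0.3 * point / 1.96, 0.7 * point, 1.3 * point)
  }
  for (nm in c("bc_treatment_scale", "oc_treatment_scale")) {
    add(nm, "gamma", 1, 0.3 / 1.96, 0.7, 1.3)
  }
  entries
}

#' Tornado summary of one-way sensitivity analyses
#'
#' Evaluates [one_way()] over the full parameter catalogue at the published
#' variation ranges (95% intervals or +-10% for probabilities and utilities,
#' +-30% for costs) and orders parameters by the absolute ICER spread.
#'
#' @param params base bundle.
#' @param perspective `"payer"` or `"societal"`.
#' @param discount_mode discounting mode.
#' @return data frame with `param`, `icer_low`, `icer_high`, `spread`,
#'   ordered widest first.
#' @export
tornado <- function(params, perspective = c("societal", "payer"),
                    discount_mode = "who") {
  perspective <- match.arg(perspective)
  cat_ <- psa_catalog(params)
  rows <- lapply(cat_, function(e) {
    ow <- one_way(e$name, e$low, e$high, params, perspective, discount_mode)
    data.frame(param = e$name, icer_low = ow$icer_low,
               icer_high = ow$icer_high, spread = ow$spread)
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread), ]
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets (probabilities Beta, utilities truncated
#' log-normal, costs Gamma, fitted by method of moments) and evaluates the
#' full pipeline for each. Reproducible for a fixed seed: one master seed,
#' with draws taken parameter by parameter in the documented catalogue order
#' (`n` draws per parameter).
#'
#' @param n number of simulations (1000 in the published analysis).
#' @param seed master RNG seed.
#' @param params base bundle.
#' @param discount_mode discounting mode.
#' @param catalog optionally a modified [psa_catalog()] (e.g. with zero SDs
#'   for degeneracy checks).
#' @return a `brca_psa_samples` data frame with one row per draw: the
#'   incremental costs (payer and societal), incremental QALYs and
#'   life-years, and both ICERs.
#' @export
run_psa <- function(n = 1000, seed = 1L, params, discount_mode = "who",
                    catalog = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.null(catalog)) catalog <- psa_catalog(params)
  set.seed(seed)
  draws <- lapply(catalog, function(e) {
    spec <- fit_uncertainty_distribution(e$point, e$family, sd = e$sd)
    sample_distribution(spec, n, upper = e$upper)
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p_i <- set_many_params(params, lapply(draws, `[`, i))
    ev <- evaluate_strategies(p_i, discount_mode)
    out[[i]] <- data.frame(
      draw = i,
      delta_cost_payer = ev$icer_payer$delta_cost,
      delta_cost_societal = ev$icer_societal$delta_cost,
      delta_qaly = ev$icer_payer$delta_effect,
      delta_ly = ev$pop$ly - ev$fh$ly,
      icer_payer = ev$icer_payer$icer,
      icer_societal = ev$icer_societal$icer
    )
  }
  samples <- do.call(rbind, out)
  attr(samples, "seed") <- seed
  attr(samples, "country") <- params$profile$name
  class(samples) <- c("brca_psa_samples", "data.frame")
  samples
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value `w`, the proportion of PSA draws with
#' non-negative net monetary benefit, `w * dQALY - dCost >= 0`. The
#' net-benefit criterion handles cost-saving draws correctly where a raw
#' ICER comparison would not.
#'
#' @param samples a `brca_psa_samples`.
#' @param wtp_grid vector of WTP thresholds ($/QALY).
#' @param perspective `"payer"` or `"societal"`.
#' @return a `brca_ceac_curve` data frame with `wtp` and
#'   `proportion_cost_effective`.
#' @export
ceac <- function(samples, wtp_grid, perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  if (nrow(samples) == 0) stop("no PSA samples supplied", call. = FALSE)
  if (length(wtp_grid) == 0) stop("empty WTP grid", call. = FALSE)
  dc <- if (perspective == "payer") samples$delta_cost_payer else
    samples$delta_cost_societal
  de <- samples$delta_qaly
  prop <- vapply(wtp_grid, function(w) mean(w * de - dc >= 0), numeric(1))
  out <- data.frame(wtp = wtp_grid, proportion_cost_effective = prop)
  attr(out, "perspective") <- perspective
  class(out) <- c("brca_ceac_curve", "data.frame")
  out
}

#' Maximum test cost at which population testing stays cost-effective
#'
#' Bisection on the BRCA test cost for the cost at which the ICER equals the
#' willingness-to-pay threshold (the ICER is monotone increasing in the test
#' cost, asserted by a probe before searching). Transition dynamics do not
#' depend on the test cost, so the cohort traces are computed once and the
#' economic accrual is re-run per probe.
#'
#' @param wtp willingness-to-pay threshold ($/QALY).
#' @param params base bundle.
#' @param perspective `"payer"` or `"societal"`.
#' @param discount_mode discounting mode.
#' @param tolerance convergence tolerance on `|ICER - wtp|` ($1 per QALY by
#'   default).
#' @param upper initial upper bracket for the search (doubled as needed).
#' @return list with `test_cost`, the paired `icer`, and `wtp`; `test_cost`
#'   is `NA` with a `"never cost-effective"` message when even a free test
#'   exceeds the threshold.
#' @export
threshold_test_cost <- function(wtp, params,
                                perspective = c("societal", "payer"),
                                discount_mode = "who", tolerance = 1,
                                upper = 1600) {
  perspective <- match.arg(perspective)
  rates <- discount_rates(params$profile, discount_mode)
  matrices <- build_matrix_set(params)
  arm_pop0 <- make_population_arm(params)
  arm_fh0 <- make_fh_arm(params)
  ct_pop <- run_cohort(arm_pop0, params, matrices)
  ct_fh <- run_cohort(arm_fh0, params, matrices)
  icer_at <- function(cost) {
    p2 <- set_model_param(params, "brca_test", cost)
    ap <- make_population_arm(p2); af <- make_fh_arm(p2)
    rp <- accrue(ct_pop, ap, p2, rates)
    rf <- accrue(ct_fh, af, p2, rates)
    compute_icer(rp, rf, perspective, p2$profile)$icer
  }
  if (icer_at(150) <= icer_at(50)) {
    stop("ICER is not increasing in the test cost; bisection precondition fails",
         call. = FALSE)
  }
  lo <- 0
  f_lo <- icer_at(lo)
  if (f_lo > wtp) {
    return(list(test_cost = NA_real_, icer = f_lo, wtp = wtp,
                message = "never cost-effective"))
  }
  hi <- upper
  for (i in 1:30) {
    if (icer_at(hi) >= wtp) break
    hi <- hi * 2
    if (hi > 1e7) stop("no finite threshold below $1e7", call. = FALSE)
  }
  mid <- (lo + hi) / 2
  f_mid <- icer_at(mid)
  while (abs(f_mid - wtp) > tolerance && hi - lo > 1e-6) {
    if (f_mid <= wtp) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
    f_mid <- icer_at(mid)
  }
  list(test_cost = mid, icer = f_mid, wtp = wtp)
}
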