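# Economic accrual: discounted life-years, QALYs, payer and societal costs
# over a cohort trace, plus undiscounted per-million event counts.
#
# Accrual convention: state membership is valued at cycle start (cycle t
# carries discount exponent t, t = 0, 1, ...); one-off event costs are
# charged in the cycle whose transition generates them. No half-cycle
# correction is applied.

#' Discount factor
#'
#' @param rate per-annum discount rate (>= 0).
#' @param cycle cycle index (0 = no discounting).
#' @return `(1 + rate)^(-cycle)`.
#' @export
#' @examples
#' discount_factor(0.03, 1)    # 0.9709
discount_factor <- function(rate, cycle) {
  if (any(rate < 0)) stop("discount rate must be >= 0", call. = FALSE)
  if (any(cycle < 0)) stop("cycle index must be >= 0", call. = FALSE)
  (1 + rate)^(-cycle)
}

#' Resolve the discount rates for an analysis
#'
#' @param profile a `brca_country_profile`.
#' @param mode `"who"` (3% costs and effects) or `"local"`
#'   (country-recommended rates).
#' @return list with `cost` and `effect` rates.
#' @export
discount_rates <- function(profile, mode = c("who", "local")) {
  mode <- match.arg(mode)
  if (mode == "who") {
    list(cost = 0.03, effect = 0.03)
  } else {
    list(cost = profile$discount_cost_rate,
         effect = profile$discount_effect_rate)
  }
}

wage_at <- function(wage_schedule, ages) {
  w <- wage_schedule$wage[match(ages, wage_schedule$age)]
  w[is.na(w)] <- 0
  w
}

#' Productivity loss for a single event (human-capital approach)
#'
#' At diagnosis: temporary disability (workdays absent valued at the
#' age-specific daily wage) plus permanent disability (the discounted stream
#' of age-specific gross earnings from diagnosis to retirement, scaled by the
#' effective hours-reduction-or-departure fraction). At death: premature
#' mortality (the full discounted wage stream from the age at death to
#' retirement). All components are scaled by labour-force participation and
#' are zero at or beyond retirement age. The returned value is a present
#' value at the event time.
#'
#' @param event `"diagnosis"` or `"death"`.
#' @param age age at the event.
#' @param cancer `"bc"` or `"oc"` (or `"chd"` for fatal heart-disease
#'   events); the components are cancer-agnostic but the label is kept for
#'   reporting.
#' @param profile a `brca_country_profile` (wages, retirement,
#'   participation).
#' @param productivity a `brca_productivity_params`.
#' @param rate discount rate for the within-stream discounting.
#' @return currency amount (2016 USD PPP).
#' @export
#' @examples
#' uk <- make_country_fixture("UK")
#' productivity_loss("death", 55, "bc", uk$profile, uk$productivity, 0)
productivity_loss <- function(event = c("diagnosis", "death"), age, cancer,
                              profile, productivity, rate = 0.03) {
  event <- match.arg(event)
  ret <- profile$retirement_age
  q <- profile$labour_participation
  if (age >= ret || q == 0) return(0)
  years <- age:(ret - 1)
  wages <- wage_at(profile$wage_schedule, years)
  stream <- sum(wages * discount_factor(rate, years - age)) * q
  if (event == "death") {
    stream
  } else {
    pp <- productivity
    temporary <- wage_at(profile$wage_schedule, age) * q *
      pp$absence_days / pp$workdays_per_year
    eff <- pp$departure_fraction +
      (1 - pp$departure_fraction) * pp$hours_reduction
    temporary + stream * eff
  }
}

# utility vector over the state space, given stage durations
state_utilities <- function(params) {
  S <- build_state_space()
  u <- stats::setNames(rep(params$utilities$healthy, length(S)), S)
  stage_of_year <- rep(1:4, times = params$survival$stage_durations)
  for (g in cancer_groups()) {
    stage_u <- if (grepl("_bc", g)) params$utilities$bc else params$utilities$oc
    for (k in 1:5) u[paste0(g, "_y", k)] <- stage_u[stage_of_year[k]]
    u[paste0(g, "_survivor")] <- params$utilities$healthy
  }
  u[death_states()] <- 0
  u
}

# annual state-occupancy payer costs at a given age
state_costs_at_age <- function(params, age) {
  S <- build_state_space()
  cs <- params$costs
  prof <- params$profile
  cost <- stats::setNames(numeric(length(S)), S)
  screening_states <- c("carrier_none", "carrier_chemoprev",
                        "carrier_rrso_hrt", "carrier_rrso_nohrt")
  if (age <= 70) cost[screening_states] <- cs$screening_annual
  if (age >= prof$rrso_age && age < prof$hrt_stop_age) {
    cost[c("carrier_rrso_hrt", "carrier_rrm_rrso_hrt")] <-
      cost[c("carrier_rrso_hrt", "carrier_rrm_rrso_hrt")] + cs$hrt_annual
  }
  if (age >= prof$rrso_age) {
    rrso_states <- c("carrier_rrso_hrt", "carrier_rrso_nohrt",
                     "carrier_rrm_rrso_hrt", "carrier_rrm_rrso_nohrt")
    cost[rrso_states] <- cost[rrso_states] + cs$bone_monitoring_annual
  }
  stage_of_year <- rep(1:4, times = params$survival$stage_durations)
  for (g in cancer_groups()) {
    stage_c <- if (grepl("_bc", g)) cs$bc_treatment_stage else cs$oc_treatment_stage
    for (k in 1:5) cost[paste0(g, "_y", k)] <- stage_c[stage_of_year[k]]
  }
  cost
}

#' Accrue discounted outcomes over a cohort trace
#'
#' Computes discounted life-years, QALYs (stage utilities for the cancer
#' years, one-cycle utility decrements in the surgery years), discounted
#' payer costs (testing pathway, surgeries, chemoprevention, screening, HRT,
#' bone health monitoring, heart-disease events, stage-based cancer
#' treatment) and societal costs (payer costs plus the three-component
#' productivity loss), together with undiscounted per-million lifetime event
#' counts.
#'
#' @param ct a `brca_cohort_trace` from [run_cohort()].
#' @param arm_spec the `brca_arm_spec` that produced it.
#' @param params the `brca_model_params` bundle.
#' @param rates discount rates, e.g. [discount_rates()] output.
#' @param perspective reporting perspective recorded on the result; both
#'   payer and societal totals are always computed.
#' @return a `brca_strategy_result`.
#' @export
accrue <- function(ct, arm_spec, params, rates = list(cost = 0.03, effect = 0.03),
                   perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  prof <- params$profile
  cycles <- ct$cycles
  if (!identical(arm_spec$label, ct$arm)) {
    stop("configuration error: trace and arm spec are inconsistent",
         call. = FALSE)
  }
  u <- state_utilities(params)
  alive_idx <- state_index(setdiff(ct$state_space, death_states()))
  df_e <- discount_factor(rates$effect, 0:(cycles - 1))
  df_c <- discount_factor(rates$cost, 0:(cycles - 1))

  ly <- 0; qaly <- 0; payer <- 0; productivity_total <- 0
  cs <- params$costs
  ev <- ct$events
  ages <- prof$start_age + seq_len(cycles) - 1
  cost_rows <- vapply(ages, function(a) state_costs_at_age(params, a),
                      numeric(length(u)))
  diagnosis_loss <- vapply(ages, function(a) {
    productivity_loss("diagnosis", a, "bc", prof, params$productivity,
                      rates$cost)
  }, numeric(1))
  death_loss <- vapply(ages, function(a) {
    productivity_loss("death", a, "bc", prof, params$productivity, rates$cost)
  }, numeric(1))

  payer <- payer + arm_spec$cycle0_cost  # cycle 0, undiscounted

  for (t in seq_len(cycles)) {
    v <- ct$occupancy[t, ]
    alive <- sum(v[alive_idx])
    ly <- ly + alive * df_e[t]
    qaly <- qaly + sum(v * u) * df_e[t]
    # one-cycle surgery disutilities on the flows entering surgery this cycle
    qaly <- qaly - ev$rrm_flow[t] * (1 - params$utilities$rrm) * df_e[t]
    qaly <- qaly - ev$rrso_flow[t] * (1 - params$utilities$rrso) * df_e[t]

    cost_t <- sum(v * cost_rows[, t]) +
      ev$rrm_flow[t] * cs$rrm_procedure +
      ev$rrso_flow[t] * cs$rrso_procedure +
      ev$chemo_flow[t] * cs$chemoprevention_course +
      ev$chd_events[t] * cs$chd_treatment
    payer <- payer + cost_t * df_c[t]

    prod_t <- (ev$new_bc[t] + ev$new_oc[t]) * diagnosis_loss[t] +
      (ev$death_bc[t] + ev$death_oc[t] + ev$death_chd[t]) * death_loss[t]
    productivity_total <- productivity_total + prod_t * df_c[t]
  }

  counts <- c(bc_cases = sum(ev$new_bc), oc_cases = sum(ev$new_oc),
              bc_deaths = sum(ev$death_bc), oc_deaths = sum(ev$death_oc),
              chd_deaths = sum(ev$death_chd)) * 1e6

  structure(list(arm = arm_spec$label, perspective = perspective,
                 ly = ly, qaly = qaly,
                 cost_payer = payer,
                 cost_societal = payer + productivity_total,
                 productivity_loss = productivity_total,
                 per_million = counts, rates = rates),
            class = "brca_strategy_result")
}

#' @export
print.brca_strategy_result <- function(x, ...) {
  cat("<brca_strategy_result>", x$arm, "\n")
  cat(sprintf("  LY %.4f | QALY %.4f | payer $%.0f | societal $%.0f\n",
              x$ly, x$qaly, x$cost_payer, x$cost_societal))
  cat("  per million:",
      paste(names(x$per_million), round(x$per_million), collapse = ", "),
      "\n")
  invisible(x)
}

strategy_cost <- function(result, perspective) {
  switch(perspective,
         payer = result$cost_payer,
         societal = result$cost_societal,
         stop("unknown perspective: ", perspective, call. = FALSE))
}
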