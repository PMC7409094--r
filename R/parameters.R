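#' @title Model probability inputs
#'
#' @description
#' `probability_table()` constructs the set of pathway probabilities driving
#' the cohort model: mutation prevalence, family-history prevalence, uptake of
#' risk-reducing mastectomy (RRM), risk-reducing salpingo-oophorectomy (RRSO)
#' and chemoprevention, the risk reductions those interventions confer, excess
#' coronary heart disease (CHD) risk after premenopausal RRSO without hormone
#' replacement therapy (HRT), HRT compliance, genetic-testing uptake and the
#' prevalence of variants of uncertain significance (VUS).
#'
#' Defaults are the published point estimates with their 95% confidence
#' intervals or ranges, used downstream by the one-way and probabilistic
#' sensitivity analyses.
#'
#' @param ... named overrides of any parameter, e.g. `p9 = 1`.
#' @param intervals optional data frame with columns `parameter`, `low`,
#'   `high` replacing the default uncertainty intervals.
#'
#' @return An object of class `brca_probability_table`: a named list of
#'   numeric point values with an `intervals` attribute.
#' @export
#' @examples
#' pt <- probability_table()
#' pt$p1            # carrier prevalence in the general population
#' probability_table(p9 = 1)$p9
probability_table <- function(..., intervals = NULL) {
  defaults <- list(
    p1_prevalence_general = 0.0067,
    p2_rrm_uptake = 0.47,
    p3_rrso_oc_risk_reduction = 0.96,
    p4_fh_positive = 0.0098,
    p5_prevalence_fh_positive = 0.1,
    p6_prevalence_fh_negative = 0.0058,
    p7_rrm_bc_risk_reduction_without_rrso = 0.91,
    p8_rrso_uptake = 0.55,
    p9_rrso_bc_hazard_ratio = 0.49,
    p10_rrm_bc_risk_reduction_with_rrso = 0.95,
    p11_excess_chd_risk = 0.0072,
    p12_fatal_chd_risk = 0.0303,
    p13_hrt_compliance = 0.8,
    p14_chemoprevention_bc_hazard_ratio = 0.71,
    p15_chemoprevention_uptake = 0.163,
    test_uptake = 0.70,
    vus_prevalence = 0.02
  )
  # short aliases p1..p15 map onto the long names
  long <- names(defaults)
  short <- c(paste0("p", 1:15), "test_uptake", "vus_prevalence")
  overrides <- list(...)
  for (nm in names(overrides)) {
    idx <- match(nm, short)
    key <- if (!is.na(idx)) long[idx] else nm
    if (!key %in% long) {
      stop("unknown probability parameter: ", nm, call. = FALSE)
    }
    defaults[[key]] <- overrides[[nm]]
  }
  if (is.null(intervals)) intervals <- default_probability_intervals()
  pt <- structure(defaults, class = "brca_probability_table",
                  intervals = intervals)
  validate_probability_table(pt)
  pt
}

default_probability_intervals <- function() {
  data.frame(
    parameter = c(paste0("p", c(1:4, 6:15)), "test_uptake", "vus_prevalence"),
    low  = c(0.0059, 0.34, 0.80, 0.0047, 0.0051, 0.62, 0.45, 0.37, 0.78,
             0.0068, 0.011, 0.76, 0.60, 0.136, 0.63, 0.018),
    high = c(0.0077, 0.56, 0.96, 0.0179, 0.0068, 0.98, 0.64, 0.65, 0.99,
             0.0076, 0.043, 0.83, 0.83, 0.190, 0.77, 0.022),
    stringsAsFactors = FALSE
  )
}

#' Access a probability by its short name
#'
#' @param pt a `brca_probability_table`.
#' @param name short name (`"p1"` .. `"p15"`, `"test_uptake"`,
#'   `"vus_prevalence"`).
#' @return the numeric point value.
#' @export
prob <- function(pt, name) {
  long <- names(unclass(pt))
  short <- c(paste0("p", 1:15), "test_uptake", "vus_prevalence")
  idx <- match(name, short)
  key <- if (!is.na(idx)) long[idx] else name
  if (!key %in% long) stop("unknown probability parameter: ", name, call. = FALSE)
  pt[[key]]
}

validate_probability_table <- function(pt) {
  vals <- unlist(unclass(pt))
  hr <- c("p9_rrso_bc_hazard_ratio", "p14_chemoprevention_bc_hazard_ratio")
  probs <- vals[setdiff(names(vals), hr)]
  if (any(probs < 0 | probs > 1)) {
    bad <- names(probs)[probs < 0 | probs > 1]
    stop("probability out of [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(vals[hr] <= 0)) stop("hazard ratios must be > 0", call. = FALSE)
  iv <- attr(pt, "intervals")
  if (!is.null(iv)) {
    short <- c(paste0("p", 1:15), "test_uptake", "vus_prevalence")
    for (i in seq_len(nrow(iv))) {
      p <- prob(pt, iv$parameter[i])
      if (iv$parameter[i] %in% short &&
          (p < iv$low[i] - 1e-12 || p > iv$high[i] + 1e-12)) {
        stop("interval for ", iv$parameter[i],
             " does not bracket the point value", call. = FALSE)
      }
    }
  }
  invisible(pt)
}

#' @export
print.brca_probability_table <- function(x, ...) {
  cat("<brca_probability_table>\n")
  v <- unlist(unclass(x))
  print(round(v, 4))
  invisible(x)
}

#' Health-state utility scores
#'
#' Utility weights (1 = perfect health, 0 = death) for the four breast-cancer
#' and four ovarian-cancer stages, the two risk-reducing surgeries (applied as
#' a one-cycle decrement in the surgery year) and the healthy state.
#'
#' @param bc,oc length-4 numeric vectors: early, advanced, recurrent,
#'   end-stage utilities.
#' @param rrm,rrso surgery-cycle utilities, with standard deviations
#'   `rrm_sd`, `rrso_sd` used by the probabilistic sensitivity analysis.
#' @param healthy utility of the well states.
#' @return An object of class `brca_utility_table`.
#' @export
utility_table <- function(bc = c(0.71, 0.65, 0.45, 0.16),
                          oc = c(0.81, 0.55, 0.61, 0.16),
                          rrm = 0.88, rrm_sd = 0.22,
                          rrso = 0.95, rrso_sd = 0.10,
                          healthy = 1.0) {
  stopifnot(length(bc) == 4, length(oc) == 4)
  u <- c(bc, oc, rrm, rrso, healthy)
  if (any(u < 0 | u > 1)) stop("utilities must lie in [0, 1]", call. = FALSE)
  structure(list(bc = bc, oc = oc, rrm = rrm, rrm_sd = rrm_sd,
                 rrso = rrso, rrso_sd = rrso_sd, healthy = healthy),
            class = "brca_utility_table")
}

#' Cost schedule (2016 USD, purchasing-power-parity adjusted)
#'
#' All monetary inputs to the model. Stage treatment costs are annual costs
#' while occupying the corresponding post-diagnosis stage (early, advanced,
#' recurrent, end-stage). The default testing cost of $200 is the standard
#' internationally available BRCA test price used for the base case; the
#' remaining defaults are synthetic placeholders at UK-like magnitudes and are
#' replaced per country by the synthetic generator or user-supplied values.
#'
#' @param brca_test,pretest_counselling,posttest_counselling_carrier,posttest_counselling_vus
#'   one-off testing-pathway costs per woman.
#' @param rrm_procedure,rrso_procedure one-off surgery costs.
#' @param hrt_annual,bone_monitoring_annual,screening_annual annual costs
#'   (HRT to age 51; bone health monitoring incl. DEXA after RRSO; MRI or
#'   mammography screening for unmastectomised detected carriers).
#' @param chd_treatment cost per coronary heart disease event.
#' @param bc_treatment_stage,oc_treatment_stage length-4 annual treatment
#'   costs by stage.
#' @param chemoprevention_course one-off cost of a chemoprevention course.
#' @return An object of class `brca_cost_schedule`.
#' @export
cost_schedule <- function(brca_test = 200,
                          pretest_counselling = 30,
                          posttest_counselling_carrier = 250,
                          posttest_counselling_vus = 120,
                          rrm_procedure = 11000,
                          rrso_procedure = 5500,
                          hrt_annual = 150,
                          bone_monitoring_annual = 120,
                          chd_treatment = 15000,
                          bc_treatment_stage = c(20000, 28000, 35000, 45000),
                          oc_treatment_stage = c(25000, 32000, 38000, 48000),
                          screening_annual = 450,
                          chemoprevention_course = 1500) {
  cs <- list(brca_test = brca_test,
             pretest_counselling = pretest_counselling,
             posttest_counselling_carrier = posttest_counselling_carrier,
             posttest_counselling_vus = posttest_counselling_vus,
             rrm_procedure = rrm_procedure,
             rrso_procedure = rrso_procedure,
             hrt_annual = hrt_annual,
             bone_monitoring_annual = bone_monitoring_annual,
             chd_treatment = chd_treatment,
             bc_treatment_stage = bc_treatment_stage,
             oc_treatment_stage = oc_treatment_stage,
             screening_annual = screening_annual,
             chemoprevention_course = chemoprevention_course)
  if (any(unlist(cs) < 0)) stop("costs must be non-negative", call. = FALSE)
  stopifnot(length(bc_treatment_stage) == 4, length(oc_treatment_stage) == 4)
  structure(cs, class = "brca_cost_schedule")
}

# Country-level constants: cycle counts, willingness-to-pay thresholds,
# female population over 30, retirement ages (lower bounds of published
# ranges), labour-force participation and local discount rates.
country_constants <- function() {
  data.frame(
    name = c("UK", "USA", "Netherlands", "China", "Brazil", "India"),
    cycles = c(53L, 52L, 53L, 48L, 49L, 38L),
    female_population_over_30 = c(21760299, 101428241, 5694479,
                                  422831894, 58670634, 298650697),
    retirement_age = c(65, 62, 68, 50, 60, 60),
    labour_participation = c(0.5677, 0.5599, 0.5802, 0.6203, 0.5332, 0.2745),
    wtp_1gdp = c(42656, 57589, 50539, 15531, 15182, 6574),
    wtp_3gdp = c(127969, 172766, 151616, 46592, 45545, 19722),
    wtp_guideline_low = c(28471, 50000, 24390, NA, NA, NA),
    wtp_guideline_high = c(42857, 100000, 60976, NA, NA, NA),
    discount_cost_local = c(0.035, 0.03, 0.04, 0.03, 0.03, 0.03),
    discount_effect_local = c(0.035, 0.03, 0.015, 0.03, 0.03, 0.03),
    stringsAsFactors = FALSE
  )
}

#' Build or load a country profile
#'
#' A country profile gathers the country-level constants the model needs:
#' number of annual Markov cycles from age 30 (set by life expectancy),
#' discount rates, willingness-to-pay (WTP) thresholds, female population over
#' 30, retirement age, labour-force participation, a wage schedule, and the
#' median intervention ages (RRM at 37, RRSO at 40, HRT until 51).
#'
#' @param source a country name (`"UK"`, `"USA"`, `"Netherlands"`, `"China"`,
#'   `"Brazil"`, `"India"`), a path to a YAML file, or a named list supplying
#'   every field.
#' @param wage_schedule optional data frame (`age`, `wage`) overriding the
#'   default synthetic wage curve.
#' @return An object of class `brca_country_profile`.
#' @export
#' @examples
#' uk <- load_country_profile("UK")
#' uk$cycles
load_country_profile <- function(source, wage_schedule = NULL) {
  if (is.character(source) && length(source) == 1 && file.exists(source)) {
    source <- yaml::read_yaml(source)
    if (!is.null(source$wage_schedule)) {
      source$wage_schedule <- as.data.frame(source$wage_schedule)
    }
  }
  if (is.character(source)) {
    cc <- country_constants()
    row <- cc[cc$name == source, ]
    if (nrow(row) == 0) {
      stop("unknown country: ", source, " (known: ",
           paste(cc$name, collapse = ", "), ")", call. = FALSE)
    }
    if (is.null(wage_schedule)) {
      wage_schedule <- make_wage_schedule(synthetic_spec(), source)
    }
    prof <- list(
      name = row$name, cycles = row$cycles, start_age = 30,
      discount_cost_rate = row$discount_cost_local,
      discount_effect_rate = row$discount_effect_local,
      wtp_1gdp = row$wtp_1gdp, wtp_3gdp = row$wtp_3gdp,
      wtp_guideline_low = row$wtp_guideline_low,
      wtp_guideline_high = row$wtp_guideline_high,
      female_population_over_30 = row$female_population_over_30,
      retirement_age = row$retirement_age,
      labour_participation = row$labour_participation,
      wage_schedule = wage_schedule,
      rrm_age = 37, rrso_age = 40, hrt_stop_age = 51
    )
  } else {
    required <- c("name", "cycles", "start_age", "discount_cost_rate",
                  "discount_effect_rate", "wtp_1gdp", "wtp_3gdp",
                  "female_population_over_30", "retirement_age",
                  "labour_participation", "wage_schedule")
    missing <- setdiff(required, names(source))
    if (length(missing) > 0) {
      stop("country profile configuration is missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    defaults <- list(wtp_guideline_low = NA_real_,
                     wtp_guideline_high = NA_real_,
                     rrm_age = 37, rrso_age = 40, hrt_stop_age = 51)
    prof <- utils::modifyList(defaults, source)
    prof$wage_schedule <- as.data.frame(prof$wage_schedule)
  }
  prof <- structure(prof, class = "brca_country_profile")
  validate_country_profile(prof)
  prof
}

validate_country_profile <- function(p) {
  if (!is.numeric(p$cycles) || p$cycles < 1) {
    stop("validation error: cycles must be >= 1", call. = FALSE)
  }
  rates <- c(p$discount_cost_rate, p$discount_effect_rate)
  if (any(rates < 0 | rates > 0.1)) {
    stop("validation error: discount rates must lie in [0, 0.1]",
         call. = FALSE)
  }
  if (p$labour_participation < 0 || p$labour_participation > 1) {
    stop("validation error: labour participation must lie in [0, 1]",
         call. = FALSE)
  }
  if (!(p$rrm_age < p$rrso_age && p$rrso_age < p$hrt_stop_age &&
        p$hrt_stop_age < p$start_age + p$cycles)) {
    stop("validation error: intervention ages must satisfy ",
         "rrm_age < rrso_age < hrt_stop_age < start_age + cycles",
         call. = FALSE)
  }
  stopifnot(is.data.frame(p$wage_schedule),
            all(c("age", "wage") %in% names(p$wage_schedule)))
  if (any(p$wage_schedule$wage < 0)) {
    stop("validation error: wages must be non-negative", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.brca_country_profile <- function(x, ...) {
  cat("<brca_country_profile> ", x$name, "\n", sep = "")
  cat(sprintf("  cycles: %d (ages %d-%d)\n", x$cycles, x$start_age,
              x$start_age + x$cycles))
  cat(sprintf("  discount (local): cost %.1f%%, effect %.1f%%\n",
              100 * x$discount_cost_rate, 100 * x$discount_effect_rate))
  cat(sprintf("  WTP 1xGDP/3xGDP: %s / %s $/QALY\n",
              format(x$wtp_1gdp, big.mark = ","),
              format(x$wtp_3gdp, big.mark = ",")))
  cat(sprintf("  female population over 30: %s\n",
              format(x$female_population_over_30, big.mark = ",")))
  invisible(x)
}

#' Write a country profile to YAML
#'
#' @param profile a `brca_country_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_country_profile <- function(profile, path) {
  p <- unclass(profile)
  p$wage_schedule <- as.list(p$wage_schedule)
  yaml::write_yaml(p, path)
  invisible(path)
}

#' Life table constructor and validation
#'
#' @param age integer ages.
#' @param qx annual all-cause death probabilities.
#' @return a `brca_life_table` data frame with columns `age`, `qx`.
#' @export
life_table <- function(age, qx) {
  lt <- data.frame(age = as.integer(age), qx = as.numeric(qx))
  if (any(lt$qx < 0 | lt$qx > 1)) {
    stop("life table qx values must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(lt$age)) stop("duplicated ages in life table", call. = FALSE)
  class(lt) <- c("brca_life_table", "data.frame")
  lt
}

# Death probability lookup; errors if the modelled span is not covered.
lt_qx <- function(lt, ages) {
  idx <- match(ages, lt$age)
  if (anyNA(idx)) {
    stop("life table does not cover age(s) ",
         paste(ages[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  lt$qx[idx]
}

#' @export
#' @rdname life_table
#' @param lt a life table.
#' @param path CSV file path (columns `age`, `qx`).
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[, c("age", "qx")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname life_table
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  life_table(d$age, d$qx)
}

#' Incidence schedule IO
#'
#' Incidence schedules are long data frames with columns `age`, `group`
#' (`"sporadic"` or `"carrier"`), `cancer` (`"bc"` or `"oc"`) and `incidence`
#' (annual probability of diagnosis).
#'
#' @param x an incidence schedule data frame.
#' @param path CSV path.
#' @return the schedule (read) or `path` (write), invisibly.
#' @export
write_incidence <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("age", "group", "cancer", "incidence")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname write_incidence
read_incidence <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_incidence(d)
  d
}

validate_incidence <- function(d) {
  stopifnot(all(c("age", "group", "cancer", "incidence") %in% names(d)))
  if (any(d$incidence < 0 | d$incidence > 1)) {
    stop("incidence probabilities must lie in [0, 1]", call. = FALSE)
  }
  wide <- incidence_lookup(d)
  for (cn in c("bc", "oc")) {
    if (any(wide[[paste0("carrier_", cn)]] <
            wide[[paste0("sporadic_", cn)]] - 1e-12)) {
      stop("carrier incidence must be >= sporadic incidence at every age",
           call. = FALSE)
    }
  }
  invisible(d)
}

# wide lookup: one row per age with sporadic_bc, sporadic_oc, carrier_bc,
# carrier_oc columns
incidence_lookup <- function(d) {
  ages <- sort(unique(d$age))
  out <- data.frame(age = ages)
  for (g in c("sporadic", "carrier")) {
    for (cn in c("bc", "oc")) {
      sub <- d[d$group == g & d$cancer == cn, ]
      out[[paste0(g, "_", cn)]] <- sub$incidence[match(ages, sub$age)]
    }
  }
  if (anyNA(out)) stop("incidence schedule has gaps", call. = FALSE)
  out
}

#' Five-year survival model
#'
#' Cancer survival is modelled through five post-diagnosis years with a flat
#' annual cancer-specific death probability calibrated so that five-cycle
#' survival (absent background mortality) equals the five-year survival
#' fraction; thereafter mortality reverts to the background life table.
#' Utilities and treatment costs traverse the four clinical stages according
#' to `stage_durations` (years spent in early, advanced, recurrent and
#' end-stage over the five post-diagnosis years).
#'
#' @param bc_5yr,oc_5yr five-year survival fractions.
#' @param stage_durations length-4 integer years summing to 5.
#' @return a `brca_survival_model`.
#' @export
survival_model <- function(bc_5yr = 0.86, oc_5yr = 0.36,
                           stage_durations = c(2, 1, 1, 1)) {
  if (bc_5yr < 0 || bc_5yr > 1 || oc_5yr < 0 || oc_5yr > 1) {
    stop("survival fractions must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(stage_durations) == 4, sum(stage_durations) == 5)
  structure(list(bc_5yr = bc_5yr, oc_5yr = oc_5yr,
                 stage_durations = stage_durations),
            class = "brca_survival_model")
}

#' Productivity-loss parameters (human-capital approach)
#'
#' The three sub-components of productivity loss: temporary disability
#' (workdays absent after diagnosis), permanent disability (reduced working
#' hours after return to work plus workforce departure), and premature
#' mortality (lost wage stream from death to retirement). Magnitudes for the
#' temporary and permanent components are synthetic placeholders.
#'
#' @param absence_days workdays absent per cancer diagnosis.
#' @param hours_reduction fractional reduction in working hours among
#'   returners.
#' @param departure_fraction fraction permanently leaving the workforce.
#' @param workdays_per_year working days per year used to convert annual
#'   wages to daily wages.
#' @return a `brca_productivity_params`.
#' @export
productivity_params <- function(absence_days = 110,
                                hours_reduction = 0.15,
                                departure_fraction = 0.10,
                                workdays_per_year = 260) {
  stopifnot(absence_days >= 0, workdays_per_year > 0)
  if (hours_reduction < 0 || hours_reduction > 1 ||
      departure_fraction < 0 || departure_fraction > 1) {
    stop("disability fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(absence_days = absence_days,
                 hours_reduction = hours_reduction,
                 departure_fraction = departure_fraction,
                 workdays_per_year = workdays_per_year),
            class = "brca_productivity_params")
}

#' Bundle all model inputs
#'
#' @param profile a `brca_country_profile`.
#' @param probs a `brca_probability_table`.
#' @param utilities a `brca_utility_table`.
#' @param costs a `brca_cost_schedule`.
#' @param life_table a `brca_life_table` covering the modelled age span.
#' @param incidence an incidence schedule (see [read_incidence()]).
#' @param survival a `brca_survival_model`.
#' @param productivity a `brca_productivity_params`.
#' @return a `brca_model_params` list bundle.
#' @export
model_params <- function(profile, probs, utilities, costs, life_table,
                         incidence, survival, productivity) {
  validate_incidence(incidence)
  span <- profile$start_age:(profile$start_age + profile$cycles - 1)
  lt_qx(life_table, span)   # errors if coverage incomplete
  structure(list(profile = profile, probs = probs, utilities = utilities,
                 costs = costs, life_table = life_table,
                 incidence = incidence, survival = survival,
                 productivity = productivity),
            class = "brca_model_params")
}

#' @export
print.brca_model_params <- function(x, ...) {
  cat("<brca_model_params> country:", x$profile$name,
      "| cycles:", x$profile$cycles,
      "| BRCA test cost:", x$costs$brca_test, "\n")
  invisible(x)
}

#' Fit an uncertainty distribution by method of moments
#'
#' Maps a point estimate plus either a standard deviation or a 95% interval
#' onto the distribution family used by the probabilistic sensitivity
#' analysis: Beta for probabilities, Gamma for costs, log-normal for
#' utilities. When an interval `(low, high)` is supplied the standard
#' deviation is taken as `(high - low) / (2 * 1.96)`, i.e. the interval is
#' read as a normal-theory 95% CI on the given scale. A zero standard
#' deviation (or a degenerate interval) yields a point mass.
#'
#' @param point the mean.
#' @param family `"beta"`, `"gamma"` or `"lognormal"`.
#' @param low,high optional 95% interval bounds.
#' @param sd optional standard deviation (overrides the interval).
#' @return a `brca_dist_spec` with elements `family`, `mean`, `sd` and the
#'   fitted shape parameters.
#' @export
#' @examples
#' d <- fit_uncertainty_distribution(0.47, "beta", low = 0.34, high = 0.56)
#' d$sd   # about 0.056
fit_uncertainty_distribution <- function(point,
                                         family = c("beta", "gamma", "lognormal"),
                                         low = NULL, high = NULL, sd = NULL) {
  family <- match.arg(family)
  if (is.null(sd)) {
    if (is.null(low) || is.null(high)) {
      stop("supply either sd or an interval (low, high)", call. = FALSE)
    }
    if (high < low) stop("interval must have low <= high", call. = FALSE)
    sd <- (high - low) / (2 * 1.96)
  }
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  if (family == "beta" && (point < 0 || point > 1)) {
    stop("beta family requires a point value in [0, 1]", call. = FALSE)
  }
  if (family %in% c("gamma", "lognormal") && point < 0) {
    stop(family, " family requires a non-negative point value", call. = FALSE)
  }
  if (sd == 0) {
    return(structure(list(family = "point", mean = point, sd = 0),
                     class = "brca_dist_spec"))
  }
  pars <- switch(family,
    beta = {
      if (point <= 0 || point >= 1) {
        stop("beta family with sd > 0 requires a point value in (0, 1)",
             call. = FALSE)
      }
      v <- sd^2
      if (v >= point * (1 - point)) {
        stop("sd too large for a beta distribution with this mean",
             call. = FALSE)
      }
      nu <- point * (1 - point) / v - 1
      list(shape1 = point * nu, shape2 = (1 - point) * nu)
    },
    gamma = list(shape = point^2 / sd^2, rate = point / sd^2),
    lognormal = {
      sigma2 <- log(1 + sd^2 / point^2)
      list(meanlog = log(point) - sigma2 / 2, sdlog = sqrt(sigma2))
    }
  )
  structure(c(list(family = family, mean = point, sd = sd), pars),
            class = "brca_dist_spec")
}

#' Draw from a fitted uncertainty distribution
#'
#' Log-normal draws intended for utilities can be truncated at 1 by
#' resampling (`upper = 1`), since a utility cannot exceed perfect health.
#'
#' @param spec a `brca_dist_spec`.
#' @param n number of draws.
#' @param upper optional upper truncation bound enforced by resampling.
#' @return numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n, upper = NULL) {
  draw <- function(m) {
    switch(spec$family,
      point = rep(spec$mean, m),
      beta = stats::rbeta(m, spec$shape1, spec$shape2),
      gamma = stats::rgamma(m, shape = spec$shape, rate = spec$rate),
      lognormal = stats::rlnorm(m, spec$meanlog, spec$sdlog)
    )
  }
  x <- draw(n)
  if (!is.null(upper)) {
    for (i in 1:100) {
      bad <- x > upper
      if (!any(bad)) break
      x[bad] <- draw(sum(bad))
    }
    x <- pmin(x, upper)
  }
  x
}
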