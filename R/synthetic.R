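#' Synthetic input specification
#'
#' Shape parameters for the synthetic emulators of the model's external data
#' sources: a Gompertz all-cause mortality curve, log-normal-shaped (in age)
#' unimodal cancer incidence curves with a carrier excess component, a humped
#' age-earnings curve, and country cost magnitudes. The shapes are
#' configuration, not claims about the real registry data; calibration
#' targets (carrier cumulative risks, life expectancy) are the quantities the
#' analysis actually depends on.
#'
#' @param seed integer seed recorded with generated bundles.
#' @param gompertz_slope exponential age slope of the mortality hazard.
#' @param carrier_bc_risk_to_80,carrier_oc_risk_to_80 cumulative-risk
#'   calibration targets for carriers at age 80 (breast cancer 0.70, inside
#'   the published 69-72% band; ovarian cancer 0.305, the midpoint of the
#'   published 17-44% band).
#' @param bc_peak_age,bc_width,oc_peak_age,oc_width sporadic incidence curve
#'   shapes (log-age scale widths).
#' @param carrier_bc_peak_age,carrier_bc_width,carrier_oc_peak_age,carrier_oc_width
#'   shapes of the carrier excess-incidence component (earlier onset).
#' @param max_age last age generated.
#' @return a `brca_synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           gompertz_slope = 0.085,
                           carrier_bc_risk_to_80 = 0.70,
                           carrier_oc_risk_to_80 = 0.305,
                           bc_peak_age = 62, bc_width = 0.28,
                           oc_peak_age = 63, oc_width = 0.26,
                           carrier_bc_peak_age = 50, carrier_bc_width = 0.22,
                           carrier_oc_peak_age = 58, carrier_oc_width = 0.18,
                           max_age = 110) {
  structure(list(seed = as.integer(seed),
                 gompertz_slope = gompertz_slope,
                 carrier_bc_risk_to_80 = carrier_bc_risk_to_80,
                 carrier_oc_risk_to_80 = carrier_oc_risk_to_80,
                 bc_peak_age = bc_peak_age, bc_width = bc_width,
                 oc_peak_age = oc_peak_age, oc_width = oc_width,
                 carrier_bc_peak_age = carrier_bc_peak_age,
                 carrier_bc_width = carrier_bc_width,
                 carrier_oc_peak_age = carrier_oc_peak_age,
                 carrier_oc_width = carrier_oc_width,
                 max_age = max_age),
            class = "brca_synthetic_spec")
}

# Synthetic country anchors: sporadic cumulative-risk targets chosen so the
# per-country general-population cancer burden is of realistic magnitude
# (higher in Europe/Americas than in China/India), wage levels (annual gross
# earnings at the curve peak, 2016 USD PPP) and a cost scale factor applied
# to the baseline cost schedule. Five-year survival fractions are
# CONCORD-like synthetic values.
synthetic_country_anchors <- function() {
  data.frame(
    name = c("UK", "USA", "Netherlands", "China", "Brazil", "India"),
    sporadic_bc_risk = c(0.115, 0.109, 0.114, 0.0295, 0.0689, 0.0160),
    sporadic_oc_risk = c(0.0163, 0.0104, 0.0114, 0.0042, 0.0058, 0.0032),
    wage_level = c(42000, 52000, 48000, 15000, 14000, 6000),
    cost_factor = c(1.0, 1.6, 0.95, 0.35, 0.40, 0.20),
    bc_5yr = c(0.86, 0.90, 0.87, 0.83, 0.75, 0.66),
    oc_5yr = c(0.36, 0.41, 0.41, 0.39, 0.33, 0.29),
    target_le = c(83, 82, 83, 78, 79, 68),
    stringsAsFactors = FALSE
  )
}

#' Life expectancy implied by a life table
#'
#' Curtate expectation plus a half-year correction:
#' \eqn{LE(a_0) = a_0 + 1/2 + \sum_{t \ge 1} S(t)} where \eqn{S(t)} is the
#' probability of surviving `t` whole years from `start_age`. Used both as
#' the calibration objective of [make_life_table()] and as its independent
#' check (simple summation over the table).
#'
#' @param lt a `brca_life_table`.
#' @param start_age age from which expectation is taken.
#' @return expected age at death, in years.
#' @export
life_expectancy <- function(lt, start_age = 30) {
  ages <- start_age:max(lt$age)
  q <- lt_qx(lt, ages)
  surv <- cumprod(1 - q)
  start_age + 0.5 + sum(surv)
}

#' Generate a calibrated synthetic life table
#'
#' Gompertz mortality \eqn{h(a) = b\,e^{c(a-30)}} with the baseline `b`
#' calibrated by root finding so the life expectancy at age 30 matches
#' `target_life_expectancy` (expressed as expected age at death) within 0.5
#' years. Deterministic for a fixed spec.
#'
#' @param spec a `brca_synthetic_spec`.
#' @param target_life_expectancy expected age at death, between 60 and 90.
#' @return a `brca_life_table` covering ages 30 to `spec$max_age`.
#' @export
#' @examples
#' lt <- make_life_table(synthetic_spec(), 83)
#' life_expectancy(lt)   # ~83
make_life_table <- function(spec, target_life_expectancy) {
  if (target_life_expectancy < 60 || target_life_expectancy > 90) {
    stop("target life expectancy must lie between 60 and 90", call. = FALSE)
  }
  ages <- 30:spec$max_age
  build <- function(log_b) {
    h <- exp(log_b) * exp(spec$gompertz_slope * (ages - 30))
    life_table(ages, pmin(1, 1 - exp(-h)))
  }
  obj <- function(log_b) life_expectancy(build(log_b)) - target_life_expectancy
  lo <- -14; hi <- -2
  if (obj(lo) < 0 || obj(hi) > 0) {
    stop("life-table calibration error: target unattainable with this spec",
         call. = FALSE)
  }
  root <- stats::uniroot(obj, c(lo, hi), tol = 1e-10)
  lt <- build(root$root)
  if (abs(life_expectancy(lt) - target_life_expectancy) > 0.5) {
    stop("life-table calibration error: did not converge", call. = FALSE)
  }
  lt
}

# Unimodal log-normal-shaped curve in age, height 1 at the peak.
age_curve <- function(ages, peak, width) {
  exp(-(log(ages / peak))^2 / (2 * width^2))
}

#' Cumulative risk implied by an annual incidence schedule
#'
#' Product-limit computation: \eqn{1 - \prod_a (1 - i(a))} over
#' `from <= age < to`, ignoring competing mortality (the convention used for
#' published carrier risk-to-age figures).
#'
#' @param incidence data frame with `age` and `incidence` columns.
#' @param from,to age window.
#' @return cumulative probability of diagnosis.
#' @export
cumulative_risk <- function(incidence, from = 30, to = 80) {
  sel <- incidence$age >= from & incidence$age < to
  1 - prod(1 - incidence$incidence[sel])
}

#' Generate a calibrated synthetic incidence schedule
#'
#' Sporadic incidence is a unimodal log-normal-shaped curve whose height is
#' calibrated so cumulative risk from 30 to 80 hits the target; carrier
#' incidence adds an earlier-peaking excess component on top of the sporadic
#' curve (so carrier incidence exceeds sporadic incidence at every age by
#' construction), calibrated to the carrier cumulative-risk target.
#'
#' @param spec a `brca_synthetic_spec`.
#' @param group `"sporadic"` or `"carrier"`.
#' @param cancer `"bc"` or `"oc"`.
#' @param sporadic_target cumulative sporadic risk to 80 (a country anchor).
#' @return data frame `age`, `group`, `cancer`, `incidence`.
#' @export
make_incidence <- function(spec, group = c("sporadic", "carrier"),
                           cancer = c("bc", "oc"),
                           sporadic_target = 0.115) {
  group <- match.arg(group)
  cancer <- match.arg(cancer)
  ages <- 30:spec$max_age
  shp <- if (cancer == "bc") {
    list(peak = spec$bc_peak_age, width = spec$bc_width,
         cpeak = spec$carrier_bc_peak_age, cwidth = spec$carrier_bc_width,
         ctarget = spec$carrier_bc_risk_to_80)
  } else {
    list(peak = spec$oc_peak_age, width = spec$oc_width,
         cpeak = spec$carrier_oc_peak_age, cwidth = spec$carrier_oc_width,
         ctarget = spec$carrier_oc_risk_to_80)
  }
  calibrate_height <- function(base, shape, target) {
    # solves cumulative_risk(base + k * shape) = target for k >= 0
    if (target <= 0) return(0)
    risk <- function(logk) {
      inc <- pmin(0.999, base + exp(logk) * shape)
      1 - prod((1 - inc)[ages >= 30 & ages < 80]) - target
    }
    stats::uniroot(risk, c(-20, 2), tol = 1e-12)$root
  }
  base_shape <- age_curve(ages, shp$peak, shp$width)
  sporadic <- if (sporadic_target <= 0) {
    rep(0, length(ages))
  } else {
    exp(calibrate_height(0, base_shape, sporadic_target)) * base_shape
  }
  inc <- if (group == "sporadic") {
    sporadic
  } else {
    excess_shape <- age_curve(ages, shp$cpeak, shp$cwidth)
    if (shp$ctarget <= 0) {
      sporadic
    } else {
      k <- exp(calibrate_height(sporadic, excess_shape, shp$ctarget))
      pmin(0.999, sporadic + k * excess_shape)
    }
  }
  data.frame(age = ages, group = group, cancer = cancer, incidence = inc,
             stringsAsFactors = FALSE)
}

make_incidence_set <- function(spec, anchors) {
  do.call(rbind, list(
    make_incidence(spec, "sporadic", "bc", anchors$sporadic_bc_risk),
    make_incidence(spec, "carrier", "bc", anchors$sporadic_bc_risk),
    make_incidence(spec, "sporadic", "oc", anchors$sporadic_oc_risk),
    make_incidence(spec, "carrier", "oc", anchors$sporadic_oc_risk)
  ))
}

#' Synthetic age-earnings curve
#'
#' A humped gross-earnings profile peaking in the late forties, scaled to the
#' country wage level. Placeholder for published wage schedules.
#'
#' @param spec a `brca_synthetic_spec`.
#' @param country country name (sets the wage level) or a numeric wage level.
#' @return data frame `age`, `wage` over ages 16 to `spec$max_age` (zero
#'   beyond the table is implied by lookup).
#' @export
make_wage_schedule <- function(spec, country = "UK") {
  level <- if (is.numeric(country)) {
    country
  } else {
    a <- synthetic_country_anchors()
    row <- a[a$name == country, ]
    if (nrow(row) == 0) stop("unknown country: ", country, call. = FALSE)
    row$wage_level
  }
  ages <- 16:spec$max_age
  mult <- exp(-((ages - 47) / 28)^2)
  data.frame(age = ages, wage = level * mult)
}

#' Assemble a complete synthetic country fixture
#'
#' Builds an internally consistent input bundle for one of the six modelled
#' countries: profile constants, a life table calibrated to the country's
#' life expectancy (start age + cycle count), calibrated incidence schedules,
#' a cost schedule scaled to the country's price level, synthetic five-year
#' survival, and productivity-loss parameters. Deterministic given the seed.
#'
#' @param name country name.
#' @param seed integer seed stored in the bundle.
#' @return a `brca_model_params` bundle.
#' @export
#' @examples
#' uk <- make_country_fixture("UK")
#' uk$profile$cycles
make_country_fixture <- function(name, seed = 1L) {
  spec <- synthetic_spec(seed = seed)
  anchors <- synthetic_country_anchors()
  row <- anchors[anchors$name == name, ]
  if (nrow(row) == 0) {
    stop("unknown country: ", name, " (known: ",
         paste(anchors$name, collapse = ", "), ")", call. = FALSE)
  }
  profile <- load_country_profile(name,
                                  wage_schedule = make_wage_schedule(spec, name))
  base <- cost_schedule()
  costs <- cost_schedule(
    brca_test = base$brca_test,  # standard international test price, unscaled
    pretest_counselling = base$pretest_counselling * row$cost_factor,
    posttest_counselling_carrier = base$posttest_counselling_carrier * row$cost_factor,
    posttest_counselling_vus = base$posttest_counselling_vus * row$cost_factor,
    rrm_procedure = base$rrm_procedure * row$cost_factor,
    rrso_procedure = base$rrso_procedure * row$cost_factor,
    hrt_annual = base$hrt_annual * row$cost_factor,
    bone_monitoring_annual = base$bone_monitoring_annual * row$cost_factor,
    chd_treatment = base$chd_treatment * row$cost_factor,
    bc_treatment_stage = base$bc_treatment_stage * row$cost_factor,
    oc_treatment_stage = base$oc_treatment_stage * row$cost_factor,
    screening_annual = base$screening_annual * row$cost_factor,
    chemoprevention_course = base$chemoprevention_course * row$cost_factor
  )
  params <- model_params(
    profile = profile,
    probs = probability_table(),
    utilities = utility_table(),
    costs = costs,
    life_table = make_life_table(spec, row$target_le),
    incidence = make_incidence_set(spec, row),
    survival = survival_model(bc_5yr = row$bc_5yr, oc_5yr = row$oc_5yr),
    productivity = productivity_params()
  )
  attr(params, "seed") <- as.integer(seed)
  attr(params, "synthetic") <- TRUE
  params
}
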