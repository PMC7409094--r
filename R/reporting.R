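# Report generation mirroring the published table layouts, plus manifest
# logging and figure helpers.

#' Run manifest
#'
#' @param country,perspective,discount_mode,seed,scenario run identifiers.
#' @param config paths or labels of configuration inputs.
#' @return list recording the inputs, package version and timestamp.
#' @export
run_manifest <- function(country = NA, perspective = NA, discount_mode = NA,
                         seed = NA, scenario = NA, config = list()) {
  list(package = "brcacea",
       version = as.character(utils::packageVersion("brcacea")),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
       country = country, perspective = perspective,
       discount_mode = discount_mode, seed = seed, scenario = scenario,
       config = config)
}

#' Base-case report (baseline-analysis table layout)
#'
#' One row per arm with discounted life-years, QALYs and costs from both
#' perspectives, followed by the ICERs, classifications, WTP thresholds and
#' the life-expectancy gain in days (reported at one decimal).
#'
#' @param params a `brca_model_params` bundle, or a country name (a synthetic
#'   fixture is generated).
#' @param discount_mode `"who"` or `"local"`.
#' @return list with `arms` (data frame), `icer` (data frame) and `manifest`.
#' @export
report_base_case <- function(params, discount_mode = "who") {
  if (is.character(params)) params <- make_country_fixture(params)
  ev <- evaluate_strategies(params, discount_mode)
  arms <- data.frame(
    arm = c("population", "fh"),
    ly = c(ev$pop$ly, ev$fh$ly),
    qaly = c(ev$pop$qaly, ev$fh$qaly),
    cost_payer = c(ev$pop$cost_payer, ev$fh$cost_payer),
    cost_societal = c(ev$pop$cost_societal, ev$fh$cost_societal)
  )
  prof <- params$profile
  icer <- data.frame(
    perspective = c("payer", "societal"),
    icer = c(ev$icer_payer$icer, ev$icer_societal$icer),
    classification = c(ev$icer_payer$classification,
                       ev$icer_societal$classification),
    wtp_1gdp = prof$wtp_1gdp, wtp_3gdp = prof$wtp_3gdp,
    wtp_guideline_low = prof$wtp_guideline_low,
    wtp_guideline_high = prof$wtp_guideline_high,
    life_days_gained = round(ev$life_days_gained, 1)
  )
  list(arms = arms, icer = icer,
       manifest = run_manifest(country = prof$name,
                               discount_mode = discount_mode))
}

#' Population-impact report (lifetime-impact table layout)
#'
#' Per-million event counts in each arm, their difference, and the actual
#' national counts from [scale_impact()], for breast-cancer cases,
#' ovarian-cancer cases, cause-specific deaths and excess coronary
#' heart-disease deaths.
#'
#' @param params a `brca_model_params` bundle or country name.
#' @param discount_mode discounting mode (event counts are undiscounted; the
#'   mode is recorded for the manifest only).
#' @return list with `impact` (data frame) and `manifest`.
#' @export
report_impact <- function(params, discount_mode = "who") {
  if (is.character(params)) params <- make_country_fixture(params)
  ev <- evaluate_strategies(params, discount_mode)
  pm_pop <- ev$pop$per_million
  pm_fh <- ev$fh$per_million
  pop <- params$profile$female_population_over_30
  sc <- scale_impact(pm_pop, pm_fh, pop)
  impact <- data.frame(
    event = c("BC cases", "OC cases", "BC deaths", "OC deaths",
              "Excess CHD deaths"),
    per_million_population_testing = round_half_away(pm_pop),
    per_million_fh_testing = round_half_away(pm_fh),
    difference_per_million = round_half_away(sc$difference_per_million),
    actual = round_half_away(sc$difference_per_million * pop / 1e6)
  )
  list(impact = impact,
       manifest = run_manifest(country = params$profile$name,
                               discount_mode = discount_mode))
}

#' Scenario report (scenario-analysis table layout)
#'
#' @param params a `brca_model_params` bundle or country name.
#' @param scenarios a scenario catalogue ([scenario_catalog()] by default).
#' @param discount_mode discounting mode.
#' @return list with `scenarios` (one row per scenario with both ICERs) and
#'   `manifest`.
#' @export
report_scenarios <- function(params, scenarios = scenario_catalog(),
                             discount_mode = "who") {
  if (is.character(params)) params <- make_country_fixture(params)
  rows <- lapply(names(scenarios), function(nm) {
    ev <- run_scenario(scenarios[[nm]], params, discount_mode)
    data.frame(scenario = nm, label = scenarios[[nm]]$label,
               ly_pop = ev$pop$ly, qaly_pop = ev$pop$qaly,
               cost_payer_pop = ev$pop$cost_payer,
               cost_societal_pop = ev$pop$cost_societal,
               ly_fh = ev$fh$ly, qaly_fh = ev$fh$qaly,
               cost_payer_fh = ev$fh$cost_payer,
               cost_societal_fh = ev$fh$cost_societal,
               icer_payer = ev$icer_payer$icer,
               icer_societal = ev$icer_societal$icer)
  })
  list(scenarios = do.call(rbind, rows),
       manifest = run_manifest(country = params$profile$name,
                               discount_mode = discount_mode))
}

#' PSA report: samples and CEAC export
#'
#' @param params a `brca_model_params` bundle or country name.
#' @param n,seed simulation size and master seed.
#' @param wtp_grid WTP grid for the acceptability curves.
#' @param discount_mode discounting mode.
#' @return list with `samples`, `ceac_payer`, `ceac_societal`, `manifest`.
#' @export
report_psa <- function(params, n = 1000, seed = 1L,
                       wtp_grid = seq(0, 200000, by = 5000),
                       discount_mode = "who") {
  if (is.character(params)) params <- make_country_fixture(params)
  samples <- run_psa(n, seed, params, discount_mode)
  list(samples = samples,
       ceac_payer = ceac(samples, wtp_grid, "payer"),
       ceac_societal = ceac(samples, wtp_grid, "societal"),
       manifest = run_manifest(country = params$profile$name, seed = seed,
                               discount_mode = discount_mode))
}

#' Test-cost threshold report
#'
#' @param params a `brca_model_params` bundle or country name.
#' @param wtp WTP threshold (country 3x GDP by default).
#' @param perspective,discount_mode analysis settings.
#' @return list with `threshold` (from [threshold_test_cost()]) and
#'   `manifest`.
#' @export
report_threshold <- function(params, wtp = NULL,
                             perspective = c("societal", "payer"),
                             discount_mode = "who") {
  perspective <- match.arg(perspective)
  if (is.character(params)) params <- make_country_fixture(params)
  if (is.null(wtp)) wtp <- params$profile$wtp_3gdp
  th <- threshold_test_cost(wtp, params, perspective, discount_mode)
  list(threshold = th,
       manifest = run_manifest(country = params$profile$name,
                               perspective = perspective,
                               discount_mode = discount_mode))
}

#' Write a report data frame to CSV
#'
#' @param x a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve a `brca_ceac_curve` (or named list of them to overlay).
#' @return a ggplot object: proportion of simulations cost-effective
#'   against the willingness-to-pay threshold.
#' @export
plot_ceac <- function(curve) {
  if (is.data.frame(curve)) curve <- list(CEAC = curve)
  d <- do.call(rbind, lapply(names(curve), function(nm) {
    cbind(as.data.frame(curve[[nm]]), series = nm)
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wtp,
                                  y = .data$proportion_cost_effective,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay threshold ($/QALY)",
                  y = "Proportion of simulations cost-effective",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ICER against BRCA test cost
#'
#' @param params a `brca_model_params` bundle or country name.
#' @param costs grid of test costs ($).
#' @param perspective,discount_mode analysis settings.
#' @return a ggplot object (x: test cost in $, y: ICER per QALY).
#' @export
plot_icer_vs_test_cost <- function(params, costs = seq(50, 400, by = 25),
                                   perspective = c("societal", "payer"),
                                   discount_mode = "who") {
  perspective <- match.arg(perspective)
  if (is.character(params)) params <- make_country_fixture(params)
  icers <- vapply(costs, function(cc) {
    ev <- evaluate_strategies(set_model_param(params, "brca_test", cc),
                              discount_mode)
    if (perspective == "payer") ev$icer_payer$icer else ev$icer_societal$icer
  }, numeric(1))
  d <- data.frame(test_cost = costs, icer = icers)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$test_cost, y = .data$icer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "BRCA testing cost ($)", y = "ICER ($/QALY)") +
    ggplot2::theme_minimal()
}
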