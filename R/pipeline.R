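#' Evaluate both testing strategies under one parameter bundle
#'
#' Runs the full deterministic pipeline: builds the two arm specifications,
#' propagates both cohort traces through the shared transition matrices,
#' accrues discounted outcomes, and computes payer and societal ICERs.
#'
#' @param params a `brca_model_params` bundle (e.g. from
#'   [make_country_fixture()]).
#' @param discount_mode `"who"` (3%/3%) or `"local"` (country-recommended
#'   rates).
#' @param fh_split passed to [make_fh_arm()].
#' @return a `brca_evaluation`: list with the two `brca_strategy_result`s
#'   (`pop`, `fh`), `icer_payer`, `icer_societal`, and `life_days_gained`.
#' @export
#' @examples
#' \donttest{
#' ev <- evaluate_strategies(make_country_fixture("UK"))
#' ev$icer_payer$icer
#' }
evaluate_strategies <- function(params, discount_mode = c("who", "local"),
                                fh_split = "consistent") {
  discount_mode <- match.arg(discount_mode)
  rates <- discount_rates(params$profile, discount_mode)
  matrices <- build_matrix_set(params)
  arm_pop <- make_population_arm(params)
  arm_fh <- make_fh_arm(params, split = fh_split)
  ct_pop <- run_cohort(arm_pop, params, matrices)
  ct_fh <- run_cohort(arm_fh, params, matrices)
  res_pop <- accrue(ct_pop, arm_pop, params, rates)
  res_fh <- accrue(ct_fh, arm_fh, params, rates)
  structure(list(
    country = params$profile$name,
    discount_mode = discount_mode,
    pop = res_pop, fh = res_fh,
    icer_payer = compute_icer(res_pop, res_fh, "payer", params$profile),
    icer_societal = compute_icer(res_pop, res_fh, "societal", params$profile),
    life_days_gained = life_days_gained(res_pop, res_fh)
  ), class = "brca_evaluation")
}

#' @export
print.brca_evaluation <- function(x, ...) {
  cat("<brca_evaluation>", x$country, "(discounting:", x$discount_mode, ")\n")
  cat(sprintf("  payer ICER:    $%8.0f/QALY (%s)\n",
              x$icer_payer$icer, x$icer_payer$classification))
  cat(sprintf("  societal ICER: $%8.0f/QALY (%s)\n",
              x$icer_societal$icer, x$icer_societal$classification))
  cat(sprintf("  life expectancy gained: %.1f days\n", x$life_days_gained))
  invisible(x)
}
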