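# Comparative outcomes: ICER, cost-effectiveness classification,
# life-expectancy gain and population-impact scaling.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Incremental cost-effectiveness ratio between the two arms
#'
#' `ICER = (Cost_pop - Cost_fh) / (Effect_pop - Effect_fh)` on QALYs, with
#' the classification read against the country's willingness-to-pay
#' thresholds: cost-saving if the intervention costs less and yields more
#' QALYs; highly cost-effective if the ICER is at or below 1x GDP per
#' capita; cost-effective at or below 3x GDP per capita (thresholds are
#' inclusive); dominated if it costs more and yields fewer QALYs. A zero
#' QALY difference leaves the ICER undefined and classifies by the sign of
#' the cost difference.
#'
#' @param result_pop,result_fh `brca_strategy_result`s for the
#'   population-testing and family-history arms computed under identical
#'   parameters.
#' @param perspective `"payer"` or `"societal"`.
#' @param profile a `brca_country_profile` supplying WTP thresholds.
#' @param wtp optional explicit WTP threshold overriding the 3x GDP value
#'   for the recorded `wtp_used`.
#' @return a `brca_icer_result` with `delta_cost`, `delta_effect`, `icer`,
#'   `classification`, `wtp_used`.
#' @export
compute_icer <- function(result_pop, result_fh,
                         perspective = c("societal", "payer"),
                         profile = NULL, wtp = NULL) {
  perspective <- match.arg(perspective)
  if (!identical(result_pop$rates, result_fh$rates)) {
    stop("results were computed under different discount rates", call. = FALSE)
  }
  dc <- strategy_cost(result_pop, perspective) -
    strategy_cost(result_fh, perspective)
  de <- result_pop$qaly - result_fh$qaly
  wtp1 <- if (!is.null(profile)) profile$wtp_1gdp else NA_real_
  wtp3 <- if (!is.null(profile)) profile$wtp_3gdp else NA_real_
  wtp_used <- if (!is.null(wtp)) wtp else wtp3
  if (de == 0) {
    icer <- NA_real_
    classification <- if (dc > 0) "dominated" else "cost-saving"
  } else {
    icer <- dc / de
    classification <- if (de > 0 && dc < 0) {
      "cost-saving"
    } else if (de < 0 && dc > 0) {
      "dominated"
    } else if (!is.na(wtp1) && icer <= wtp1 && de > 0) {
      "highly-cost-effective"
    } else if (!is.na(wtp_used) && icer <= wtp_used && de > 0) {
      "cost-effective"
    } else {
      "not-cost-effective"
    }
  }
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 delta_ly = result_pop$ly - result_fh$ly,
                 classification = classification,
                 perspective = perspective, wtp_used = wtp_used),
            class = "brca_icer_result")
}

#' @export
print.brca_icer_result <- function(x, ...) {
  cat(sprintf("<brca_icer_result> %s: ICER $%.0f/QALY (dC $%.2f, dQALY %.6f) -> %s\n",
              x$perspective, x$icer, x$delta_cost, x$delta_effect,
              x$classification))
  invisible(x)
}

#' Life expectancy gained, in days
#'
#' @param result_pop,result_fh paired `brca_strategy_result`s.
#' @return `(LY_pop - LY_fh) * 365.25` (days; callers report at one
#'   decimal).
#' @export
#' @examples
#' # a 0.01 discounted-life-year difference is about 3.65 days
life_days_gained <- function(result_pop, result_fh) {
  (result_pop$ly - result_fh$ly) * 365.25
}

#' Scale per-million event counts to a national population
#'
#' @param per_million_pop,per_million_fh per-million event counts in the two
#'   arms (vectors allowed).
#' @param population national female population aged over 30.
#' @return list with `difference_per_million` (population arm minus
#'   family-history arm) and `actual` (difference scaled by
#'   `population / 1e6`, rounded half away from zero to integers).
#' @export
#' @examples
#' scale_impact(112014, 114666, 21760299)   # UK breast-cancer row
scale_impact <- function(per_million_pop, per_million_fh, population) {
  if (population <= 0) stop("population must be positive", call. = FALSE)
  population <- as.numeric(population)   # avoid integer overflow
  diff <- as.numeric(per_million_pop) - as.numeric(per_million_fh)
  list(difference_per_million = diff,
       actual = round_half_away(diff * population / 1e6))
}
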