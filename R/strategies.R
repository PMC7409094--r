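# Comparator arm specifications.
#
# Both arms share the engine's state space; an arm spec fixes the initial
# distribution at age 30 and the one-off cycle-0 testing-pathway costs
# (pre-test counselling and the test for all testers, post-test counselling
# for detected carriers and for the VUS fraction of testers).

new_arm_spec <- function(label, tested_fraction, detected_fraction,
                         undetected_fraction, params) {
  S <- build_state_space()
  init <- stats::setNames(numeric(length(S)), S)
  init["carrier_none"] <- detected_fraction
  init["carrier_undetected"] <- undetected_fraction
  init["healthy_noncarrier"] <- 1 - detected_fraction - undetected_fraction
  cs <- params$costs
  vus <- prob(params$probs, "vus_prevalence")
  components <- c(
    testing = tested_fraction * cs$brca_test,
    pretest_counselling = tested_fraction * cs$pretest_counselling,
    posttest_carrier = detected_fraction * cs$posttest_counselling_carrier,
    posttest_vus = tested_fraction * vus * cs$posttest_counselling_vus
  )
  structure(list(label = label,
                 tested_fraction = tested_fraction,
                 detected_fraction = detected_fraction,
                 undetected_fraction = undetected_fraction,
                 init = init,
                 cycle0_cost = sum(components),
                 cycle0_components = components),
            class = "brca_arm_spec")
}

#' Population-testing arm
#'
#' All women aged 30 and over are offered testing; a fraction `test_uptake`
#' accepts. Detected carriers (`p1 * test_uptake`) enter the detected
#' untreated state; carriers who declined testing remain undetected and are
#' treated identically to undetected carriers in the comparator arm.
#'
#' @param params a `brca_model_params` bundle.
#' @return a `brca_arm_spec`.
#' @export
#' @examples
#' arm <- make_population_arm(make_country_fixture("UK"))
#' arm$tested_fraction   # 0.70
make_population_arm <- function(params) {
  pr <- params$probs
  tested <- prob(pr, "test_uptake")
  p1 <- prob(pr, "p1")
  detected <- p1 * tested
  new_arm_spec("population", tested, detected, p1 - detected, params)
}

#' Clinical-criteria / family-history testing arm
#'
#' Only women with a qualifying family history (`p4`) are offered testing;
#' carriers among them (`p5`) who accept testing (`test_uptake`) are
#' detected. All remaining carriers stay undetected and receive no
#' risk-reducing interventions.
#'
#' @param params a `brca_model_params` bundle.
#' @param split `"consistent"` (default) forces detected + undetected carrier
#'   mass to equal the population prevalence `p1`; `"p6"` instead builds the
#'   undetected mass from the family-history-negative prevalence `p6` plus
#'   untested/undetected FH-positive carriers (the two are numerically close
#'   because `(1-p4)*p6 + p4*p5` is consistent with `p1`).
#' @return a `brca_arm_spec`.
#' @export
make_fh_arm <- function(params, split = c("consistent", "p6")) {
  split <- match.arg(split)
  pr <- params$probs
  uptake <- prob(pr, "test_uptake")
  p4 <- prob(pr, "p4"); p5 <- prob(pr, "p5")
  tested <- p4 * uptake
  detected <- p4 * p5 * uptake
  undetected <- if (split == "consistent") {
    prob(pr, "p1") - detected
  } else {
    (1 - p4) * prob(pr, "p6") + p4 * p5 * (1 - uptake)
  }
  if (undetected < 0) {
    stop("inconsistent parameters: detected carriers exceed prevalence",
         call. = FALSE)
  }
  new_arm_spec("fh", tested, detected, undetected, params)
}

#' @export
print.brca_arm_spec <- function(x, ...) {
  cat("<brca_arm_spec>", x$label,
      sprintf("| tested %.4f | carriers detected %.6f / undetected %.6f\n",
              x$tested_fraction, x$detected_fraction, x$undetected_fraction))
  cat(sprintf("  cycle-0 testing-pathway cost: $%.2f per woman\n",
              x$cycle0_cost))
  invisible(x)
}
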