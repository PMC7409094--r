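# State-transition engine.
#
# One shared state space serves both comparator arms; the family-history arm
# simply places more carriers in the undetected state. Healthy carrier states
# carry an intervention label (none / chemoprevention / RRM / RRSO +- HRT /
# RRM+RRSO +- HRT); cancer states progress through five post-diagnosis years
# and a long-term survivor state; the four death states are absorbing.

healthy_states <- function() {
  c("healthy_noncarrier", "carrier_undetected",
    "carrier_none", "carrier_chemoprev", "carrier_rrm",
    "carrier_rrso_hrt", "carrier_rrso_nohrt",
    "carrier_rrm_rrso_hrt", "carrier_rrm_rrso_nohrt")
}

cancer_groups <- function() c("brca_bc", "brca_oc", "sporadic_bc", "sporadic_oc")

#' Build the shared model state space
#'
#' @param arm `"population"` or `"fh"`; both arms share one label set (the
#'   arms differ only in their initial distribution and testing costs).
#' @return character vector of state labels.
#' @export
#' @examples
#' length(build_state_space())   # 37
build_state_space <- function(arm = c("population", "fh")) {
  match.arg(arm)
  cancer <- as.vector(t(outer(cancer_groups(), c(paste0("y", 1:5), "survivor"),
                              paste, sep = "_")))
  c(healthy_states(), cancer,
    "death_bc", "death_oc", "death_chd", "death_other")
}

# index helpers over the fixed state ordering
state_index <- function(labels) match(labels, build_state_space())

death_states <- function() c("death_bc", "death_oc", "death_chd", "death_other")

#' Intervention effect on carrier cancer incidence
#'
#' Multiplier applied to baseline carrier incidence in a given healthy
#' intervention state: RRSO reduces ovarian-cancer risk by `p3` (multiplier
#' `1 - p3`); RRM alone reduces breast-cancer risk by `p7`; RRM with RRSO by
#' `p10`; RRSO alone applies the hazard ratio `p9` to breast-cancer risk;
#' chemoprevention applies the hazard ratio `p14`. Hazard ratios are applied
#' directly to annual probabilities (valid for small annual risks).
#'
#' @param intervention_state a healthy-state label.
#' @param cancer `"bc"` or `"oc"`.
#' @param age current age (part of the operation contract; the multipliers
#'   themselves are age-constant).
#' @param probs a `brca_probability_table`.
#' @return a non-negative multiplier.
#' @export
#' @examples
#' carrier_hazard_modifier("carrier_rrso_hrt", "oc", 45, probability_table())
carrier_hazard_modifier <- function(intervention_state, cancer, age, probs) {
  if (!intervention_state %in% healthy_states()) {
    stop("unknown intervention state: ", intervention_state, call. = FALSE)
  }
  stopifnot(cancer %in% c("bc", "oc"))
  rrso <- grepl("rrso", intervention_state)
  rrm <- grepl("carrier_rrm", intervention_state)
  if (cancer == "oc") {
    if (rrso) 1 - prob(probs, "p3") else 1
  } else {
    if (rrm && rrso) {
      1 - prob(probs, "p10")
    } else if (rrm) {
      1 - prob(probs, "p7")
    } else if (rrso) {
      prob(probs, "p9")
    } else if (intervention_state == "carrier_chemoprev") {
      prob(probs, "p14")
    } else {
      1
    }
  }
}

# Competing-risk combination: annual probabilities are converted to rates,
# summed, converted back, and the total event probability is apportioned
# proportionally to the rates. Order-independent.
combine_competing <- function(p) {
  p <- pmin(p, 1 - 1e-15)
  r <- -log1p(-p)
  total_rate <- sum(r)
  if (total_rate <= 0) return(p * 0)
  (1 - exp(-total_rate)) * r / total_rate
}

#' One-cycle transition matrix at a given age
#'
#' Builds the row-stochastic annual transition matrix over the shared state
#' space: healthy states face competing cancer incidence (intervention
#' multipliers applied for detected carriers), background all-cause
#' mortality, and — in RRSO-without-HRT states — fatal excess coronary heart
#' disease (`p11 * p12` annually); cancer-year states carry a flat annual
#' cancer death probability calibrated so five-cycle survival equals the
#' five-year survival fraction, reverting to background mortality in the
#' survivor state.
#'
#' @param age current age (years).
#' @param arm arm label (matrices are arm-independent; kept for the
#'   interface contract).
#' @param params a `brca_model_params` bundle.
#' @return a `length(S) x length(S)` matrix with unit row sums.
#' @export
transition_matrix <- function(age, arm = "population", params) {
  prof <- params$profile
  if (age < prof$start_age || age >= prof$start_age + prof$cycles) {
    stop("age ", age, " outside the modelled span", call. = FALSE)
  }
  fill_transition_matrix(age, engine_context(params))
}

# Precomputed, age-independent engine quantities: state indices, detected
# carriers' intervention multipliers, incidence and mortality by age.
engine_context <- function(params) {
  S <- build_state_space()
  prof <- params$profile
  ages <- prof$start_age:(prof$start_age + prof$cycles - 1)
  wide <- incidence_lookup(params$incidence)
  ai <- match(ages, wide$age)
  if (anyNA(ai)) {
    stop("incidence schedule does not cover age(s) ",
         paste(ages[is.na(ai)], collapse = ", "), call. = FALSE)
  }
  pr <- params$probs
  hs <- healthy_states()
  detected <- !hs %in% c("healthy_noncarrier", "carrier_undetected")
  bc_mult <- ifelse(detected,
                    vapply(hs, carrier_hazard_modifier, numeric(1),
                           cancer = "bc", age = prof$start_age, probs = pr), 1)
  oc_mult <- ifelse(detected,
                    vapply(hs, carrier_hazard_modifier, numeric(1),
                           cancer = "oc", age = prof$start_age, probs = pr), 1)
  d_cancer <- c(bc = 1 - params$survival$bc_5yr^(1 / 5),
                oc = 1 - params$survival$oc_5yr^(1 / 5))
  list(
    S = S, n = length(S), ages = ages, params = params,
    i_healthy = match(hs, S), carrier = hs != "healthy_noncarrier",
    nohrt = grepl("nohrt", hs),
    bc_mult = bc_mult, oc_mult = oc_mult,
    i_brca_bc1 = match("brca_bc_y1", S), i_spor_bc1 = match("sporadic_bc_y1", S),
    i_brca_oc1 = match("brca_oc_y1", S), i_spor_oc1 = match("sporadic_oc_y1", S),
    i_death = match(death_states(), S),
    i_death_bc = match("death_bc", S), i_death_oc = match("death_oc", S),
    i_death_chd = match("death_chd", S), i_death_other = match("death_other", S),
    cancer_idx = lapply(stats::setNames(cancer_groups(), cancer_groups()),
                        function(g) match(c(paste0(g, "_y", 1:5),
                                            paste0(g, "_survivor")), S)),
    d_cancer = d_cancer,
    chd_fatal = prob(pr, "p11") * prob(pr, "p12"),
    carrier_bc = wide$carrier_bc[ai], sporadic_bc = wide$sporadic_bc[ai],
    carrier_oc = wide$carrier_oc[ai], sporadic_oc = wide$sporadic_oc[ai],
    q_bg = lt_qx(params$life_table, ages)
  )
}

fill_transition_matrix <- function(age, ctx) {
  t <- match(age, ctx$ages)
  n <- ctx$n
  M <- matrix(0, n, n, dimnames = list(ctx$S, ctx$S))
  q_bg <- ctx$q_bg[t]
  prof <- ctx$params$profile
  for (j in seq_along(ctx$i_healthy)) {
    i <- ctx$i_healthy[j]
    bc <- (if (ctx$carrier[j]) ctx$carrier_bc[t] else ctx$sporadic_bc[t]) *
      ctx$bc_mult[j]
    oc <- (if (ctx$carrier[j]) ctx$carrier_oc[t] else ctx$sporadic_oc[t]) *
      ctx$oc_mult[j]
    chd <- if (ctx$nohrt[j] && age >= prof$rrso_age) ctx$chd_fatal else 0
    p <- combine_competing(c(bc, oc, chd, q_bg))
    M[i, if (ctx$carrier[j]) ctx$i_brca_bc1 else ctx$i_spor_bc1] <- p[1]
    M[i, if (ctx$carrier[j]) ctx$i_brca_oc1 else ctx$i_spor_oc1] <- p[2]
    M[i, ctx$i_death_chd] <- p[3]
    M[i, ctx$i_death_other] <- p[4]
    M[i, i] <- 1 - sum(p)
  }
  for (g in cancer_groups()) {
    idx <- ctx$cancer_idx[[g]]
    cn <- if (grepl("_bc", g)) "bc" else "oc"
    i_cdeath <- if (cn == "bc") ctx$i_death_bc else ctx$i_death_oc
    p <- combine_competing(c(ctx$d_cancer[[cn]], q_bg))
    for (k in 1:5) {
      i <- idx[k]
      M[i, i_cdeath] <- p[1]
      M[i, ctx$i_death_other] <- p[2]
      M[i, idx[k + 1]] <- 1 - sum(p)
    }
    i <- idx[6]
    M[i, ctx$i_death_other] <- q_bg
    M[i, i] <- 1 - q_bg
  }
  for (i in ctx$i_death) M[i, i] <- 1
  bad <- abs(rowSums(M) - 1) > 1e-9
  if (any(bad)) {
    stop("internal consistency error: transition rows off unity: ",
         paste(ctx$S[bad], collapse = ", "), call. = FALSE)
  }
  M
}

# Deterministic intervention redistribution applied at the median surgery
# ages: at rrm_age, detected untreated carriers take RRM with p2 and the
# remainder start chemoprevention with p15; at rrso_age, untreated,
# chemoprevention and RRM carriers take RRSO with p8, splitting p13 / 1-p13
# between HRT and no-HRT. Row-stochastic by construction.
redistribution_matrix <- function(age, params) {
  S <- build_state_space()
  R <- diag(length(S))
  dimnames(R) <- list(S, S)
  pr <- params$probs
  if (age == params$profile$rrm_age) {
    p2 <- prob(pr, "p2"); p15 <- prob(pr, "p15")
    i <- match("carrier_none", S)
    R[i, ] <- 0
    R[i, match("carrier_rrm", S)] <- p2
    R[i, match("carrier_chemoprev", S)] <- (1 - p2) * p15
    R[i, i] <- (1 - p2) * (1 - p15)
  }
  if (age == params$profile$rrso_age) {
    p8 <- prob(pr, "p8"); p13 <- prob(pr, "p13")
    split <- function(from, hrt_to, nohrt_to) {
      i <- match(from, S)
      stay <- R[i, i]
      R[i, i] <<- stay * (1 - p8)
      R[i, match(hrt_to, S)] <<- R[i, match(hrt_to, S)] + stay * p8 * p13
      R[i, match(nohrt_to, S)] <<- R[i, match(nohrt_to, S)] + stay * p8 * (1 - p13)
    }
    split("carrier_none", "carrier_rrso_hrt", "carrier_rrso_nohrt")
    split("carrier_chemoprev", "carrier_rrso_hrt", "carrier_rrso_nohrt")
    split("carrier_rrm", "carrier_rrm_rrso_hrt", "carrier_rrm_rrso_nohrt")
  }
  R
}

# Precompute the per-cycle transition matrices (and redistribution where it
# applies) for a parameter bundle. Returned as a list of matrices indexed by
# cycle.
build_matrix_set <- function(params, arm = "population") {
  prof <- params$profile
  ctx <- engine_context(params)
  lapply(ctx$ages, function(a) {
    M <- fill_transition_matrix(a, ctx)
    if (a %in% c(prof$rrm_age, prof$rrso_age)) {
      list(R = redistribution_matrix(a, params), M = M)
    } else {
      list(R = NULL, M = M)
    }
  })
}

#' Run the annual-cycle cohort trace for one strategy arm
#'
#' Propagates the initial state distribution through `cycles` annual
#' transitions, applying the deterministic intervention redistribution at the
#' median RRM and RRSO ages, and records the event flows the economic
#' accounting needs (new cancer diagnoses, cause-specific deaths, surgery and
#' chemoprevention uptake, coronary heart disease events).
#'
#' @param arm_spec a `brca_arm_spec` (see [make_population_arm()]).
#' @param params a `brca_model_params` bundle.
#' @param matrices optional precomputed [build_matrix_set()] result.
#' @return a `brca_cohort_trace`: list with `trace` (rows = cycle 0..cycles),
#'   `occupancy` (within-cycle occupancy after redistribution, rows =
#'   cycle 0..cycles-1), and `events` (per-cycle flow data frame).
#' @export
run_cohort <- function(arm_spec, params, matrices = NULL) {
  S <- build_state_space()
  n <- length(S)
  prof <- params$profile
  cycles <- prof$cycles
  init <- arm_spec$init
  if (abs(sum(init) - 1) > 1e-9) {
    stop("initial distribution must sum to 1", call. = FALSE)
  }
  if (is.null(matrices)) matrices <- build_matrix_set(params)

  trace <- matrix(0, cycles + 1, n, dimnames = list(NULL, S))
  occupancy <- matrix(0, cycles, n, dimnames = list(NULL, S))
  trace[1, ] <- init

  hs <- healthy_states()
  i_bc1 <- state_index(paste0(c("brca_bc", "sporadic_bc"), "_y1"))
  i_oc1 <- state_index(paste0(c("brca_oc", "sporadic_oc"), "_y1"))
  i_dbc <- state_index("death_bc"); i_doc <- state_index("death_oc")
  i_dchd <- state_index("death_chd")
  i_healthy <- state_index(hs)
  i_nohrt <- state_index(c("carrier_rrso_nohrt", "carrier_rrm_rrso_nohrt"))
  pr <- params$probs

  zeros <- numeric(cycles)
  new_bc <- zeros; new_oc <- zeros; death_bc <- zeros; death_oc <- zeros
  death_chd <- zeros; rrm_flow <- zeros; rrso_flow <- zeros
  chemo_flow <- zeros; chd_events <- zeros
  p2 <- prob(pr, "p2"); p8 <- prob(pr, "p8")
  p11 <- prob(pr, "p11"); p15 <- prob(pr, "p15")
  i_none <- state_index("carrier_none")
  i_chemo <- state_index("carrier_chemoprev")
  i_rrm <- state_index("carrier_rrm")

  for (t in seq_len(cycles)) {
    age <- prof$start_age + t - 1
    v <- trace[t, ]
    step <- matrices[[t]]
    if (!is.null(step$R)) {
      if (age == prof$rrm_age) {
        rrm_flow[t] <- v[i_none] * p2
        chemo_flow[t] <- v[i_none] * (1 - p2) * p15
      }
      if (age == prof$rrso_age) {
        rrso_flow[t] <- p8 * (v[i_none] + v[i_chemo] + v[i_rrm])
      }
      v <- drop(v %*% step$R)
    }
    occupancy[t, ] <- v
    M <- step$M
    trace[t + 1, ] <- drop(v %*% M)
    vh <- v[i_healthy]
    new_bc[t] <- sum(vh * rowSums(M[i_healthy, i_bc1, drop = FALSE]))
    new_oc[t] <- sum(vh * rowSums(M[i_healthy, i_oc1, drop = FALSE]))
    death_bc[t] <- trace[t + 1, i_dbc] - trace[t, i_dbc]
    death_oc[t] <- trace[t + 1, i_doc] - trace[t, i_doc]
    death_chd[t] <- trace[t + 1, i_dchd] - trace[t, i_dchd]
    if (age >= prof$rrso_age) {
      chd_events[t] <- sum(v[i_nohrt]) * p11
    }
  }

  ev <- data.frame(cycle = seq_len(cycles) - 1,
                   age = prof$start_age + seq_len(cycles) - 1,
                   new_bc = new_bc, new_oc = new_oc, death_bc = death_bc,
                   death_oc = death_oc, death_chd = death_chd,
                   rrm_flow = rrm_flow, rrso_flow = rrso_flow,
                   chemo_flow = chemo_flow, chd_events = chd_events)

  structure(list(trace = trace, occupancy = occupancy, events = ev,
                 state_space = S, cycles = cycles,
                 start_age = prof$start_age, arm = arm_spec$label),
            class = "brca_cohort_trace")
}

#' @export
print.brca_cohort_trace <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  dead <- sum(last[death_states()])
  cat("<brca_cohort_trace> arm:", x$arm, "|", x$cycles, "cycles | final dead:",
      sprintf("%.3f", dead), "\n")
  invisible(x)
}

#' Export a cohort trace as a long data frame
#'
#' @param ct a `brca_cohort_trace`.
#' @return data frame with `cycle`, `state`, `occupancy`.
#' @export
trace_to_df <- function(ct) {
  data.frame(cycle = rep(0:ct$cycles, times = length(ct$state_space)),
             state = rep(ct$state_space, each = ct$cycles + 1),
             occupancy = as.vector(ct$trace))
}

#' Individual-level microsimulation of the same transition matrices
#'
#' Samples `n` individuals through the identical per-cycle transition (and
#' redistribution) matrices used by [run_cohort()], aggregated as state
#' counts. Serves as an independent stochastic check on the deterministic
#' cohort trace.
#'
#' @param arm_spec a `brca_arm_spec`.
#' @param params a `brca_model_params` bundle.
#' @param n number of simulated individuals.
#' @param seed RNG seed.
#' @return matrix of occupancy fractions, rows = cycle 0..cycles.
#' @export
microsim_cohort <- function(arm_spec, params, n = 200000, seed = 1L) {
  S <- build_state_space()
  cycles <- params$profile$cycles
  matrices <- build_matrix_set(params)
  set.seed(seed)
  counts <- drop(stats::rmultinom(1, n, arm_spec$init))
  out <- matrix(0, cycles + 1, length(S), dimnames = list(NULL, S))
  out[1, ] <- counts / n
  for (t in seq_len(cycles)) {
    step <- matrices[[t]]
    Meff <- if (is.null(step$R)) step$M else step$R %*% step$M
    nxt <- numeric(length(S))
    for (s in which(counts > 0)) {
      nxt <- nxt + drop(stats::rmultinom(1, counts[s], Meff[s, ]))
    }
    counts <- nxt
    out[t + 1, ] <- counts / n
  }
  out
}
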