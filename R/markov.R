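#' Economic parameters of the ART programme
#'
#' Bundles the three cost/outcome constants the Markov model consumes. The
#' base case reflects a programme-wide costing of 45 Zambian treatment sites:
#' $556 per patient-year of ART (so $139 per 90-day quarter), a lifetime
#' programme cost of $6,118 per patient alive and in care at the 6-month
#' horizon (already discounted at 3% upstream and inclusive of historical
#' second-line ART switching), and 7.3 discounted DALYs averted per such
#' survivor. No further discounting happens inside the model: first-year
#' costs are not discounted and the lifetime tail arrives pre-discounted.
#'
#' @param annual_art_cost USD per patient-year of ART.
#' @param lifetime_cost_per_survivor USD lifetime programme cost assigned to a
#'   patient alive/active at 6 months.
#' @param dalys_per_survivor DALYs averted per patient alive/active at 6
#'   months.
#' @return an object of class `econ_params`: a list with the three inputs plus
#'   `quarterly_art_cost = annual_art_cost / 4`.
#' @export
#' @examples
#' econ_params()
#' econ_params(annual_art_cost = 1200)
econ_params <- function(annual_art_cost = 556,
                        lifetime_cost_per_survivor = 6118,
                        dalys_per_survivor = 7.3) {
  if (annual_art_cost <= 0 || lifetime_cost_per_survivor <= 0 || dalys_per_survivor <= 0) {
    abort("all economic parameters must be strictly positive",
      class = "nutricea_validation_error"
    )
  }
  quarterly <- annual_art_cost / 4
  if (lifetime_cost_per_survivor <= 2 * quarterly) {
    abort("lifetime cost per survivor must exceed two quarters of ART cost",
      class = "nutricea_validation_error"
    )
  }
  structure(
    list(
      annual_art_cost = annual_art_cost,
      quarterly_art_cost = quarterly,
      lifetime_cost_per_survivor = lifetime_cost_per_survivor,
      dalys_per_survivor = dalys_per_survivor
    ),
    class = "econ_params"
  )
}

#' @export
print.econ_params <- function(x, ...) {
  cat("ART programme economic parameters\n")
  cat(sprintf("  annual ART cost:            $%.2f (quarterly $%.2f)\n",
              x$annual_art_cost, x$quarterly_art_cost))
  cat(sprintf("  lifetime cost per survivor: $%.2f\n", x$lifetime_cost_per_survivor))
  cat(sprintf("  DALYs averted per survivor: %.2f\n", x$dalys_per_survivor))
  invisible(x)
}

# Internal: check a 2-row transition tibble used by the engine.
.check_two_cycles <- function(transitions) {
  if (!is.data.frame(transitions) || nrow(transitions) != 2) {
    abort("the 6-month model requires exactly 2 quarterly transitions (Q1, Q2)",
      class = "nutricea_validation_error"
    )
  }
  tot <- transitions$p_alive + transitions$p_dead + transitions$p_ltfu
  if (any(abs(tot - 1) > 1e-9) ||
      any(transitions$p_alive < 0 | transitions$p_dead < 0 | transitions$p_ltfu < 0)) {
    abort("each transition triple must be non-negative and sum to 1",
      class = "nutricea_validation_error"
    )
  }
  invisible(transitions)
}

#' Evaluate the two-cycle Markov cohort model
#'
#' Moves a cohort through two 90-day cycles of a three-state unidirectional
#' Markov model (alive/active in care, deceased, lost to follow-up; the latter
#' two absorbing) and accumulates expected per-starting-patient cost and
#' health outcome. Every patient entering a quarter accrues that quarter's
#' full ART cost regardless of end-of-quarter disposition (no half-cycle
#' correction). Patients alive and active after cycle 2 receive the lifetime
#' tail: `lifetime_cost_per_survivor` minus the two quarterly ART costs
#' already accrued, plus `dalys_per_survivor` averted DALYs.
#'
#' @param transitions a 2-row tibble with columns `p_alive`, `p_dead`,
#'   `p_ltfu` (quarters 1 and 2, in order), e.g. one stratum's rows from
#'   [derive_transitions()].
#' @param econ an [econ_params()] object.
#' @return a one-row tibble of class `cohort_outcome` with columns
#'   `six_month_survival`, `quarterly_exposure` (expected quarter-entries per
#'   starting patient, `1 + p_alive(Q1)`), `supplement_exposure` (identical
#'   under the base assumption that supplement is dispensed each entered
#'   quarter), `expected_cost` (USD, ART side only) and `expected_dalys`.
#' @export
#' @examples
#' tr <- derive_transitions(zambia_cohort())
#' run_cohort_model(dplyr::filter(tr, stratum == "<16.0", quarter <= 2), econ_params())
run_cohort_model <- function(transitions, econ) {
  stopifnot(inherits(econ, "econ_params"))
  .check_two_cycles(transitions)
  p_a1 <- transitions$p_alive[1]
  p_a2 <- transitions$p_alive[2]
  surv <- p_a1 * p_a2
  exposure <- 1 + p_a1
  q <- econ$quarterly_art_cost
  cost <- q * exposure + surv * (econ$lifetime_cost_per_survivor - 2 * q)
  out <- tibble(
    six_month_survival = surv,
    quarterly_exposure = exposure,
    supplement_exposure = exposure,
    expected_cost = cost,
    expected_dalys = surv * econ$dalys_per_survivor
  )
  class(out) <- c("cohort_outcome", class(out))
  out
}

#' Cost per DALY averted
#'
#' The cost-effectiveness ratio of a programme: expected per-starting-patient
#' cost (optionally plus an extra per-patient cost such as supplement spend)
#' divided by expected DALYs averted.
#'
#' @param outcome a `cohort_outcome` row from [run_cohort_model()].
#' @param extra_cost additional USD per starting patient (default 0).
#' @return USD per DALY averted (scalar).
#' @export
cost_per_daly <- function(outcome, extra_cost = 0) {
  if (outcome$expected_dalys <= 0) {
    abort("expected DALYs averted is zero: cost per DALY is undefined",
      class = "nutricea_validation_error"
    )
  }
  (outcome$expected_cost + extra_cost) / outcome$expected_dalys
}

#' Per-patient microsimulation of the cohort model
#'
#' Independent Monte-Carlo check on [run_cohort_model()]: each simulated
#' patient is drawn through the two quarters with categorical draws from the
#' transition triples, accruing the same quarterly costs and lifetime tail as
#' the analytic engine. Sample means converge to the analytic outcome; used
#' in tests as an oracle, exported because it is handy for model audits.
#'
#' @inheritParams run_cohort_model
#' @param n_patients number of simulated patients.
#' @param seed optional integer seed for reproducibility.
#' @return a one-row tibble shaped like [run_cohort_model()] output, holding
#'   sample-mean estimates, plus `n_patients`.
#' @export
simulate_patients <- function(transitions, econ, n_patients, seed = NULL) {
  stopifnot(inherits(econ, "econ_params"), n_patients >= 1)
  .check_two_cycles(transitions)
  if (!is.null(seed)) set.seed(seed)
  # states: 1 alive, 2 dead, 3 ltfu
  q1 <- sample.int(3L, n_patients, replace = TRUE,
    prob = c(transitions$p_alive[1], transitions$p_dead[1], transitions$p_ltfu[1]))
  alive1 <- q1 == 1L
  n1 <- sum(alive1)
  q2 <- integer(n_patients)
  if (n1 > 0) {
    q2[alive1] <- sample.int(3L, n1, replace = TRUE,
      prob = c(transitions$p_alive[2], transitions$p_dead[2], transitions$p_ltfu[2]))
  }
  alive2 <- alive1 & q2 == 1L
  qc <- econ$quarterly_art_cost
  cost <- qc + qc * alive1 + alive2 * (econ$lifetime_cost_per_survivor - 2 * qc)
  out <- tibble(
    six_month_survival = mean(alive2),
    quarterly_exposure = 1 + mean(alive1),
    supplement_exposure = 1 + mean(alive1),
    expected_cost = mean(cost),
    expected_dalys = mean(alive2) * econ$dalys_per_survivor,
    n_patients = n_patients
  )
  class(out) <- c("cohort_outcome", class(out))
  out
}
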