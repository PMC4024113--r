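#' One-way sensitivity analysis: ART programme cost
#'
#' Re-solves the threshold supplement price across a sweep of annual ART
#' costs. At each cost C the quarterly ART cost becomes C/4 and the lifetime
#' programme cost per survivor is rescaled proportionally from the base case
#' (base lifetime cost times C divided by the base annual cost); DALYs averted
#' per survivor are unchanged. The stratum willingness to pay is recomputed at
#' each cost before the threshold solve, so the comparison is always against
#' ART alone at the same price level.
#'
#' @param cohort a validated cohort tibble.
#' @param annual_costs annual ART costs to sweep (USD per patient-year); the
#'   published sweep is $500 to $1200.
#' @param r_mort,r_ltfu intervention effect; the published sensitivity uses
#'   20% on both.
#' @param base_econ base-case [econ_params()] providing the anchor for the
#'   proportional lifetime-cost scaling.
#' @param mode probability rounding mode, see [derive_transitions()].
#' @return a tibble of class `art_cost_sweep` with columns `stratum`,
#'   `annual_art_cost`, `wtp`, `s_star`.
#' @export
#' @examples
#' art_cost_sweep(zambia_cohort(), annual_costs = c(556, 1200))
art_cost_sweep <- function(cohort,
                           annual_costs = seq(500, 1200, by = 25),
                           r_mort = 0.2, r_ltfu = 0.2,
                           base_econ = econ_params(),
                           mode = c("percentages", "counts")) {
  mode <- match.arg(mode)
  if (any(annual_costs <= 0)) {
    abort("annual_costs must be strictly positive", class = "nutricea_validation_error")
  }
  tr <- derive_transitions(cohort, mode = mode)
  res <- purrr::map_dfr(sort(annual_costs), function(cost) {
    econ <- econ_params(
      annual_art_cost = cost,
      lifetime_cost_per_survivor =
        base_econ$lifetime_cost_per_survivor * cost / base_econ$annual_art_cost,
      dalys_per_survivor = base_econ$dalys_per_survivor
    )
    purrr::map_dfr(unique(tr$stratum), function(s) {
      trans2 <- .stratum_transitions(tr, s)
      wtp <- cost_per_daly(run_cohort_model(trans2, econ))
      tibble(
        stratum = s, annual_art_cost = cost, wtp = wtp,
        s_star = .stratum_threshold(trans2, econ, r_mort, r_ltfu, wtp = wtp)
      )
    })
  })
  class(res) <- c("art_cost_sweep", class(res))
  res
}

# Internal: expected outcome of one arm when a fraction of the patients
# classified as LTFU at 6 months later return to care. Returned patients are
# assigned the lifetime tail net of the ART cost they accrued before exit
# (one quarter for a Q1 exit, two for a Q2 exit) and the full DALY benefit;
# supplement exposure is unchanged (no second course on return).
.return_outcome <- function(trans2, econ, return_fraction) {
  p_a1 <- trans2$p_alive[1]
  surv <- p_a1 * trans2$p_alive[2]
  ltfu_q1 <- trans2$p_ltfu[1]
  ltfu_q2 <- p_a1 * trans2$p_ltfu[2]
  q <- econ$quarterly_art_cost
  lt <- econ$lifetime_cost_per_survivor
  cost <- q * (1 + p_a1) + surv * (lt - 2 * q) +
    return_fraction * (ltfu_q1 * (lt - q) + ltfu_q2 * (lt - 2 * q))
  dalys <- (surv + return_fraction * (ltfu_q1 + ltfu_q2)) * econ$dalys_per_survivor
  list(cost = cost, dalys = dalys, supplement_exposure = 1 + p_a1)
}

#' One-way sensitivity analysis: return to care after loss to follow-up
#'
#' The primary model treats loss to follow-up as an absorbing exit. This
#' sensitivity assumes a fraction of the patients classified as lost at 6
#' months subsequently return to care, generating the same lifetime programme
#' cost (net of ART cost accrued before exit) and DALYs averted as patients
#' who never left; returned patients receive no second course of
#' supplementation. The same return assumption is applied to the ART-alone
#' comparator before its willingness to pay is computed, so parity compares
#' like with like. The threshold supplement price is then solved at parity:
#' `S* = (WTP_return * DALYs' - cost') / supplement_exposure'` with primes
#' denoting the intervention-adjusted, return-adjusted arm.
#'
#' @inheritParams art_cost_sweep
#' @param return_fractions fractions of 6-month LTFU patients who later
#'   return, each in \[0, 1\]; the published sweep is 0.2 to 0.8.
#' @param econ an [econ_params()] object.
#' @return a tibble of class `ltfu_return_sweep` with columns `stratum`,
#'   `return_fraction`, `wtp`, `s_star`.
#' @export
#' @examples
#' ltfu_return_threshold(zambia_cohort(), return_fractions = c(0, 0.5))
ltfu_return_threshold <- function(cohort,
                                  return_fractions = seq(0.2, 0.8, by = 0.1),
                                  r_mort = 0.2, r_ltfu = 0.2,
                                  econ = econ_params(),
                                  mode = c("percentages", "counts")) {
  mode <- match.arg(mode)
  if (any(return_fractions < 0 | return_fractions > 1)) {
    abort("return fractions must lie in [0, 1]", class = "nutricea_validation_error")
  }
  tr <- derive_transitions(cohort, mode = mode)
  res <- purrr::map_dfr(unique(tr$stratum), function(s) {
    trans2 <- .stratum_transitions(tr, s)
    adj <- apply_effect(trans2, r_mort, r_ltfu)
    purrr::map_dfr(return_fractions, function(f) {
      comparator <- .return_outcome(trans2, econ, f)
      wtp <- comparator$cost / comparator$dalys
      arm <- .return_outcome(adj, econ, f)
      tibble(
        stratum = s, return_fraction = f, wtp = wtp,
        s_star = (wtp * arm$dalys - arm$cost) / arm$supplement_exposure
      )
    })
  })
  class(res) <- c("ltfu_return_sweep", class(res))
  res
}
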