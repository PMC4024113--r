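#' Apply a proportional intervention effect to quarterly transitions
#'
#' Models supplementation as multiplying each quarter's death probability by
#' `1 - r_mort` and each quarter's LTFU probability by `1 - r_ltfu`, with the
#' freed probability mass reallocated to remaining alive and active in care.
#'
#' @param transitions tibble of transitions (any strata/quarters) as from
#'   [derive_transitions()].
#' @param r_mort proportional reduction in quarterly mortality, in \[0, 1\].
#' @param r_ltfu proportional reduction in quarterly LTFU, in \[0, 1\].
#' @return the transitions tibble with adjusted `p_alive`, `p_dead`, `p_ltfu`.
#' @export
#' @examples
#' tr <- derive_transitions(zambia_cohort())
#' apply_effect(tr, r_mort = 0.2, r_ltfu = 0.2)
apply_effect <- function(transitions, r_mort, r_ltfu) {
  if (r_mort < 0 || r_mort > 1 || r_ltfu < 0 || r_ltfu > 1) {
    abort("r_mort and r_ltfu must lie in [0, 1]", class = "nutricea_validation_error")
  }
  transitions %>%
    mutate(
      p_dead = .data$p_dead * (1 - r_mort),
      p_ltfu = .data$p_ltfu * (1 - r_ltfu),
      p_alive = 1 - .data$p_dead - .data$p_ltfu
    )
}

#' Willingness-to-pay benchmark of ART alone
#'
#' The cost per DALY averted achieved by standard ART in each BMI stratum,
#' computed from the historical transition probabilities with no supplement.
#' This is the parity benchmark ("willingness to pay", WTP): a combined
#' supplement + ART programme is judged cost-effective in a stratum only if
#' its cost per DALY averted does not exceed that stratum's WTP.
#'
#' @param cohort a validated cohort tibble.
#' @param econ an [econ_params()] object.
#' @param mode probability rounding mode, see [derive_transitions()].
#' @return a tibble with columns `stratum` and `wtp` (USD per DALY averted).
#' @export
#' @examples
#' willingness_to_pay(zambia_cohort(), econ_params())
willingness_to_pay <- function(cohort, econ, mode = c("percentages", "counts")) {
  mode <- match.arg(mode)
  tr <- derive_transitions(cohort, mode = mode)
  purrr::map_dfr(unique(tr$stratum), function(s) {
    out <- run_cohort_model(.stratum_transitions(tr, s), econ)
    tibble(stratum = s, wtp = cost_per_daly(out))
  })
}

# Internal scalar solver: maximum quarterly supplement price for one stratum's
# 2-cycle transitions. The parity condition
#   (cost' + S * exposure') / dalys' == wtp
# is linear in S, so the solve is closed-form.
.stratum_threshold <- function(trans2, econ, r_mort, r_ltfu, wtp = NULL) {
  if (is.null(wtp)) wtp <- cost_per_daly(run_cohort_model(trans2, econ))
  adj <- apply_effect(trans2, r_mort, r_ltfu)
  out <- run_cohort_model(adj, econ)
  (wtp * out$expected_dalys - out$expected_cost) / out$supplement_exposure
}

#' Maximum cost-effective quarterly supplement price
#'
#' Solves, per stratum, the largest quarterly supplement cost S* at which the
#' combined supplement + ART programme still matches the stratum's own ART
#' alone willingness-to-pay. The supplement is costed like ART: one quarter's
#' price accrues to every patient entering each of the two cycles under the
#' intervention-adjusted survival. The parity equation is linear in the price,
#' so S* has the closed form
#' `(WTP * DALYs' - cost') / supplement_exposure'`, primes denoting the
#' intervention-adjusted model.
#'
#' A negative S* (possible only if the "intervention" worsens outcomes) is
#' returned as-is with a warning: no positive price achieves parity.
#'
#' @inheritParams willingness_to_pay
#' @param r_mort,r_ltfu proportional reductions in quarterly mortality and
#'   LTFU conferred by the supplement, each in \[0, 1\].
#' @return a tibble with columns `stratum`, `r_mort`, `r_ltfu`, `s_star`
#'   (USD per quarter).
#' @export
#' @examples
#' max_supplement_cost(zambia_cohort(), econ_params(), r_mort = 0.2, r_ltfu = 0.2)
max_supplement_cost <- function(cohort, econ, r_mort, r_ltfu,
                                mode = c("percentages", "counts")) {
  mode <- match.arg(mode)
  tr <- derive_transitions(cohort, mode = mode)
  res <- purrr::map_dfr(unique(tr$stratum), function(s) {
    tibble(
      stratum = s, r_mort = r_mort, r_ltfu = r_ltfu,
      s_star = .stratum_threshold(.stratum_transitions(tr, s), econ, r_mort, r_ltfu)
    )
  })
  if (any(res$s_star < 0)) {
    warn("negative threshold price: no positive supplement cost achieves parity")
  }
  res
}

# The four published effect scenarios.
.default_scenarios <- function() {
  tibble(
    scenario = c(
      "20% mortality benefit, no retention benefit",
      "No mortality benefit, 20% retention benefit",
      "20% mortality and 20% retention benefit",
      "50% mortality and 50% retention benefit"
    ),
    r_mort = c(0.2, 0, 0.2, 0.5),
    r_ltfu = c(0, 0.2, 0.2, 0.5)
  )
}

#' Scenario matrix of threshold supplement prices
#'
#' Maximum allowable quarterly supplement costs, per malnourished BMI stratum,
#' for the four published effect scenarios: 20% mortality reduction only, 20%
#' LTFU reduction only, 20% on both, and 50% on both.
#'
#' @inheritParams willingness_to_pay
#' @param scenarios a tibble with columns `scenario`, `r_mort`, `r_ltfu`;
#'   defaults to the four published scenarios.
#' @param strata stratum labels to include; all must be present in `cohort`.
#' @return a tibble with columns `scenario`, `r_mort`, `r_ltfu`, then one
#'   `s_star` column per stratum (wide, mirroring the published table layout).
#' @export
#' @examples
#' scenario_table(zambia_cohort(), econ_params())
scenario_table <- function(cohort, econ, scenarios = .default_scenarios(),
                           strata = malnourished_strata(),
                           mode = c("percentages", "counts")) {
  mode <- match.arg(mode)
  missing_strata <- setdiff(strata, unique(cohort$stratum))
  if (length(missing_strata) > 0) {
    abort(
      paste0("cohort is missing stratum/strata: ", paste(missing_strata, collapse = ", ")),
      class = "nutricea_validation_error"
    )
  }
  tr <- derive_transitions(cohort, mode = mode)
  long <- purrr::pmap_dfr(scenarios, function(scenario, r_mort, r_ltfu) {
    purrr::map_dfr(strata, function(s) {
      tibble(
        scenario = scenario, r_mort = r_mort, r_ltfu = r_ltfu, stratum = s,
        s_star = .stratum_threshold(.stratum_transitions(tr, s), econ, r_mort, r_ltfu)
      )
    })
  })
  tidyr::pivot_wider(long, names_from = "stratum", values_from = "s_star")
}

#' Six-month retention surface over intervention effects
#'
#' Percentage of starting patients remaining alive and active in care at 6
#' months for each (mortality reduction, LTFU reduction) pair on a grid. The
#' (0, 0) cell is the historical 6-month retention.
#'
#' @inheritParams willingness_to_pay
#' @param r_mort_grid,r_ltfu_grid numeric vectors of proportional reductions
#'   (the published figure sweeps 0 to 0.5).
#' @return a tibble of class `retention_surface` with columns `stratum`,
#'   `r_mort`, `r_ltfu`, `pct_alive` (per 100 starting patients).
#' @export
#' @examples
#' retention_surface(zambia_cohort(), r_mort_grid = c(0, 0.5), r_ltfu_grid = c(0, 0.5))
retention_surface <- function(cohort,
                              r_mort_grid = seq(0, 0.5, by = 0.05),
                              r_ltfu_grid = seq(0, 0.5, by = 0.1),
                              mode = c("percentages", "counts")) {
  mode <- match.arg(mode)
  tr <- derive_transitions(cohort, mode = mode)
  grid <- tidyr::expand_grid(
    stratum = unique(tr$stratum),
    r_mort = r_mort_grid,
    r_ltfu = r_ltfu_grid
  )
  res <- grid %>%
    mutate(pct_alive = purrr::pmap_dbl(grid, function(stratum, r_mort, r_ltfu) {
      adj <- apply_effect(.stratum_transitions(tr, stratum), r_mort, r_ltfu)
      100 * adj$p_alive[1] * adj$p_alive[2]
    }))
  class(res) <- c("retention_surface", class(res))
  res
}

#' Parity frontier for a given supplement price
#'
#' For each mortality-reduction value on a grid, finds the LTFU reduction at
#' which the combined programme's cost per DALY averted exactly equals the
#' stratum's ART-alone willingness to pay when the supplement costs
#' `supplement_cost` per quarter. Effect combinations beyond the frontier
#' (larger reductions) are strictly more cost-effective than parity. Grid
#' points admitting no solution in \[0, 1\] are omitted.
#'
#' The threshold price is monotone increasing in the LTFU reduction, so the
#' root is found by bracketed bisection (`stats::uniroot`, tolerance 1e-6).
#'
#' @inheritParams willingness_to_pay
#' @param supplement_cost quarterly supplement price (USD, >= 0).
#' @param resolution spacing of the mortality-reduction grid on \[0, 1\].
#' @param strata stratum labels to trace; default all malnourished strata
#'   present in `cohort`.
#' @return a tibble of class `parity_frontier` with columns `stratum`,
#'   `supplement_cost`, `r_mort`, `r_ltfu`.
#' @export
#' @examples
#' parity_frontier(zambia_cohort(), econ_params(), supplement_cost = 10.99,
#'                 resolution = 0.05)
parity_frontier <- function(cohort, econ, supplement_cost, resolution = 0.005,
                            strata = intersect(malnourished_strata(), unique(cohort$stratum)),
                            mode = c("percentages", "counts")) {
  mode <- match.arg(mode)
  if (supplement_cost < 0) {
    abort("supplement_cost must be non-negative", class = "nutricea_validation_error")
  }
  tr <- derive_transitions(cohort, mode = mode)
  r_grid <- seq(0, 1, by = resolution)
  res <- purrr::map_dfr(strata, function(s) {
    trans2 <- .stratum_transitions(tr, s)
    wtp <- cost_per_daly(run_cohort_model(trans2, econ))
    pts <- purrr::map_dfr(r_grid, function(rm) {
      f <- function(rl) .stratum_threshold(trans2, econ, rm, rl, wtp = wtp) - supplement_cost
      f0 <- f(0)
      f1 <- f(1)
      if (f0 > 0 || f1 < 0) return(tibble())  # no root in [0, 1]
      rl <- if (f0 == 0) 0 else uniroot(f, c(0, 1), tol = 1e-6)$root
      tibble(stratum = s, supplement_cost = supplement_cost, r_mort = rm, r_ltfu = rl)
    })
    pts
  })
  class(res) <- c("parity_frontier", class(res))
  res
}

#' Fit the full cost-effectiveness analysis
#'
#' Convenience wrapper bundling the whole pipeline for one cohort table and
#' one set of economic parameters: per-stratum Markov outcomes under
#' historical transitions, WTP benchmarks, and the published scenario matrix
#' of threshold supplement prices. Supports [tidy()], [glance()] and
#' [ggplot2::autoplot()].
#'
#' @inheritParams willingness_to_pay
#' @param strata strata entering the scenario matrix (WTP and outcomes are
#'   reported for every stratum present).
#' @return an object of class `cea_fit`.
#' @export
#' @examples
#' fit <- fit_cea(zambia_cohort(), econ_params())
#' tidy(fit)
#' glance(fit)
fit_cea <- function(cohort, econ = econ_params(),
                    strata = malnourished_strata(),
                    mode = c("percentages", "counts")) {
  mode <- match.arg(mode)
  cohort <- validate_cohort_table(cohort)
  tr <- derive_transitions(cohort, mode = mode)
  outcomes <- purrr::map_dfr(unique(tr$stratum), function(s) {
    out <- run_cohort_model(.stratum_transitions(tr, s), econ)
    dplyr::bind_cols(tibble(stratum = s), as_tibble(out))
  })
  outcomes$wtp <- outcomes$expected_cost / outcomes$expected_dalys
  structure(
    list(
      cohort = cohort,
      econ = econ,
      mode = mode,
      transitions = tr,
      outcomes = outcomes,
      scenarios = scenario_table(cohort, econ, strata = strata, mode = mode)
    ),
    class = "cea_fit"
  )
}

#' @export
print.cea_fit <- function(x, ...) {
  cat("Two-cycle Markov cost-effectiveness analysis (", x$mode, " mode)\n\n", sep = "")
  cat("Willingness-to-pay benchmarks (ART alone, USD per DALY averted):\n")
  wtp <- x$outcomes[, c("stratum", "wtp")]
  for (i in seq_len(nrow(wtp))) {
    cat(sprintf("  %-12s $%.2f\n", wtp$stratum[i], wtp$wtp[i]))
  }
  cat("\nMaximum cost-effective quarterly supplement price (USD):\n")
  print(as.data.frame(x$scenarios), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_cea
#' @param x a `cea_fit` object.
#' @param ... unused.
#' @method tidy cea_fit
#' @export
tidy.cea_fit <- function(x, ...) {
  x$outcomes %>%
    select("stratum", "six_month_survival", "quarterly_exposure",
           "expected_cost", "expected_dalys", "wtp")
}

#' @rdname fit_cea
#' @method glance cea_fit
#' @export
glance.cea_fit <- function(x, ...) {
  tibble(
    n_strata = length(unique(x$cohort$stratum)),
    n_quarters = max(x$cohort$quarter),
    starting_patients = sum(x$cohort$n_entering[x$cohort$quarter == 1]),
    annual_art_cost = x$econ$annual_art_cost,
    lifetime_cost_per_survivor = x$econ$lifetime_cost_per_survivor,
    dalys_per_survivor = x$econ$dalys_per_survivor,
    mode = x$mode
  )
}
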