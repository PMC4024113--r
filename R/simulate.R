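#' Simulate a cohort disposition table
#'
#' Generates a synthetic quarterly disposition table with the generative
#' structure the analysis assumes: within each stratum and quarter the
#' outcomes of the patients entering that quarter are a single multinomial
#' draw over (alive/active, dead, LTFU) with the quarter's true
#' probabilities, and the survivors feed the next quarter. Sampling is at
#' cohort-count level rather than per-patient event streams, which is
#' sufficient for the model and much cheaper. The result satisfies every
#' cohort-table invariant and round-trips through [write_cohort_table()] /
#' [load_cohort_table()].
#'
#' @param true_transitions a transitions tibble (columns `stratum`, `quarter`,
#'   `p_alive`, `p_dead`, `p_ltfu`), e.g. from [derive_transitions()]; these
#'   are the true per-quarter probabilities.
#' @param n_start number of patients entering quarter 1; either a single
#'   value recycled across strata or a vector named by stratum.
#' @param seed optional integer seed.
#' @return a validated cohort tibble.
#' @export
#' @examples
#' truth <- derive_transitions(zambia_cohort(), mode = "counts")
#' simulate_cohort(truth, n_start = 5096, seed = 1)
simulate_cohort <- function(true_transitions, n_start, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  strata <- unique(true_transitions$stratum)
  if (!is.null(names(n_start))) {
    n0 <- n_start[strata]
    if (anyNA(n0)) {
      abort("n_start names do not cover every stratum", class = "nutricea_validation_error")
    }
  } else {
    n0 <- rep(n_start, length.out = length(strata))
  }
  if (any(n0 < 1)) {
    abort("n_start must be at least 1", class = "nutricea_validation_error")
  }
  rows <- purrr::map2_dfr(strata, n0, function(s, n) {
    tr <- true_transitions[true_transitions$stratum == s, ]
    tr <- tr[order(tr$quarter), ]
    n_enter <- n
    purrr::map_dfr(seq_len(nrow(tr)), function(q) {
      p <- c(tr$p_alive[q], tr$p_dead[q], tr$p_ltfu[q])
      draw <- as.vector(rmultinom(1, size = n_enter, prob = p))
      row <- tibble(
        stratum = s, quarter = as.integer(q), n_entering = n_enter,
        n_alive = draw[1], n_dead = draw[2], n_ltfu = draw[3]
      )
      n_enter <<- draw[1]
      row
    })
  })
  validate_cohort_table(rows)
}

#' Parameter-recovery experiment on synthetic cohorts
#'
#' Repeatedly simulates cohort tables from known true transition
#' probabilities, re-runs the estimation pipeline on each replicate (derive
#' raw-count transitions, then the downstream willingness to pay and
#' threshold supplement price), and summarises the sampling distribution of
#' each estimator against its true value. Per-replicate random streams are
#' derived deterministically from the master seed, so experiments are
#' reproducible.
#'
#' @param true_transitions true per-quarter probabilities (as in
#'   [simulate_cohort()]); quarters beyond Q2 are simulated but the 6-month
#'   estimators use Q1-Q2.
#' @param n_start quarter-1 cohort size per stratum.
#' @param n_replicates number of simulated cohorts (>= 2).
#' @param econ an [econ_params()] object.
#' @param r_mort,r_ltfu intervention effect used for the threshold estimator.
#' @param seed master seed.
#' @return an object of class `recovery_experiment`: a list with
#'   `replicates` (per-replicate estimates of `p_dead` by quarter, `wtp`, and
#'   `s_star`, per stratum) and `summary` (per stratum and estimand: truth,
#'   mean, sd, 2.5%/97.5% percentiles of the estimates, and whether that
#'   interval covers the truth). [tidy()] returns the summary.
#' @export
#' @examples
#' truth <- derive_transitions(zambia_cohort(), mode = "counts")
#' truth <- dplyr::filter(truth, stratum == "<16.0", quarter <= 2)
#' recovery_experiment(truth, n_start = 5096, n_replicates = 50, seed = 7)
recovery_experiment <- function(true_transitions, n_start, n_replicates,
                                econ = econ_params(),
                                r_mort = 0.2, r_ltfu = 0.2, seed = NULL) {
  if (n_replicates < 2) {
    abort("n_replicates must be at least 2", class = "nutricea_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  replicates <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    cohort <- simulate_cohort(true_transitions, n_start, seed = rep_seeds[i])
    est_tr <- derive_transitions(cohort, mode = "counts")
    downstream <- purrr::map_dfr(unique(est_tr$stratum), function(s) {
      trans2 <- .stratum_transitions(est_tr, s)
      wtp <- cost_per_daly(run_cohort_model(trans2, econ))
      tibble(
        stratum = s, wtp = wtp,
        s_star = .stratum_threshold(trans2, econ, r_mort, r_ltfu, wtp = wtp)
      )
    })
    est_tr %>%
      filter(.data$quarter <= 2) %>%
      mutate(replicate = i) %>%
      select("replicate", "stratum", "quarter", "p_alive", "p_dead", "p_ltfu") %>%
      left_join(downstream, by = "stratum")
  })

  truth_long <- .recovery_truths(true_transitions, econ, r_mort, r_ltfu)
  est_long <- replicates %>%
    tidyr::pivot_longer(c("p_alive", "p_dead", "p_ltfu"),
      names_to = "estimand", values_to = "estimate"
    ) %>%
    mutate(estimand = paste0(.data$estimand, "_q", .data$quarter)) %>%
    select("replicate", "stratum", "estimand", "estimate") %>%
    bind_rows(
      replicates %>%
        filter(.data$quarter == 1) %>%
        tidyr::pivot_longer(c("wtp", "s_star"),
          names_to = "estimand", values_to = "estimate"
        ) %>%
        select("replicate", "stratum", "estimand", "estimate")
    )

  summary <- est_long %>%
    group_by(.data$stratum, .data$estimand) %>%
    summarise(
      mean = mean(.data$estimate),
      sd = sd(.data$estimate),
      lower = quantile(.data$estimate, 0.025, names = FALSE),
      upper = quantile(.data$estimate, 0.975, names = FALSE),
      .groups = "drop"
    ) %>%
    left_join(truth_long, by = c("stratum", "estimand")) %>%
    mutate(covered = .data$truth >= .data$lower & .data$truth <= .data$upper)

  structure(
    list(replicates = replicates, summary = summary, n_start = n_start,
         n_replicates = n_replicates),
    class = "recovery_experiment"
  )
}

# Internal: true values of every estimand tracked by recovery_experiment.
.recovery_truths <- function(true_transitions, econ, r_mort, r_ltfu) {
  strata <- unique(true_transitions$stratum)
  purrr::map_dfr(strata, function(s) {
    trans2 <- .stratum_transitions(true_transitions, s)
    wtp <- cost_per_daly(run_cohort_model(trans2, econ))
    probs <- trans2 %>%
      tidyr::pivot_longer(c("p_alive", "p_dead", "p_ltfu"),
        names_to = "estimand", values_to = "truth"
      ) %>%
      mutate(estimand = paste0(.data$estimand, "_q", .data$quarter)) %>%
      select("estimand", "truth")
    bind_rows(
      probs,
      tibble(
        estimand = c("wtp", "s_star"),
        truth = c(wtp, .stratum_threshold(trans2, econ, r_mort, r_ltfu, wtp = wtp))
      )
    ) %>%
      mutate(stratum = s, .before = 1)
  })
}

#' @rdname recovery_experiment
#' @param x a `recovery_experiment` object.
#' @param ... unused.
#' @method tidy recovery_experiment
#' @export
tidy.recovery_experiment <- function(x, ...) x$summary

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf(
    "Parameter-recovery experiment: %d replicates, n_start = %s\n\n",
    x$n_replicates, paste(x$n_start, collapse = "/")
  ))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}
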