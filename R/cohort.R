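#' Load a quarterly cohort disposition table
#'
#' Reads a CSV of BMI-stratified quarterly cohort dispositions into a validated
#' tibble. Each row gives, for one stratum and one 90-day quarter on ART, the
#' number of patients alive/active at the start of the quarter and the number
#' alive/active, dead, and lost to follow-up (LTFU) at its end. These counts
#' are the source of every transition probability in the Markov model.
#'
#' The expected schema (header required) is
#' `stratum,quarter,n_entering,n_alive,n_dead,n_ltfu`, one row per
#' stratum-quarter, UTF-8, comma-delimited. The packaged fixture
#' (`zambia_cohort()`) carries the historical Zambian national ART programme
#' table: 19,247 adults with BMI < 18.5 kg/m^2 (plus the >18.5 reference
#' stratum) followed quarterly over the first year of treatment.
#'
#' @param source path to a CSV file conforming to the schema above.
#' @return a tibble with columns `stratum`, `quarter`, `n_entering`,
#'   `n_alive`, `n_dead`, `n_ltfu`, sorted by stratum then quarter, with all
#'   validity invariants checked (see [validate_cohort_table()]).
#' @seealso [zambia_cohort()], [derive_transitions()], [write_cohort_table()]
#' @export
#' @examples
#' cohort <- zambia_cohort()
#' dplyr::filter(cohort, stratum == "<16.0")
load_cohort_table <- function(source) {
  if (!file.exists(source)) {
    abort(paste0("cohort file not found: ", source), class = "nutricea_io_error")
  }
  tab <- readr::read_csv(
    source,
    col_types = readr::cols(
      stratum = readr::col_character(),
      quarter = readr::col_integer(),
      n_entering = readr::col_double(),
      n_alive = readr::col_double(),
      n_dead = readr::col_double(),
      n_ltfu = readr::col_double()
    )
  )
  missing_cols <- setdiff(
    c("stratum", "quarter", "n_entering", "n_alive", "n_dead", "n_ltfu"),
    names(tab)
  )
  if (length(missing_cols) > 0) {
    abort(
      paste0("cohort CSV is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "nutricea_validation_error"
    )
  }
  validate_cohort_table(tab)
}

#' The packaged historical cohort fixture
#'
#' Quarterly survival and loss to follow-up in the Zambian national ART
#' programme (May 2004 - October 2010), stratified by baseline BMI. Four
#' strata, quarters 1-4.
#'
#' @return a validated cohort tibble (see [load_cohort_table()]).
#' @export
zambia_cohort <- function() {
  load_cohort_table(
    system.file("extdata", "zambia_cohort.csv", package = "nutricea", mustWork = TRUE)
  )
}

#' Validate a cohort disposition table
#'
#' Checks the structural invariants the Markov model relies on:
#' all counts non-negative; within every row
#' `n_alive + n_dead + n_ltfu == n_entering`; quarters consecutive from 1
#' within each stratum; and the chaining invariant that the patients entering
#' quarter q+1 are exactly those alive at the end of quarter q. Violations
#' raise a validation error naming the offending stratum and quarter.
#'
#' @param cohort a data frame with the cohort CSV schema.
#' @return the cohort as a tibble, sorted by stratum and quarter.
#' @export
validate_cohort_table <- function(cohort) {
  cohort <- as_tibble(cohort) %>%
    mutate(quarter = as.integer(.data$quarter)) %>%
    arrange(.data$stratum, .data$quarter)

  counts <- c("n_entering", "n_alive", "n_dead", "n_ltfu")
  for (col in counts) {
    bad <- which(is.na(cohort[[col]]) | cohort[[col]] < 0)
    if (length(bad) > 0) {
      abort(
        sprintf(
          "negative or missing %s for stratum '%s', quarter %d",
          col, cohort$stratum[bad[1]], cohort$quarter[bad[1]]
        ),
        class = "nutricea_validation_error"
      )
    }
  }

  bad <- which(with(cohort, n_alive + n_dead + n_ltfu != n_entering))
  if (length(bad) > 0) {
    abort(
      sprintf(
        "dispositions do not sum to n_entering for stratum '%s', quarter %d",
        cohort$stratum[bad[1]], cohort$quarter[bad[1]]
      ),
      class = "nutricea_validation_error"
    )
  }

  by_str <- split(cohort, cohort$stratum)
  for (tab in by_str) {
    if (!identical(tab$quarter, seq_len(nrow(tab)))) {
      abort(
        sprintf("quarters for stratum '%s' are not consecutive from 1", tab$stratum[1]),
        class = "nutricea_validation_error"
      )
    }
    if (nrow(tab) > 1) {
      chain_bad <- which(tab$n_entering[-1] != tab$n_alive[-nrow(tab)])
      if (length(chain_bad) > 0) {
        abort(
          sprintf(
            "chaining violation for stratum '%s': n_entering of quarter %d != n_alive of quarter %d",
            tab$stratum[1], tab$quarter[chain_bad[1] + 1], tab$quarter[chain_bad[1]]
          ),
          class = "nutricea_validation_error"
        )
      }
    }
  }
  cohort
}

#' Write a cohort table to CSV
#'
#' Emits the same schema [load_cohort_table()] reads, so tables (including
#' simulated ones) round-trip exactly.
#'
#' @param cohort a validated cohort tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  cohort <- validate_cohort_table(cohort)
  readr::write_csv(
    cohort[, c("stratum", "quarter", "n_entering", "n_alive", "n_dead", "n_ltfu")],
    path
  )
  invisible(path)
}

#' Derive quarterly Markov transition probabilities
#'
#' Converts disposition counts into the conditional per-quarter probability
#' triple (alive/active, dead, LTFU), each conditional on being alive and
#' active at the start of the quarter. Two rounding conventions are provided:
#'
#' * `"percentages"` (default): each ratio is rounded to one decimal place in
#'   percent before division by 100, matching the precision at which such
#'   tables are conventionally published; triples whose rounded components sum
#'   to within 1e-3 of 1 are renormalized proportionally, larger deviations
#'   are an error. Reproduction runs of the published analysis use this mode,
#'   which recovers the original results most closely (the upstream analysis
#'   evidently consumed rounded inputs).
#' * `"counts"`: exact division of the raw counts; the mode of choice for new
#'   data.
#'
#' @param cohort a validated cohort tibble (any number of strata).
#' @param mode `"percentages"` or `"counts"` (may be abbreviated).
#' @return a tibble with columns `stratum`, `quarter`, `p_alive`, `p_dead`,
#'   `p_ltfu`; one row per stratum-quarter, each triple summing to 1.
#' @export
#' @examples
#' derive_transitions(zambia_cohort(), mode = "percentages")
derive_transitions <- function(cohort, mode = c("percentages", "counts")) {
  mode <- match.arg(mode)
  cohort <- validate_cohort_table(cohort)
  bad <- which(cohort$n_entering == 0)
  if (length(bad) > 0) {
    abort(
      sprintf(
        "no patients entering stratum '%s', quarter %d: conditional probabilities undefined",
        cohort$stratum[bad[1]], cohort$quarter[bad[1]]
      ),
      class = "nutricea_validation_error"
    )
  }
  tr <- cohort %>%
    mutate(
      p_alive = .data$n_alive / .data$n_entering,
      p_dead = .data$n_dead / .data$n_entering,
      p_ltfu = .data$n_ltfu / .data$n_entering
    )
  if (mode == "percentages") {
    tr <- tr %>%
      mutate(across(c("p_alive", "p_dead", "p_ltfu"), ~ round(.x, 3)))
    tot <- tr$p_alive + tr$p_dead + tr$p_ltfu
    off <- which(abs(tot - 1) > 1e-3 + 1e-9)
    if (length(off) > 0) {
      abort(
        sprintf(
          "rounded percentages for stratum '%s', quarter %d deviate from 100%% by more than 0.1 points",
          tr$stratum[off[1]], tr$quarter[off[1]]
        ),
        class = "nutricea_validation_error"
      )
    }
    tr <- tr %>%
      mutate(across(c("p_alive", "p_dead", "p_ltfu"), ~ .x / tot))
  }
  tr %>% select("stratum", "quarter", "p_alive", "p_dead", "p_ltfu")
}

#' Cumulative cohort disposition
#'
#' Fractions of the original (quarter-1) cohort that are alive/active, dead,
#' and lost to follow-up by the end of a given quarter. Computed from raw
#' counts, so the alive fraction equals the product of per-quarter raw-count
#' survival probabilities.
#'
#' @param cohort a validated cohort tibble.
#' @param through_quarter quarter (inclusive) at which to take stock.
#' @return a tibble with columns `stratum`, `through_quarter`, `alive`,
#'   `dead`, `ltfu`; the three fractions sum to 1.
#' @export
#' @examples
#' cumulative_disposition(zambia_cohort(), through_quarter = 2)
cumulative_disposition <- function(cohort, through_quarter) {
  cohort <- validate_cohort_table(cohort)
  if (length(through_quarter) != 1 || !(through_quarter %in% cohort$quarter)) {
    abort("through_quarter must be a single quarter present in the table",
      class = "nutricea_validation_error"
    )
  }
  cohort %>%
    group_by(.data$stratum) %>%
    summarise(
      through_quarter = as.integer(through_quarter),
      alive = .data$n_alive[through_quarter] / .data$n_entering[1],
      dead = sum(.data$n_dead[seq_len(through_quarter)]) / .data$n_entering[1],
      ltfu = sum(.data$n_ltfu[seq_len(through_quarter)]) / .data$n_entering[1],
      .groups = "drop"
    )
}

# Internal: extract the 2-cycle transition matrix rows for one stratum,
# ordered Q1, Q2. Errors if fewer than 2 quarters are available.
.stratum_transitions <- function(transitions, stratum) {
  tr <- transitions[transitions$stratum == stratum & transitions$quarter <= 2L, ]
  if (nrow(tr) < 2) {
    abort(
      sprintf("stratum '%s' needs at least 2 quarters for the 6-month model", stratum),
      class = "nutricea_validation_error"
    )
  }
  tr[order(tr$quarter), ]
}
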