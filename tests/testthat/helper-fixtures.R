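# Shared fixture builders. Everything is constructed in code; the only file
# fixtures are the packaged CSVs.

historical_cohort <- function() zambia_cohort()

base_econ <- function() econ_params()

# A tiny two-quarter, single-stratum cohort with hand-checkable counts.
toy_cohort <- function(stratum = "toy") {
  tibble::tibble(
    stratum = stratum,
    quarter = 1:2,
    n_entering = c(100, 80),
    n_alive = c(80, 60),
    n_dead = c(12, 8),
    n_ltfu = c(8, 12)
  )
}

# A 2-row transition tibble from explicit probability triples.
make_transitions <- function(q1, q2, stratum = "toy") {
  tibble::tibble(
    stratum = stratum,
    quarter = 1:2,
    p_alive = c(q1[1], q2[1]),
    p_dead = c(q1[2], q2[2]),
    p_ltfu = c(q1[3], q2[3])
  )
}

# Random valid 2-quarter transitions (dirichlet-ish via normalized uniforms,
# kept away from p_alive = 0 so DALYs stay positive).
random_transitions <- function() {
  draw <- function() {
    x <- c(runif(1, 0.3, 1), runif(2, 0, 0.35))
    x / sum(x)
  }
  make_transitions(draw(), draw())
}

# Analytic mean and variance of the per-patient cost distribution under the
# two-cycle model: a patient costs q (exits in Q1), 2q (exits in Q2), or the
# full lifetime cost (survives both cycles).
patient_cost_moments <- function(trans2, econ) {
  q <- econ$quarterly_art_cost
  lt <- econ$lifetime_cost_per_survivor
  p_a1 <- trans2$p_alive[1]
  p_a2 <- trans2$p_alive[2]
  probs <- c(1 - p_a1, p_a1 * (1 - p_a2), p_a1 * p_a2)
  vals <- c(q, 2 * q, lt)
  m <- sum(probs * vals)
  list(mean = m, var = sum(probs * vals^2) - m^2)
}
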