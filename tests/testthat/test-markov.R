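test_that("economic parameter invariants are enforced", {
  econ <- econ_params()
  expect_equal(econ$quarterly_art_cost, 556 / 4)
  expect_error(econ_params(annual_art_cost = -5), class = "nutricea_validation_error")
  expect_error(econ_params(lifetime_cost_per_survivor = 200),
    class = "nutricea_validation_error"
  )
  expect_output(print(econ), "139.00")
})

test_that("the engine matches the hand-spreadsheet oracle on the severe stratum", {
  # oracle, computed independently from the published one-decimal inputs:
  #   survival = 0.716 * 0.858                       = 0.614328
  #   cost     = 139 * 1.716 + 0.614328 * (6118-278) = 3826.19952
  #   dalys    = 0.614328 * 7.3                      = 4.4845944
  tr <- make_transitions(c(0.716, 0.173, 0.111), c(0.858, 0.050, 0.092))
  out <- run_cohort_model(tr, base_econ())
  expect_equal(out$six_month_survival, 0.614328, tolerance = 1e-12)
  expect_equal(out$quarterly_exposure, 1.716, tolerance = 1e-12)
  expect_equal(out$expected_cost, 3826.19952, tolerance = 1e-9)
  expect_equal(out$expected_dalys, 4.4845944, tolerance = 1e-12)
  expect_equal(cost_per_daly(out), 853.187, tolerance = 1e-4)
})

test_that("degenerate cohorts hit the model boundaries", {
  econ <- base_econ()
  everyone <- run_cohort_model(make_transitions(c(1, 0, 0), c(1, 0, 0)), econ)
  expect_equal(everyone$six_month_survival, 1)
  expect_equal(everyone$expected_cost, econ$lifetime_cost_per_survivor)
  expect_equal(everyone$expected_dalys, econ$dalys_per_survivor)

  nobody <- run_cohort_model(make_transitions(c(0, 1, 0), c(1, 0, 0)), econ)
  expect_equal(nobody$six_month_survival, 0)
  expect_equal(nobody$expected_cost, econ$quarterly_art_cost)
  expect_equal(nobody$expected_dalys, 0)
  expect_error(cost_per_daly(nobody), "undefined", class = "nutricea_validation_error")

  expect_error(run_cohort_model(make_transitions(c(1, 0, 0), c(1, 0, 0))[1, ], econ),
    class = "nutricea_validation_error"
  )
})

test_that("cost per DALY is a plain ratio", {
  out <- run_cohort_model(make_transitions(c(1, 0, 0), c(1, 0, 0)),
    econ_params(annual_art_cost = 100, lifetime_cost_per_survivor = 730, dalys_per_survivor = 7.3)
  )
  expect_equal(cost_per_daly(out), 100)
  expect_equal(cost_per_daly(out, extra_cost = 73), 110)
})

test_that("expected DALYs never increase when mortality worsens", {
  tr <- make_transitions(c(0.716, 0.173, 0.111), c(0.858, 0.050, 0.092))
  econ <- base_econ()
  dalys <- sapply(seq(0, 0.17, by = 0.017), function(extra) {
    worse <- dplyr::mutate(tr,
      p_dead = p_dead + extra,
      p_alive = 1 - p_dead - p_ltfu
    )
    run_cohort_model(worse, econ)$expected_dalys
  })
  expect_true(all(diff(dalys) <= 0))
})

test_that("state occupancy is conserved and absorbing states never shrink", {
  set.seed(42)
  for (i in 1:25) {
    tr <- random_transitions()
    # cycle-by-cycle occupancy of the three states
    occ <- matrix(0, nrow = 3, ncol = 3, dimnames = list(c("alive", "dead", "ltfu"), NULL))
    occ[, 1] <- c(1, 0, 0)
    for (q in 1:2) {
      occ["alive", q + 1] <- occ["alive", q] * tr$p_alive[q]
      occ["dead", q + 1] <- occ["dead", q] + occ["alive", q] * tr$p_dead[q]
      occ["ltfu", q + 1] <- occ["ltfu", q] + occ["alive", q] * tr$p_ltfu[q]
    }
    expect_true(all(abs(colSums(occ) - 1) < 1e-12))
    expect_true(all(diff(occ["dead", ]) >= 0))
    expect_true(all(diff(occ["ltfu", ]) >= 0))
    expect_equal(run_cohort_model(tr, base_econ())$six_month_survival,
      unname(occ["alive", 3]),
      tolerance = 1e-12
    )
  }
})

test_that("microsimulation agrees with the analytic engine within Monte-Carlo error", {
  set.seed(99)
  n <- 20000
  econ <- base_econ()
  for (i in 1:25) {
    tr <- random_transitions()
    analytic <- run_cohort_model(tr, econ)
    sim <- simulate_patients(tr, econ, n_patients = n, seed = 1000 + i)

    mom <- patient_cost_moments(tr, econ)
    se_cost <- sqrt(mom$var / n)
    expect_lt(abs(sim$expected_cost - analytic$expected_cost), 4 * se_cost + 1e-9)

    p <- analytic$six_month_survival
    se_surv <- sqrt(p * (1 - p) / n)
    expect_lt(abs(sim$six_month_survival - p), 4 * se_surv + 1e-9)
  }
})

test_that("microsimulation is exact in the deterministic case and reproducible", {
  tr <- make_transitions(c(1, 0, 0), c(1, 0, 0))
  econ <- base_econ()
  sim <- simulate_patients(tr, econ, n_patients = 500, seed = 5)
  analytic <- run_cohort_model(tr, econ)
  expect_equal(sim$expected_cost, analytic$expected_cost)
  expect_equal(sim$six_month_survival, 1)

  tr <- make_transitions(c(0.7, 0.2, 0.1), c(0.85, 0.05, 0.10))
  a <- simulate_patients(tr, econ, 2000, seed = 11)
  b <- simulate_patients(tr, econ, 2000, seed = 11)
  expect_identical(a, b)
})
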