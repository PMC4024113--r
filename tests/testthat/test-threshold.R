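test_that("proportional effects rescale death and LTFU and renormalize to alive", {
  tr <- make_transitions(c(0.716, 0.173, 0.111), c(0.858, 0.050, 0.092))
  adj <- apply_effect(tr, 0.2, 0.2)
  expect_equal(
    c(adj$p_alive[1], adj$p_dead[1], adj$p_ltfu[1]),
    c(0.7728, 0.1384, 0.0888),
    tolerance = 1e-12
  )
  expect_identical(apply_effect(tr, 0, 0), tr)
  perfect <- apply_effect(tr, 1, 1)
  expect_equal(perfect$p_alive, c(1, 1))
  expect_true(all(abs(adj$p_alive + adj$p_dead + adj$p_ltfu - 1) < 1e-12))
  expect_error(apply_effect(tr, 1.2, 0), class = "nutricea_validation_error")
})

test_that("WTP benchmarks order by malnutrition severity and hit a closed form", {
  wtp <- willingness_to_pay(historical_cohort(), base_econ())
  w <- setNames(wtp$wtp, wtp$stratum)
  # the severest stratum accrues the most cost per eventual survivor
  expect_true(w["<16.0"] > w["16.00-16.99"])
  expect_true(w["16.00-16.99"] > w["17.00-18.49"])

  # closed form: with full survival, WTP = lifetime cost / DALYs
  sure <- tibble::tibble(
    stratum = "s", quarter = 1:2,
    n_entering = 10, n_alive = 10, n_dead = 0, n_ltfu = 0
  )
  econ <- econ_params(lifetime_cost_per_survivor = 7300, dalys_per_survivor = 7.3)
  expect_equal(willingness_to_pay(sure, econ)$wtp, 1000)
})

test_that("a zero-effect intervention admits exactly zero supplement spend", {
  res <- max_supplement_cost(historical_cohort(), base_econ(), r_mort = 0, r_ltfu = 0)
  expect_equal(res$s_star, rep(0, nrow(res)), tolerance = 1e-12)
})

test_that("plugging S* back in restores parity with the stratum WTP", {
  cohort <- historical_cohort()
  econ <- base_econ()
  tr <- derive_transitions(cohort)
  wtp <- willingness_to_pay(cohort, econ)
  grid <- expand.grid(r_mort = c(0.1, 0.2, 0.5), r_ltfu = c(0, 0.3), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    res <- max_supplement_cost(cohort, econ, grid$r_mort[i], grid$r_ltfu[i])
    for (s in res$stratum) {
      adj <- apply_effect(dplyr::filter(tr, stratum == s, quarter <= 2),
        grid$r_mort[i], grid$r_ltfu[i]
      )
      out <- run_cohort_model(adj, econ)
      combined <- cost_per_daly(out,
        extra_cost = res$s_star[res$stratum == s] * out$supplement_exposure
      )
      expect_equal(combined, wtp$wtp[wtp$stratum == s], tolerance = 1e-9)
    }
  }
})

test_that("threshold prices are monotone in both effect sizes", {
  cohort <- dplyr::filter(historical_cohort(), stratum == "<16.0")
  econ <- base_econ()
  along_mort <- sapply(seq(0, 1, by = 0.1), function(r) {
    max_supplement_cost(cohort, econ, r, 0.2)$s_star
  })
  along_ltfu <- sapply(seq(0, 1, by = 0.1), function(r) {
    max_supplement_cost(cohort, econ, 0.2, r)$s_star
  })
  expect_true(all(diff(along_mort) >= 0))
  expect_true(all(diff(along_ltfu) >= 0))
})

test_that("the scenario matrix reproduces the published threshold table", {
  sc <- scenario_table(historical_cohort(), base_econ())
  expect_equal(sc$r_mort, c(0.2, 0, 0.2, 0.5))
  expect_equal(sc$r_ltfu, c(0, 0.2, 0.2, 0.5))
  get <- function(row, col) sc[[col]][row]
  # published: 5.49 3.03 1.94 / 5.48 3.83 3.23 / 10.99 6.86 5.28 / 27.48 17.20 13.01
  expect_equal(get(1, "<16.0"), 5.49, tolerance = 0.03)
  expect_equal(get(2, "<16.0"), 5.48, tolerance = 0.03)
  expect_equal(get(3, "<16.0"), 10.99, tolerance = 0.03)
  expect_equal(get(4, "<16.0"), 27.48, tolerance = 0.03)
  expect_equal(get(3, "16.00-16.99"), 6.86, tolerance = 0.03)
  expect_equal(get(4, "16.00-16.99"), 17.20, tolerance = 0.03)
  expect_equal(get(1, "17.00-18.49"), 1.94, tolerance = 0.03)

  # near-symmetry of the two single-endpoint scenarios in the severe stratum
  expect_lt(abs(get(1, "<16.0") - get(2, "<16.0")), 0.10)

  expect_error(
    scenario_table(dplyr::filter(historical_cohort(), stratum == "<16.0"), base_econ()),
    "missing", class = "nutricea_validation_error"
  )
})

test_that("the retention surface anchors match the published gains", {
  surf <- retention_surface(historical_cohort(),
    r_mort_grid = c(0, 0.5), r_ltfu_grid = c(0, 0.5)
  )
  gain <- function(s) {
    at <- function(rm, rl) {
      dplyr::filter(surf, stratum == s, r_mort == rm, r_ltfu == rl)$pct_alive
    }
    at(0.5, 0.5) - at(0, 0)
  }
  expect_lt(abs(gain("<16.0") - 18), 1) # published: ~18 more per 100 patients
  expect_lt(abs(gain("17.00-18.49") - 10), 1) # published: ~10 more per 100

  # the (0,0) cell is the historical six-month retention
  hist <- cumulative_disposition(historical_cohort(), 2)
  for (s in malnourished_strata()) {
    expect_equal(
      dplyr::filter(surf, stratum == s, r_mort == 0, r_ltfu == 0)$pct_alive,
      100 * dplyr::filter(hist, stratum == s)$alive,
      tolerance = 0.005 # percentage-mode rounding vs raw counts
    )
  }
})

test_that("parity frontiers invert the threshold solver", {
  cohort <- dplyr::filter(historical_cohort(), stratum == "<16.0")
  econ <- base_econ()
  s_star <- max_supplement_cost(cohort, econ, 0.2, 0.2)$s_star

  fr <- parity_frontier(cohort, econ, supplement_cost = s_star, resolution = 0.05)
  expect_true(all(fr$stratum == "<16.0"))
  at_02 <- dplyr::filter(fr, abs(r_mort - 0.2) < 1e-9)
  expect_equal(at_02$r_ltfu, 0.2, tolerance = 1e-4)

  # r_ltfu decreases as r_mort picks up more of the burden
  expect_true(all(diff(fr$r_ltfu) <= 1e-9))

  # a free supplement needs no effect at all
  fr0 <- parity_frontier(cohort, econ, supplement_cost = 0, resolution = 0.25)
  expect_equal(nrow(fr0), 1)
  expect_equal(c(fr0$r_mort, fr0$r_ltfu), c(0, 0))
})

test_that("the fitted CEA object supports tidy, glance, print and autoplot", {
  fit <- fit_cea(historical_cohort(), base_econ())
  td <- tidy(fit)
  expect_true(all(c("stratum", "six_month_survival", "wtp") %in% names(td)))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$n_strata, 4)
  expect_equal(gl$starting_patients, 5096 + 4439 + 9712 + 39133)
  expect_output(print(fit), "Willingness-to-pay")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
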