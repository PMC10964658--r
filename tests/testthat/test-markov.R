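test_that("transition matrices are row-stochastic with an absorbing dead state", {
  p <- base_case_parameters()
  tr <- p$transitions$savr
  m <- transition_matrix(5, tr, q_background = 0.01)
  expect_equal(rowSums(m), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(m["dead", ]), c(0, 0, 0, 1))
  expect_true(all(m >= 0 & m <= 1))
  # chronic states: no return to alive-and-well
  expect_equal(m["af", "aw"], 0)
  expect_equal(unname(m["ds", c("aw", "af")]), c(0, 0))
})

test_that("zero transitions and zero mortality give the identity matrix", {
  p <- make_test_params()
  m <- transition_matrix(0, p$transitions$tavi, q_background = 0)
  expect_equal(unname(m), diag(4))
})

test_that("AF/DS transition rates are constant from year 2 onwards", {
  p <- base_case_parameters()
  tr <- p$transitions$tavi
  m3 <- transition_matrix(30, tr, q_background = 0.008)  # year 3
  m5 <- transition_matrix(55, tr, q_background = 0.008)  # year 5
  expect_equal(m3, m5)
})

test_that("competing exits exceeding one raise an informative error", {
  p <- make_test_params()
  tr <- p$transitions$tavi
  tr$aw_to_af$year1 <- 0.5
  tr$aw_to_ds$year1 <- 0.4
  expect_error(transition_matrix(0, tr, q_background = 0.2), "exceed 1")
})

test_that("cohort trace conserves probability with absorbing death and exact ages", {
  for (seed in c(2, 11, 29)) {
    p <- random_parameter_set(seed)
    tr <- run_cohort(p, "savr")
    expect_equal(tr$aw + tr$af + tr$ds + tr$dead, rep(1, nrow(tr)),
                 tolerance = 1e-12)
    expect_true(all(diff(tr$dead) >= -1e-15))
    expect_equal(tr$age, p$cohort$start_age + tr$cycle / 12)
    expect_true(all(tr$flow_af[-nrow(tr)] >= 0))
    expect_true(all(tr$flow_ds[-nrow(tr)] >= 0))
  }
})

test_that("zero mortality and zero transitions leave occupancy constant", {
  p <- make_test_params(horizon = 50)
  tr <- run_cohort(p, "tavi")
  expect_equal(nrow(tr), 601)
  expect_equal(tr$aw, rep(1, 601))
})

test_that("a zero-year horizon yields only the acute distribution", {
  p <- make_test_params(horizon = 0)
  tr <- run_cohort(p, "tavi")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$aw, 1)
})

test_that("median survival interpolates and flags censoring", {
  p <- make_test_params()  # immortal cohort
  ms <- median_survival(run_cohort(p, "tavi"))
  expect_true(is.na(ms))
  expect_true(attr(ms, "censored"))
  # constant monthly death probability: geometric closed form
  pm <- 0.01
  q_annual <- 1 - (1 - pm)^12
  p2 <- make_test_params(q_annual = q_annual, start_age = 60, horizon = 40)
  ms2 <- median_survival(run_cohort(p2, "tavi"))
  expect_equal(ms2, log(0.5) / log(0.99) / 12, tolerance = 0.01)
  expect_equal(log(0.5) / log(0.99) / 12, 5.74, tolerance = 1e-2)
})

test_that("cohort engine agrees with an independent microsimulation", {
  p <- base_case_parameters()
  n_paths <- 200000
  for (arm in c("tavi", "savr")) {
    tr <- run_cohort(p, arm)
    sim <- microsimulate(p, arm, n_paths = n_paths, seed = 7)
    idx <- seq(1, nrow(tr), by = 10)
    for (s in c("aw", "af", "ds", "dead")) {
      prob <- tr[[s]][idx]
      phat <- sim[idx, s]
      tol <- 3 * sqrt(prob * (1 - prob) / n_paths) + 3 / n_paths
      expect_true(all(abs(phat - prob) <= tol),
                  label = sprintf("engine vs microsim for state %s (%s)", s, arm))
    }
  }
})

test_that("engine/microsimulation equivalence holds on random parameter sets", {
  for (seed in c(3, 17)) {
    p <- random_parameter_set(seed)
    p$cohort$horizon_years <- 20
    tr <- run_cohort(p, "tavi")
    sim <- microsimulate(p, "tavi", n_paths = 40000, seed = seed + 100)
    idx <- seq(1, nrow(tr), by = 10)
    for (s in c("aw", "dead")) {
      prob <- tr[[s]][idx]
      tol <- 4 * sqrt(prob * (1 - prob) / 40000) + 4 / 40000
      expect_true(all(abs(sim[idx, s] - prob) <= tol),
                  label = sprintf("random set %d state %s", seed, s))
    }
  }
})
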