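test_that("zero discount rates make discounted and undiscounted totals equal", {
  p <- random_parameter_set(5)
  p$discount$cost_rate <- 0
  p$discount$effect_rate <- 0
  res <- run_arm(p, "tavi")
  expect_equal(res$categories$discounted, res$categories$undiscounted,
               tolerance = 1e-9)
  expect_equal(res$qalys, res$qalys_undiscounted, tolerance = 1e-9)
})

test_that("category totals are additive", {
  for (seed in c(1, 8)) {
    p <- random_parameter_set(seed)
    res <- run_arm(p, "savr")
    expect_equal(res$total_cost, sum(res$categories$discounted), tolerance = 1e-6)
    expect_equal(res$categories$discounted[res$categories$category == "death"], 0)
  }
})

test_that("two years of perfect health in alive-and-well gives exactly 2 QALYs", {
  p <- make_test_params(horizon = 2)
  res <- run_arm(p, "tavi")
  expect_equal(res$qalys, 2)
  expect_equal(res$life_years, 2)
})

test_that("a unit entry into disabling stroke at time zero costs the month-1 total", {
  p <- make_test_params(horizon = 1)
  p$acute$tavi$disabling_stroke <- 1
  p$costs$ds_monthly <- 0
  p$costs$ds_caregiver_monthly <- 0
  p$costs$ds_caregiver_month1 <- 0
  res <- run_arm(p, "tavi")
  ds_cost <- res$categories$discounted[res$categories$category == "ds"]
  expect_equal(ds_cost, 15784)
})

test_that("raising a discount rate never increases the discounted total", {
  p <- base_case_parameters()
  costs <- vapply(c(0, 0.02, 0.04, 0.08), function(r) {
    p$discount$cost_rate <- r
    run_arm(p, "tavi")$total_cost
  }, numeric(1))
  expect_true(all(diff(costs) < 0))
  qalys <- vapply(c(0, 0.015, 0.05), function(r) {
    p$discount$effect_rate <- r
    run_arm(p, "tavi")$qalys
  }, numeric(1))
  expect_true(all(diff(qalys) < 0))
})

test_that("QALYs never exceed life years when utilities are at most 1", {
  for (seed in c(4, 9, 23)) {
    p <- random_parameter_set(seed)
    p$discount$effect_rate <- 0
    res <- run_arm(p, "tavi")
    expect_lte(res$qalys, res$life_years + 1e-12)
  }
})

test_that("incremental statistics satisfy their algebraic identities exactly", {
  cases <- list(
    c(dc = 4742, dq = 0.88714, lambda = 50000),
    c(dc = -1200.5, dq = 0.31, lambda = 20000),
    c(dc = 950, dq = -0.02, lambda = 80000)
  )
  for (cs in cases) {
    a <- list(total_cost = 1000 + cs[["dc"]], qalys = 5 + cs[["dq"]],
              life_years = 6, median_survival = 5)
    b <- list(total_cost = 1000, qalys = 5, life_years = 6, median_survival = 5)
    inc <- incremental(a, b, lambda = cs[["lambda"]])
    expect_identical(inc$inmb, cs[["lambda"]] * inc$delta_qaly - inc$delta_cost)
    expect_identical(inc$inhb, inc$delta_qaly - inc$delta_cost / cs[["lambda"]])
    expect_equal(inc$icer * inc$delta_qaly, inc$delta_cost, tolerance = 1e-12)
  }
})

test_that("published worked example: increments imply the printed ICER and benefits", {
  a <- list(total_cost = 44149, qalys = 9.50714, life_years = 12.67, median_survival = 15)
  b <- list(total_cost = 39407, qalys = 8.62, life_years = 11.89, median_survival = 13.17)
  # delta_qaly = 0.88714, derived as (39,615 + 4,742) / 50,000 from the
  # printed net monetary benefit and incremental cost
  inc <- incremental(a, b, lambda = 50000)
  expect_equal(inc$icer, 4742 / 0.88714, tolerance = 1e-9)
  expect_equal(inc$icer, 5346, tolerance = 1e-3)
  expect_equal(inc$inmb, 39615, tolerance = 1e-6)
  expect_equal(inc$inhb, 0.79, tolerance = 5e-3)
})

test_that("dominance markers follow the cost/effect quadrants", {
  mk <- function(dc, dq) incremental(
    list(total_cost = dc, qalys = dq, life_years = 0, median_survival = 1),
    list(total_cost = 0, qalys = 0, life_years = 0, median_survival = 1), 50000)
  expect_equal(mk(-100, 0.1)$dominance, "dominant")
  expect_equal(mk(100, -0.1)$dominance, "dominated")
  expect_equal(mk(100, 0.1)$dominance, "none")
  z <- mk(0, 0)
  expect_equal(z$dominance, "undefined")
  expect_true(is.na(z$icer))
  expect_equal(z$inmb, 0)
  expect_equal(z$inhb, 0)
})

test_that("tidy and glance return well-formed tibbles", {
  res <- run_base_case(base_case_parameters())
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16)  # 8 categories x 2 arms
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$delta_cost, res$incremental$delta_cost)
})
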