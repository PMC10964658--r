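test_that("per-cycle death probability matches the closed form", {
  p <- make_test_params(q_annual = 0.12)
  lt <- life_table_from_spec(p)
  # monthly cycle: 1 - 0.88^(1/12)
  expect_equal(cycle_death_probability(60, p$cohort, lt, rr = 1),
               1 - 0.88^(1 / 12), tolerance = 1e-12)
  expect_equal(1 - 0.88^(1 / 12), 0.01060, tolerance = 1e-3)
  # relative risks compose on the complement-power scale
  expect_equal(cycle_death_probability(60, p$cohort, lt, rr = 2),
               1 - (0.88^(1 / 12))^2, tolerance = 1e-12)
  expect_equal(cycle_death_probability(60, p$cohort, lt, rr = 0), 0)
  # at/beyond the terminal age the probability is 1
  expect_equal(cycle_death_probability(120, p$cohort, lt, rr = 1), 1)
  expect_equal(cycle_death_probability(125, p$cohort, lt, rr = 1), 1)
})

test_that("chaining monthly cycles reproduces annual survival to 1e-12", {
  p <- base_case_parameters()
  lt <- life_table_from_spec(p)
  for (age in c(73, 80, 95)) {
    q_annual <- 1 - prod(rep(1 - cycle_death_probability(age, p$cohort, lt, 1), 12))
    # annual cycle length recovers the table value directly
    cohort_annual <- p$cohort
    cohort_annual$cycle_length_months <- 12
    expect_equal(q_annual,
                 cycle_death_probability(age, cohort_annual, lt, 1),
                 tolerance = 1e-12)
  }
})

test_that("synthetic life table is monotone with q = 1 at the terminal age", {
  lt <- synthetic_life_table(makeham_a = 0.001, gompertz_b = 5e-5,
                             gompertz_c = 1.1, min_age = 55, terminal_age = 110)
  expect_setequal(unique(lt$sex), c("male", "female"))
  for (s in c("male", "female")) {
    q <- lt$annual_death_probability[lt$sex == s]
    expect_true(all(diff(q) >= 0))
    expect_equal(q[length(q)], 1)
    expect_true(all(q >= 0 & q <= 1))
  }
  # women carry the lower hazard
  expect_true(all(lt$annual_death_probability[lt$sex == "female"] <=
                    lt$annual_death_probability[lt$sex == "male"]))
})

test_that("life-table reader round-trips the delimited format", {
  lt <- read_life_table(system.file("extdata", "lifetable_synthetic.tsv",
                                    package = "tavicea"))
  expect_named(lt, c("age", "sex", "annual_death_probability"))
  p <- base_case_parameters()
  expect_equal(dplyr::arrange(life_table_from_spec(p), sex, age)$annual_death_probability,
               lt$annual_death_probability, tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("age\tsex\twrong_column\n60\tmale\t0.1", bad)
  expect_error(read_life_table(bad), "annual_death_probability")
})

test_that("flat life table gives geometric life expectancy within one cycle", {
  q <- 0.15
  p <- make_test_params(q_annual = q, start_age = 60, horizon = 50)
  res <- run_arm(p, "tavi")
  # E[T] for a per-month death probability pm, with mid-cycle accrual
  pm <- 1 - (1 - q)^(1 / 12)
  e_closed <- (1 / pm - 0.5) / 12
  expect_equal(res$life_years, e_closed, tolerance = 1 / 12)
  # geometric median from the closed form
  tr <- run_cohort(p, "tavi")
  expect_equal(median_survival(tr), log(0.5) / log(1 - pm) / 12,
               tolerance = 0.01)
})

test_that("capped survivor never exceeds the population survivor curve", {
  p <- make_test_params(q_annual = 0.05, start_age = 70, horizon = 30)
  p$life_table$gompertz_b <- 1e-4  # add real age structure
  lt <- life_table_from_spec(p)
  models <- list(
    survival_model("exponential", list(rate = 0.001)),
    survival_model("exponential", list(rate = 0.2), hr = 0.5),
    survival_model("weibull", list(shape = 1.4, scale = 12)),
    survival_model("gompertz", list(shape = 0.09, rate = 0.02)),
    survival_model("lognormal", list(meanlog = 2.5, sdlog = 0.6)),
    survival_model("loglogistic", list(shape = 2, scale = 14))
  )
  # brute-force population survivor from the annual table
  pop <- cumprod(1 - cycle_death_probability(
    70 + (seq_len(360) - 1) / 12, p$cohort, lt, 1))
  for (m in models) {
    cs <- capped_survivor(m, lt, p$cohort)
    expect_true(all(cs$survivor <= pop + 1e-12))
    expect_true(all(diff(cs$survivor) <= 1e-15))
    expect_true(all(cs$q >= cs$q_population - 1e-12))
  }
  # a zero-rate model degenerates to pure population mortality
  cs0 <- capped_survivor(survival_model("exponential", list(rate = 0)), lt, p$cohort)
  expect_equal(cs0$survivor, pop, tolerance = 1e-12)
  # Weibull with shape 1 equals exponential with the same scale, pre-capping
  cs_w <- capped_survivor(survival_model("weibull", list(shape = 1, scale = 10)),
                          lt, p$cohort)
  cs_e <- capped_survivor(survival_model("exponential", list(rate = 0.1)),
                          lt, p$cohort)
  expect_equal(cs_w$q_parametric, cs_e$q_parametric, tolerance = 1e-12)
})

test_that("parametric cumulative hazards agree with flexsurv", {
  skip_if_not_installed("flexsurv")
  t <- c(0.5, 2, 7, 20)
  H <- function(m) tavicea:::cumulative_hazard(m, t)
  expect_equal(H(survival_model("gompertz", list(shape = 0.1, rate = 0.03))),
               flexsurv::Hgompertz(t, shape = 0.1, rate = 0.03), tolerance = 1e-10)
  expect_equal(H(survival_model("loglogistic", list(shape = 2, scale = 14))),
               -log(1 - flexsurv::pllogis(t, shape = 2, scale = 14)), tolerance = 1e-10)
  expect_equal(H(survival_model("lognormal", list(meanlog = 2.5, sdlog = 0.6))),
               -plnorm(t, 2.5, 0.6, lower.tail = FALSE, log.p = TRUE), tolerance = 1e-10)
})
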