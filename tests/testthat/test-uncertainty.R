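test_that("degenerate distributions reproduce the base case in every draw", {
  p <- base_case_parameters()
  dists <- psa_distributions(p)[1:5, ]
  dists$sd <- 0
  psa <- run_psa(p, n = 4, seed = 3, distributions = dists)
  base <- run_base_case(p)
  expect_equal(psa$delta_cost, rep(base$incremental$delta_cost, 4))
  expect_equal(psa$delta_qaly, rep(base$incremental$delta_qaly, 4))
})

test_that("the PSA is reproducible under a fixed seed", {
  p <- base_case_parameters()
  psa1 <- run_psa(p, n = 12, seed = 99)
  psa2 <- run_psa(p, n = 12, seed = 99)
  expect_equal(as.data.frame(psa1), as.data.frame(psa2))
  psa3 <- run_psa(p, n = 12, seed = 100)
  expect_false(isTRUE(all.equal(psa1$delta_cost, psa3$delta_cost)))
})

test_that("parameter streams are independent of the rest of the catalogue", {
  p <- base_case_parameters()
  d_all <- psa_distributions(p)
  d_sub <- d_all[d_all$parameter != "costs$procedure$tavi", ]
  psa_all <- run_psa(p, n = 6, seed = 7, distributions = d_all)
  psa_sub <- run_psa(p, n = 6, seed = 7, distributions = d_sub)
  # removing one parameter leaves the others' draws unchanged: SAVR arm
  # results only depend on SAVR/shared parameters, none of which moved
  expect_equal(psa_all$savr_cost, psa_sub$savr_cost, tolerance = 1e-9)
})

test_that("CEAC is a proper probability curve with threshold-free dominance", {
  p <- base_case_parameters()
  psa <- run_psa(p, n = 60, seed = 11)
  curve <- ceac(psa)
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_equal(curve$probability[curve$lambda == 0],
               mean(psa$delta_cost < 0))
  pd <- attr(curve, "prob_dominant")
  expect_true(all(pd <= curve$probability[curve$lambda > 0] + 1e-12))
  expect_equal(pd, mean(psa$delta_cost < 0 & psa$delta_qaly > 0))
})

test_that("identical draws make the CEAC a step function at the ICER", {
  psa <- structure(
    tibble::tibble(draw = 1:5, tavi_cost = 1, tavi_qaly = 1, savr_cost = 0,
                   savr_qaly = 0, delta_cost = rep(3000, 5),
                   delta_qaly = rep(0.5, 5)),
    class = c("cea_psa", class(tibble::tibble())), lambda = 50000)
  curve <- ceac(psa, lambda_grid = c(0, 5999, 6001, 50000))
  expect_equal(curve$probability, c(0, 0, 1, 1))
  expect_error(ceac(psa, lambda_grid = numeric(0)), "non-empty")
})

test_that("tornado entries are ranked by swing without loss or duplication", {
  p <- base_case_parameters()
  ranges <- default_sensitivity_ranges(p)[1:6, ]
  tor <- one_way_dsa(p, ranges)
  expect_setequal(tor$parameter, ranges$parameter)
  expect_true(all(diff(tor$swing) <= 1e-9))
  expect_true(all(tor$swing >= 0))
})

test_that("a degenerate range gives zero swing and widening never shrinks it", {
  p <- base_case_parameters()
  base_val <- p$costs$procedure$tavi
  mk_range <- function(f) tibble::tibble(parameter = "costs$procedure$tavi",
                                         low = base_val * (1 - f),
                                         high = base_val * (1 + f))
  swings <- vapply(c(0, 0.05, 0.1, 0.2), function(f) {
    one_way_dsa(p, mk_range(f))$swing
  }, numeric(1))
  expect_equal(swings[1], 0)
  expect_true(all(diff(swings) >= -1e-9))
})

test_that("tornado is most sensitive to procedure costs and starting age", {
  p <- base_case_parameters()
  tor <- one_way_dsa(p)
  top6 <- tor$parameter[1:6]
  expect_true("costs$procedure$tavi" %in% top6)
  expect_true("costs$procedure$savr" %in% top6)
  expect_true("cohort$start_age" %in% top6)
})

test_that("ranges that do not bracket the base value are rejected", {
  p <- base_case_parameters()
  bad <- tibble::tibble(parameter = "costs$procedure$tavi",
                        low = 40000, high = 50000)
  expect_error(one_way_dsa(p, bad), "costs\\$procedure\\$tavi")
})

test_that("scenario machinery: identity, catalogue errors and consistency", {
  p <- base_case_parameters()
  base <- run_base_case(p)
  sc_base <- run_scenario(p, "base")
  expect_equal(glance(sc_base), glance(base))
  expect_error(run_scenario(p, "no_such_scenario"), "available")
  # zero-discount scenario: QALYs equal their undiscounted counterpart
  sc0 <- run_scenario(p, "discount_none")
  expect_equal(sc0$tavi$qalys, sc0$tavi$qalys_undiscounted, tolerance = 1e-9)
  expect_equal(sc0$tavi$categories$discounted, sc0$tavi$categories$undiscounted,
               tolerance = 1e-9)
})

test_that("every catalogued scenario keeps TAVI below the Dutch threshold band", {
  p <- base_case_parameters()
  sc <- run_scenarios(p)
  expect_equal(nrow(sc), nrow(scenario_catalog()))
  ok <- sc$dominance == "dominant" | (!is.na(sc$icer) & sc$icer < 80000)
  expect_true(all(ok), label = paste("scenario ICERs:",
                                     paste(round(sc$icer), collapse = ", ")))
})
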