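#' Default one-way sensitivity ranges
#'
#' Low/high values for the tornado analysis. Confidence intervals for the
#' calibrated inputs are not available, so ranges are plausible bounds:
#' +/-20% around the base value for probabilities, rates, relative risks,
#' costs and decrements (clipped to valid bounds), 68-78 years for the
#' cohort starting age, and 0-6% / 0-4% for the cost and effect discount
#' rates.
#'
#' @param params A `cea_parameters` object.
#' @return A tibble with columns `parameter` (a `$`-path), `low`, `high`.
#' @export
default_sensitivity_ranges <- function(params) {
  rel <- function(path, f = 0.2, cap = Inf) {
    base <- param_get(params, path)
    tibble(parameter = path, low = base * (1 - f), high = min(base * (1 + f), cap))
  }
  bind_rows(
    rel("costs$procedure$tavi"),
    rel("costs$procedure$savr"),
    tibble(parameter = "cohort$start_age", low = 68, high = 78),
    tibble(parameter = "discount$cost_rate", low = 0, high = 0.06),
    tibble(parameter = "discount$effect_rate", low = 0, high = 0.04),
    rel("acute$tavi$death", cap = 1),
    rel("acute$savr$death", cap = 1),
    rel("acute$savr$new_treated_af", cap = 1),
    rel("acute$tavi$new_treated_af", cap = 1),
    rel("transitions$savr$rr_af"),
    rel("transitions$tavi$aw_to_af$thereafter", cap = 1),
    rel("transitions$tavi$reintervention$year22", cap = 1),
    rel("utilities$disutility_af"),
    rel("utilities$disutility_ds"),
    rel("costs$af_monthly"),
    rel("costs$ds_monthly"),
    rel("costs$reintervention")
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each parameter alone to its low and high value, re-runs both arms,
#' and records the incremental net monetary benefit at each bound. Entries
#' are ranked by descending swing `|INMB(high) - INMB(low)|`, ties broken
#' alphabetically.
#'
#' @param params A `cea_parameters` object.
#' @param ranges Range tibble as from [default_sensitivity_ranges()]; each
#'   range must bracket the base value.
#' @param lambda Willingness-to-pay threshold (Euros/QALY).
#' @return A tibble of class `cea_tornado` with columns `parameter`, `low`,
#'   `high`, `inmb_low`, `inmb_high`, `swing`; the base-case INMB is
#'   attached as attribute `base_inmb`.
#' @export
one_way_dsa <- function(params, ranges = default_sensitivity_ranges(params),
                        lambda = 50000) {
  base_vals <- vapply(ranges$parameter, function(p) param_get(params, p), numeric(1))
  bad <- ranges$low > base_vals | ranges$high < base_vals
  if (any(bad)) {
    abort(paste0("range does not bracket base value for: ",
                 paste(ranges$parameter[bad], collapse = ", ")))
  }
  inmb_at <- function(path, value) {
    p <- param_set(params, path, value)
    run_base_case(p, lambda = lambda)$incremental$inmb
  }
  res <- purrr::map2_dfr(ranges$parameter, seq_len(nrow(ranges)), function(path, i) {
    lo <- inmb_at(path, ranges$low[i])
    hi <- inmb_at(path, ranges$high[i])
    tibble(parameter = path, low = ranges$low[i], high = ranges$high[i],
           inmb_low = lo, inmb_high = hi, swing = abs(hi - lo))
  })
  res <- arrange(res, desc(.data$swing), .data$parameter)
  structure(res, class = c("cea_tornado", class(res)),
            base_inmb = run_base_case(params, lambda = lambda)$incremental$inmb,
            lambda = lambda)
}

#' Default probabilistic sensitivity distributions
#'
#' One distribution per sampled parameter: beta for probabilities and
#' utility decrements, gamma for costs, log-normal for relative risks.
#' Published confidence intervals are not available for the calibrated
#' inputs, so each distribution is centred on the base value with a +/-20%
#' plausible range read as a 95% interval (sd = range/3.92). Parameters
#' with base value 0 are kept fixed.
#'
#' @param params A `cea_parameters` object.
#' @return A tibble with columns `parameter`, `family`
#'   (`"beta"`/`"gamma"`/`"lognormal"`), `mean`, `sd`, `lower`, `upper`.
#' @export
psa_distributions <- function(params) {
  prob_paths <- c(
    unlist(lapply(ARMS, function(a) paste0("acute$", a, "$", ACUTE_FIELDS))),
    unlist(lapply(ARMS, function(a) {
      c(paste0("transitions$", a, "$", rep(c("aw_to_af", "aw_to_ds", "af_to_ds",
                                             "rehospitalization"), each = 3),
               "$", c("year1", "year2", "thereafter")),
        paste0("transitions$", a, "$reintervention$", c("early", "year22")))
    })),
    "utilities$disutility_af", "utilities$disutility_ds")
  cost_paths <- c("costs$procedure$tavi", "costs$procedure$savr",
                  "costs$reintervention", "costs$af_month1", "costs$af_monthly",
                  "costs$ds_month1", "costs$ds_monthly",
                  "costs$ds_caregiver_month1", "costs$ds_caregiver_monthly",
                  "costs$pacemaker_monthly", "costs$rehospitalization_event",
                  "costs$mi_event")
  rr_paths <- c("transitions$tavi$rr_af", "transitions$savr$rr_af",
                "transitions$tavi$rr_ds", "transitions$savr$rr_ds")
  spec <- bind_rows(
    tibble(parameter = prob_paths, family = "beta", lower = 0, upper = 1),
    tibble(parameter = cost_paths, family = "gamma", lower = 0, upper = Inf),
    tibble(parameter = rr_paths, family = "lognormal", lower = 0, upper = Inf)
  )
  spec$mean <- vapply(spec$parameter, function(p) param_get(params, p), numeric(1))
  spec$sd <- 0.4 * spec$mean / 3.92
  spec <- spec[spec$mean > 0, ]
  arrange(spec, .data$parameter)
}

# deterministic per-parameter stream seed derived from the master seed and
# the parameter's name (not its position), so adding or removing one
# parameter leaves every other stream untouched
stream_seed <- function(seed, name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 131 + c) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 48271) %% 2147483646 + 1)
}

draw_stream <- function(family, mean, sd, lower, upper, n, stream_seed) {
  if (sd <= 0) {
    return(structure(rep(mean, n), n_redraw = 0))
  }
  set.seed(stream_seed)
  sampler <- switch(family,
    beta = {
      v <- min(sd^2, mean * (1 - mean) * 0.99)  # keep a proper beta
      k <- mean * (1 - mean) / v - 1
      function(m) stats::rbeta(m, mean * k, (1 - mean) * k)
    },
    gamma = function(m) stats::rgamma(m, shape = (mean / sd)^2, rate = mean / sd^2),
    lognormal = {
      sdlog <- sqrt(log1p((sd / mean)^2))
      function(m) stats::rlnorm(m, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
    },
    abort(paste0("unknown distribution family: ", family))
  )
  draws <- sampler(n)
  n_redraw <- 0
  for (i in which(draws < lower | draws > upper)) {
    for (try in seq_len(100)) {
      d <- sampler(1)
      n_redraw <- n_redraw + 1
      if (d >= lower && d <= upper) { draws[i] <- d; break }
    }
  }
  attr(draws, "n_redraw") <- n_redraw
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo re-runs of the full two-arm pipeline with all sampled
#' parameters drawn from their distributions. Each parameter has its own
#' random stream seeded from the master seed and the parameter's name, so
#' adding or removing a parameter does not perturb the others' draws. Out-of-bounds draws are redrawn (at most 100 attempts per
#' parameter); the redraw count is recorded.
#'
#' @param params Base `cea_parameters` object.
#' @param n Number of Monte Carlo draws (default 1000).
#' @param seed Master integer seed.
#' @param distributions Distribution tibble as from [psa_distributions()].
#' @param lambda Willingness-to-pay threshold carried into summaries.
#' @return A tibble of class `cea_psa` with one row per draw: `draw`,
#'   per-arm discounted cost and QALYs, `delta_cost`, `delta_qaly`.
#'   Attributes: `seed`, `lambda`, `distributions`, `n_redraw`.
#' @export
run_psa <- function(params, n = 1000, seed = 1,
                    distributions = psa_distributions(params),
                    lambda = 50000) {
  stopifnot(n >= 1)
  distributions <- arrange(distributions, .data$parameter)
  p_count <- nrow(distributions)
  draws <- matrix(NA_real_, n, p_count)
  n_redraw <- 0
  for (j in seq_len(p_count)) {
    d <- draw_stream(distributions$family[j], distributions$mean[j],
                     distributions$sd[j], distributions$lower[j],
                     distributions$upper[j], n,
                     stream_seed(seed, distributions$parameter[j]))
    n_redraw <- n_redraw + attr(d, "n_redraw")
    draws[, j] <- d
  }
  paths <- lapply(distributions$parameter, param_path)
  run_one <- function(i) {
    p <- unclass(params)
    for (j in seq_len(p_count)) {
      p <- purrr::assign_in(p, as.list(paths[[j]]), draws[i, j])
    }
    p <- structure(p, class = "cea_parameters")
    res <- run_base_case(p, lambda = lambda)
    c(res$tavi$total_cost, res$tavi$qalys,
      res$savr$total_cost, res$savr$qalys)
  }
  m <- vapply(seq_len(n), run_one, numeric(4))
  out <- tibble(
    draw = seq_len(n),
    tavi_cost = m[1, ], tavi_qaly = m[2, ],
    savr_cost = m[3, ], savr_qaly = m[4, ],
    delta_cost = m[1, ] - m[3, ],
    delta_qaly = m[2, ] - m[4, ]
  )
  structure(out, class = c("cea_psa", class(out)),
            seed = seed, lambda = lambda, distributions = distributions,
            n_redraw = n_redraw)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws with
#' positive incremental net monetary benefit
#' (`lambda * delta_qaly - delta_cost > 0`). The probability that the
#' intervention dominates (cheaper and more effective) is threshold-free
#' and attached as attribute `prob_dominant`.
#'
#' @param psa A `cea_psa` tibble.
#' @param lambda_grid Threshold grid in Euros/QALY (default 0 to 80,000 in
#'   steps of 1,000, the Dutch reference-value range).
#' @return A tibble of class `cea_ceac` with columns `lambda`,
#'   `probability`.
#' @export
ceac <- function(psa, lambda_grid = seq(0, 80000, by = 1000)) {
  if (length(lambda_grid) == 0) abort("lambda_grid must be non-empty")
  prob <- vapply(lambda_grid, function(l) {
    mean(l * psa$delta_qaly - psa$delta_cost > 0)
  }, numeric(1))
  structure(
    tibble(lambda = lambda_grid, probability = prob),
    class = c("cea_ceac", class(tibble())),
    prob_dominant = mean(psa$delta_cost < 0 & psa$delta_qaly > 0)
  )
}
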