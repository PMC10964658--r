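#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Turns a cohort trace into per-arm totals: discounted costs by category
#' (acute, pacemaker, rehospitalization, reintervention, and the
#' alive-and-well / treated-AF / disabling-stroke state categories; death
#' costs are fixed at 0), undiscounted life years, discounted QALYs, and
#' median survival. State time uses the trapezoidal half-cycle correction
#' (average of start- and end-of-cycle occupancy); entry and event
#' expectations are costed as flows without correction. Every cash flow in
#' cycle k is discounted by \eqn{(1+r)^{-(k+0.5)/12}} (annual compound
#' factors at cycle midpoints); the acute-phase cost falls at time 0.
#' First-month premiums (AF month 1 vs later months; DS month 1 including
#' the first-month caregiver cost) attach to incident entries, including
#' the initial distribution's AF/DS mass at time 0. QALYs multiply
#' occupancy by the age-adjusted population norm minus the state decrement,
#' clamped to \[-0.5, 1\] (with a warning when clamping binds), discounted
#' at the effect rate. A year-one snapshot of the same categories (cycles
#' 0-11, plus an informational expected myocardial-infarction cost) is
#' attached for reporting parity; it is never added to the lifetime total.
#'
#' @param trace A `cea_trace` from [run_cohort()].
#' @param params The `cea_parameters` object used to produce it.
#' @param acute The matching `cea_acute` result (taken from the trace
#'   attribute when omitted).
#' @return An object of class `cea_arm_result`: a list with `arm`,
#'   `categories` (tibble: `category`, `discounted`, `undiscounted`,
#'   `year1`), `total_cost`, `life_years` (undiscounted), `qalys`
#'   (discounted), `qalys_undiscounted`, `median_survival`, `acute_cost`.
#' @export
accrue <- function(trace, params, acute = NULL) {
  if (is.null(acute)) acute <- attr(trace, "acute")
  arm <- attr(trace, "arm")
  co <- params$costs
  cohort <- params$cohort
  n <- nrow(trace) - 1
  infl <- params$meta$inflation_factor %||% 1

  cat_names <- c("acute", "pacemaker", "rehospitalization", "reintervention",
                 "aw", "af", "ds", "death")
  zero <- setNames(rep(0, length(cat_names)), cat_names)
  if (n == 0) {
    categories <- tibble(category = cat_names,
                         discounted = unname(zero), undiscounted = unname(zero),
                         year1 = unname(zero))
    categories$discounted[1] <- categories$undiscounted[1] <-
      categories$year1[1] <- acute$expected_cost * infl
    out <- list(arm = arm, categories = categories,
                total_cost = acute$expected_cost * infl,
                life_years = 0, qalys = 0, qalys_undiscounted = 0,
                median_survival = structure(NA_real_, censored = TRUE),
                acute_cost = acute$expected_cost * infl,
                year1_snapshot = NULL)
    return(structure(out, class = "cea_arm_result"))
  }

  k <- seq_len(n) - 1
  t_mid <- (k + 0.5) * cohort$cycle_length_months / 12
  dc <- (1 + params$discount$cost_rate)^(-t_mid)
  de <- (1 + params$discount$effect_rate)^(-t_mid)
  cyc_frac <- cohort$cycle_length_months / 12

  mid <- function(x) (x[k + 1] + x[k + 2]) / 2
  aw_m <- mid(trace$aw); af_m <- mid(trace$af); ds_m <- mid(trace$ds)
  alive_m <- aw_m + af_m + ds_m
  flow_af <- trace$flow_af[k + 1]
  flow_ds <- trace$flow_ds[k + 1]
  reint <- trace$reintervention[k + 1]
  rehosp <- trace$rehospitalization[k + 1]

  # per-cycle (monthly) unit costs
  af_occ_cost <- co$af_monthly
  ds_occ_cost <- co$ds_monthly + co$ds_caregiver_monthly
  af_entry_premium <- co$af_month1 - co$af_monthly
  ds_entry_premium <- (co$ds_month1 + co$ds_caregiver_month1) - ds_occ_cost
  aw_monthly <- ifelse(k < 12, co$aw_year1 / 12, co$aw_annual / 12)

  flows <- list(
    pacemaker = co$pacemaker_monthly * acute$pacemaker_fraction * alive_m,
    rehospitalization = co$rehospitalization_event * rehosp,
    reintervention = co$reintervention * reint,
    aw = aw_monthly * aw_m,
    af = af_occ_cost * af_m + af_entry_premium * flow_af,
    ds = ds_occ_cost * ds_m + ds_entry_premium * flow_ds,
    death = rep(0, n)
  )
  # initial entries from the 30-day tree incur the month-1 premium at t = 0
  init_premium_af <- af_entry_premium * acute$initial_state[["af"]]
  init_premium_ds <- ds_entry_premium * acute$initial_state[["ds"]]

  disc <- vapply(flows, function(x) sum(x * dc), numeric(1)) * infl
  undisc <- vapply(flows, function(x) sum(x), numeric(1)) * infl
  y1 <- vapply(flows, function(x) sum((x * dc)[k < 12]), numeric(1)) * infl
  add_init <- function(v) {
    v[["af"]] <- v[["af"]] + init_premium_af * infl
    v[["ds"]] <- v[["ds"]] + init_premium_ds * infl
    v
  }
  disc <- add_init(disc); undisc <- add_init(undisc); y1 <- add_init(y1)

  acute_cost <- acute$expected_cost * infl
  categories <- tibble(
    category = cat_names,
    discounted = c(acute_cost, unname(disc[cat_names[-1]])),
    undiscounted = c(acute_cost, unname(undisc[cat_names[-1]])),
    year1 = c(acute_cost, unname(y1[cat_names[-1]]))
  )

  # utilities: age-adjusted norm minus state decrement, clamped to [-0.5, 1]
  norm <- population_norm(params$utilities, cohort$start_age + t_mid,
                          cohort$fraction_female)
  u_aw <- norm
  u_af <- norm - params$utilities$disutility_af
  u_ds <- norm - params$utilities$disutility_ds
  if (any(c(u_af, u_ds) < -0.5)) {
    warn("state utility below -0.5 after decrement; clamped")
  }
  u_af <- pmax(u_af, -0.5); u_ds <- pmax(u_ds, -0.5)
  q_cycle <- (aw_m * u_aw + af_m * u_af + ds_m * u_ds) * cyc_frac

  out <- list(
    arm = arm,
    categories = categories,
    total_cost = sum(categories$discounted),
    life_years = sum(alive_m) * cyc_frac,
    qalys = sum(q_cycle * de),
    qalys_undiscounted = sum(q_cycle),
    median_survival = median_survival(trace),
    acute_cost = acute_cost,
    mi_year1_cost = params$acute[[arm]]$myocardial_infarction * co$mi_event * infl
  )
  structure(out, class = "cea_arm_result")
}

#' @export
print.cea_arm_result <- function(x, ...) {
  cat(sprintf("<cea_arm_result> %s\n", toupper(x$arm)))
  cat(sprintf("  total cost (disc.): %10.0f EUR\n", x$total_cost))
  cat(sprintf("  life years (undisc.): %6.2f   QALYs (disc.): %6.2f\n",
              x$life_years, x$qalys))
  ms <- x$median_survival
  cat(sprintf("  median survival: %s\n",
              if (is.na(ms)) "censored (beyond horizon)" else sprintf("%.2f y", ms)))
  invisible(x)
}

#' Incremental cost-effectiveness statistics
#'
#' Computes the incremental cost, incremental QALYs, ICER, and net
#' monetary/health benefit of an intervention over a comparator at a
#' willingness-to-pay threshold. The identities
#' `inmb = lambda * delta_qaly - delta_cost` and
#' `inhb = delta_qaly - delta_cost / lambda` hold exactly; the ICER is the
#' unrounded ratio, flagged `"dominant"` (cheaper and more effective),
#' `"dominated"` (costlier and less effective) or `"undefined"`
#' (`delta_qaly = 0`) where a ratio is not meaningful.
#'
#' @param intervention,comparator `cea_arm_result` objects.
#' @param lambda Willingness-to-pay threshold in Euros per QALY (> 0).
#' @return An object of class `cea_incremental` with fields `delta_cost`,
#'   `delta_qaly`, `delta_life_years`, `delta_median_survival`, `icer`,
#'   `dominance`, `inmb`, `inhb`, `lambda`.
#' @export
incremental <- function(intervention, comparator, lambda = 50000) {
  stopifnot(lambda > 0)
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$qalys - comparator$qalys
  dly <- intervention$life_years - comparator$life_years
  dms <- as.numeric(intervention$median_survival) -
    as.numeric(comparator$median_survival)
  dominance <- if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else "none"
  icer <- if (dq == 0) NA_real_ else dc / dq
  structure(
    list(delta_cost = dc, delta_qaly = dq, delta_life_years = dly,
         delta_median_survival = dms,
         icer = icer,
         dominance = if (dq == 0) "undefined" else dominance,
         inmb = lambda * dq - dc,
         inhb = dq - dc / lambda,
         lambda = lambda),
    class = "cea_incremental"
  )
}

#' @export
print.cea_incremental <- function(x, ...) {
  cat("<cea_incremental>\n")
  cat(sprintf("  delta cost: %8.0f EUR   delta QALY: %.4f\n", x$delta_cost, x$delta_qaly))
  cat(sprintf("  ICER: %s\n",
              if (x$dominance == "dominant") "dominant (cheaper, more effective)"
              else if (x$dominance == "dominated") "dominated"
              else if (is.na(x$icer)) "undefined (delta QALY = 0)"
              else sprintf("%.0f EUR/QALY", x$icer)))
  cat(sprintf("  INMB at %0.f EUR/QALY: %8.0f EUR   INHB: %.3f QALY\n",
              x$lambda, x$inmb, x$inhb))
  invisible(x)
}

#' Run one treatment arm end to end
#'
#' Decision tree, cohort propagation and accrual for a single arm.
#'
#' @inheritParams run_cohort
#' @param include_ae_costs Passed to [run_decision_tree()].
#' @return A `cea_arm_result`.
#' @export
run_arm <- function(params, arm = c("tavi", "savr"),
                    include_ae_costs = FALSE, table = NULL) {
  arm <- match.arg(arm)
  acute <- run_decision_tree(params, arm, include_ae_costs = include_ae_costs)
  trace <- run_cohort(params, arm, acute = acute, table = table)
  accrue(trace, params, acute = acute)
}

#' Run the full cost-utility comparison
#'
#' Runs both arms through the decision tree and Markov model and computes
#' the incremental statistics at the given threshold. This is the main
#' entry point; [glance()] on the result gives the one-row summary and
#' [tidy()] the per-category cost breakdown.
#'
#' @param params A `cea_parameters` object (defaults to the packaged
#'   calibrated base case).
#' @param lambda Willingness-to-pay threshold in Euros per QALY.
#' @param include_ae_costs Scenario flag: add itemised 30-day adverse-event
#'   costs to the acute phase.
#' @return An object of class `cea_result`: list with `tavi`, `savr`
#'   (`cea_arm_result`), `incremental` (`cea_incremental`), and the
#'   parameters used.
#' @export
run_base_case <- function(params = base_case_parameters(), lambda = 50000,
                          include_ae_costs = FALSE) {
  table <- life_table_from_spec(params)
  tavi <- run_arm(params, "tavi", include_ae_costs = include_ae_costs, table = table)
  savr <- run_arm(params, "savr", include_ae_costs = include_ae_costs, table = table)
  structure(
    list(tavi = tavi, savr = savr,
         incremental = incremental(tavi, savr, lambda = lambda),
         lambda = lambda, params = params),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> TAVI vs SAVR cost-utility comparison\n\n")
  print(x$tavi); print(x$savr)
  cat("\n")
  print(x$incremental)
  invisible(x)
}
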