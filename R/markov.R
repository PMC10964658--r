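#' Single-cycle transition matrix
#'
#' Builds the 4x4 row-stochastic transition matrix over (alive-and-well,
#' treated AF, disabling stroke, dead) for one cycle. The AF and DS states
#' are chronic: they are never exited except to DS (from AF) or death. Each
#' state's death probability is the background per-cycle probability raised
#' on the hazard scale by its relative risk; self-loops absorb the
#' remainder.
#'
#' @param cycle 0-based cycle index (monthly cycles).
#' @param schedule The arm's `transitions` component (schedules plus
#'   `rr_aw`, `rr_af`, `rr_ds`).
#' @param q_background Background per-cycle death probability (before
#'   relative risks) for this cycle.
#' @return A 4x4 matrix with dimnames `aw`, `af`, `ds`, `dead`.
#' @export
transition_matrix <- function(cycle, schedule, q_background) {
  rr_death <- function(rr) 1 - (1 - q_background)^rr
  d_aw <- rr_death(schedule$rr_aw)
  d_af <- rr_death(schedule$rr_af)
  d_ds <- rr_death(schedule$rr_ds)
  p_af <- schedule_value(schedule$aw_to_af, cycle)
  p_ds <- schedule_value(schedule$aw_to_ds, cycle)
  p_afds <- schedule_value(schedule$af_to_ds, cycle)
  # when death is (near-)certain — at or beyond the life table's terminal
  # age — the morbidity transitions shrink into the remaining headroom
  if (d_aw >= 0.999 && p_af + p_ds > 0) {
    sc <- min(1, max(0, 1 - d_aw) / (p_af + p_ds))
    p_af <- p_af * sc; p_ds <- p_ds * sc
  }
  if (d_af >= 0.999) p_afds <- min(p_afds, max(0, 1 - d_af))
  if (p_af + p_ds + d_aw > 1 + 1e-12) {
    abort(sprintf(
      "competing exits from alive-and-well exceed 1 at cycle %d (aw_to_af=%.4g, aw_to_ds=%.4g, death=%.4g)",
      cycle, p_af, p_ds, d_aw))
  }
  if (p_afds + d_af > 1 + 1e-12) {
    abort(sprintf("competing exits from AF exceed 1 at cycle %d", cycle))
  }
  m <- matrix(0, 4, 4, dimnames = list(STATES, STATES))
  m["aw", ] <- c(1 - p_af - p_ds - d_aw, p_af, p_ds, d_aw)
  m["af", ] <- c(0, 1 - p_afds - d_af, p_afds, d_af)
  m["ds", ] <- c(0, 0, 1 - d_ds, d_ds)
  m["dead", "dead"] <- 1
  m
}

# background per-cycle death-probability sequence for an arm: life-table
# mortality in the base case, or a population-capped parametric model when
# the scenario survival model is enabled
background_mortality <- function(params, arm, table, n_cycles) {
  sm <- params$survival_model
  cohort <- params$cohort
  if (!is.null(sm) && isTRUE(sm$enabled)) {
    model <- survival_model(sm$family, sm$pars, hr = sm$hr[[arm]])
    capped_survivor(model, table, cohort)$q[seq_len(n_cycles)]
  } else {
    ages <- cohort$start_age + (seq_len(n_cycles) - 1) * cohort$cycle_length_months / 12
    cycle_death_probability(ages, cohort, table, rr = 1)
  }
}

#' Propagate the cohort through the Markov model
#'
#' Runs the four-state cohort model in monthly cycles over the full horizon
#' (600 cycles for the 50-year base case). Cycle 0 starts from the decision
#' tree's initial distribution. Alongside state occupancy the trace records
#' per-cycle incident entries into AF and DS (for month-1 costing),
#' expected reintervention events (alive-and-well plus AF mass times the
#' time-varying reintervention rate, held constant after year 22) and
#' expected rehospitalizations (alive mass times the arm's hospitalization
#' schedule).
#'
#' @param params A `cea_parameters` object.
#' @param arm `"tavi"` or `"savr"`.
#' @param acute A `cea_acute` result; computed with default flags when
#'   omitted.
#' @param table Life-table tibble; derived from the parameter set's
#'   Gompertz-Makeham spec when omitted.
#' @return A tibble of class `cea_trace` with one row per cycle boundary
#'   (`cycle` 0..N): columns `years`, `age`, occupancies `aw`, `af`, `ds`,
#'   `dead`, and per-cycle expectations `flow_af`, `flow_ds`,
#'   `reintervention`, `rehospitalization` (attached to the boundary
#'   opening the cycle; `NA` on the final boundary). The acute result and
#'   arm are carried as attributes.
#' @export
run_cohort <- function(params, arm = c("tavi", "savr"), acute = NULL,
                       table = NULL) {
  arm <- match.arg(arm)
  if (is.null(acute)) acute <- run_decision_tree(params, arm)
  if (is.null(table)) table <- life_table_from_spec(params)
  cohort <- params$cohort
  tr <- params$transitions[[arm]]
  n <- round(cohort$horizon_years * 12 / cohort$cycle_length_months)

  occ <- matrix(NA_real_, n + 1, 4, dimnames = list(NULL, STATES))
  occ[1, ] <- acute$initial_state
  flow_af <- flow_ds <- reint <- rehosp <- rep(NA_real_, n + 1)

  if (n > 0) {
    k <- seq_len(n) - 1
    q_bg <- background_mortality(params, arm, table, n)
    d_aw <- 1 - (1 - q_bg)^tr$rr_aw
    d_af <- 1 - (1 - q_bg)^tr$rr_af
    d_ds <- 1 - (1 - q_bg)^tr$rr_ds
    p_af <- schedule_value(tr$aw_to_af, k)
    p_ds <- schedule_value(tr$aw_to_ds, k)
    p_afds <- schedule_value(tr$af_to_ds, k)
    ri_rate <- reintervention_rate(tr$reintervention, k)
    rh_rate <- schedule_value(tr$rehospitalization, k)
    hi <- d_aw >= 0.999 & p_af + p_ds > 0
    if (any(hi)) {
      sc <- pmin(1, pmax(0, 1 - d_aw[hi]) / (p_af[hi] + p_ds[hi]))
      p_af[hi] <- p_af[hi] * sc; p_ds[hi] <- p_ds[hi] * sc
    }
    hi2 <- d_af >= 0.999
    p_afds[hi2] <- pmin(p_afds[hi2], pmax(0, 1 - d_af[hi2]))
    if (any(p_af + p_ds + d_aw > 1 + 1e-12) || any(p_afds + d_af > 1 + 1e-12)) {
      bad <- which(p_af + p_ds + d_aw > 1 + 1e-12 | p_afds + d_af > 1 + 1e-12)[1]
      abort(sprintf("competing state exits exceed 1 at cycle %d", bad - 1))
    }
    aw <- occ[1, "aw"]; af <- occ[1, "af"]; ds <- occ[1, "ds"]; dead <- occ[1, "dead"]
    for (i in seq_len(n)) {
      flow_af[i] <- aw * p_af[i]
      flow_ds[i] <- aw * p_ds[i] + af * p_afds[i]
      reint[i] <- (aw + af) * ri_rate[i]
      rehosp[i] <- (aw + af + ds) * rh_rate[i]
      aw_next <- aw * (1 - p_af[i] - p_ds[i] - d_aw[i])
      af_next <- af * (1 - p_afds[i] - d_af[i]) + aw * p_af[i]
      ds_next <- ds * (1 - d_ds[i]) + aw * p_ds[i] + af * p_afds[i]
      dead_next <- dead + aw * d_aw[i] + af * d_af[i] + ds * d_ds[i]
      aw <- aw_next; af <- af_next; ds <- ds_next; dead <- dead_next
      occ[i + 1, ] <- c(aw, af, ds, dead)
    }
  }
  out <- tibble(
    cycle = 0:n,
    years = (0:n) * cohort$cycle_length_months / 12,
    age = cohort$start_age + (0:n) * cohort$cycle_length_months / 12,
    aw = unname(occ[, "aw"]), af = unname(occ[, "af"]),
    ds = unname(occ[, "ds"]), dead = unname(occ[, "dead"]),
    flow_af = flow_af, flow_ds = flow_ds,
    reintervention = reint, rehospitalization = rehosp
  )
  structure(out, class = c("cea_trace", class(out)),
            arm = arm, acute = acute)
}

#' Median survival from a cohort trace
#'
#' Linear interpolation between the cycle boundaries bracketing an alive
#' fraction of 0.5. If the cohort never falls to 50% within the horizon the
#' result is `NA` with attribute `censored = TRUE`.
#'
#' @param trace A `cea_trace` tibble.
#' @return Median survival in years, or a censored `NA`.
#' @export
median_survival <- function(trace) {
  alive <- 1 - trace$dead
  idx <- which(alive <= 0.5)
  if (length(idx) == 0) {
    return(structure(NA_real_, censored = TRUE))
  }
  i <- idx[1]
  if (i == 1) return(0)
  a0 <- alive[i - 1]; a1 <- alive[i]
  frac <- (a0 - 0.5) / (a0 - a1)
  unname(trace$years[i - 1] + frac * (trace$years[i] - trace$years[i - 1]))
}
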