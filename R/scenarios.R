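scenario_defs <- function() {
  list(
    base = list(
      description = "Base case (no overrides)",
      apply = function(p) p),
    horizon_10y = list(
      description = "Time horizon shortened to 10 years",
      apply = function(p) { p$cohort$horizon_years <- 10; p }),
    horizon_25y = list(
      description = "Time horizon shortened to 25 years",
      apply = function(p) { p$cohort$horizon_years <- 25; p }),
    discount_none = list(
      description = "No discounting of costs or effects",
      apply = function(p) { p$discount$cost_rate <- 0; p$discount$effect_rate <- 0; p }),
    discount_equal_3pct = list(
      description = "Costs and effects both discounted at 3%/year",
      apply = function(p) { p$discount$cost_rate <- 0.03; p$discount$effect_rate <- 0.03; p }),
    reintervention_partner2 = list(
      description = "More aggressive TAVI reintervention profile (doubled rates, earlier ramp)",
      apply = function(p) {
        ri <- p$transitions$tavi$reintervention
        ri$early <- 2 * ri$early
        ri$year22 <- min(2 * ri$year22, 1)
        ri$ramp_start_year <- max(ri$ramp_start_year - 2, 1)
        p$transitions$tavi$reintervention <- ri
        p
      }),
    survival_hr075 = list(
      description = paste("Parametric trial survival with TAVI hazard ratio 0.75,",
                          "capped at general-population mortality"),
      apply = function(p) { p$survival_model$enabled <- TRUE; p }),
    stroke_risk_tavi_up = list(
      description = "Disabling-stroke risk after year 2 increased by 50% for TAVI",
      apply = function(p) {
        p$transitions$tavi$aw_to_ds$thereafter <-
          min(1.5 * p$transitions$tavi$aw_to_ds$thereafter, 1)
        p$transitions$tavi$af_to_ds$thereafter <-
          min(1.5 * p$transitions$tavi$af_to_ds$thereafter, 1)
        p
      }),
    acute_ae_costs = list(
      description = "Itemised 30-day adverse-event costs added to the acute phase",
      apply = function(p) p, include_ae_costs = TRUE),
    af_disutility_none = list(
      description = "Utility decrement for treated AF removed",
      apply = function(p) { p$utilities$disutility_af <- 0; p }),
    combined_conservative = list(
      description = paste("Simultaneous conservative assumptions: doubled TAVI",
                          "reintervention, capped trial survival, 30-day AE costs,",
                          "no AF disutility"),
      apply = function(p) {
        defs <- scenario_defs()
        p <- defs$reintervention_partner2$apply(p)
        p <- defs$survival_hr075$apply(p)
        p <- defs$af_disutility_none$apply(p)
        p
      },
      include_ae_costs = TRUE)
  )
}

#' Scenario catalogue
#'
#' The structural-assumption scenarios available to [run_scenario()]:
#' alternative horizons and discount rates, a more aggressive TAVI
#' reintervention profile, population-capped parametric trial survival
#' (TAVI hazard ratio 0.75), elevated late stroke risk for TAVI, inclusion
#' of itemised 30-day adverse-event costs, removal of the AF utility
#' decrement, and a combined conservative bundle.
#'
#' @return A tibble with columns `id` and `description`.
#' @export
scenario_catalog <- function() {
  defs <- scenario_defs()
  tibble(id = names(defs),
         description = vapply(defs, function(d) d$description, character(1)))
}

#' Run a scenario analysis
#'
#' Applies a catalogued set of parameter overrides to the base parameter
#' set and re-runs the full pipeline.
#'
#' @param params Base `cea_parameters` object.
#' @param id Scenario identifier (see [scenario_catalog()]).
#' @param lambda Willingness-to-pay threshold (Euros/QALY).
#' @return A `cea_result` with attribute `scenario` set to `id`.
#' @export
run_scenario <- function(params, id, lambda = 50000) {
  defs <- scenario_defs()
  if (!id %in% names(defs)) {
    abort(paste0("unknown scenario '", id, "'; available: ",
                 paste(names(defs), collapse = ", ")))
  }
  def <- defs[[id]]
  res <- run_base_case(def$apply(params), lambda = lambda,
                       include_ae_costs = isTRUE(def$include_ae_costs))
  attr(res, "scenario") <- id
  res
}

#' Run every catalogued scenario
#'
#' @param params Base `cea_parameters` object.
#' @param ids Scenario identifiers (default: the full catalogue).
#' @param lambda Willingness-to-pay threshold (Euros/QALY).
#' @return A tibble with one row per scenario: incremental cost, QALYs,
#'   ICER, INMB, INHB and dominance classification.
#' @export
run_scenarios <- function(params, ids = scenario_catalog()$id, lambda = 50000) {
  purrr::map_dfr(ids, function(id) {
    inc <- run_scenario(params, id, lambda = lambda)$incremental
    tibble(scenario = id, delta_cost = inc$delta_cost,
           delta_qaly = inc$delta_qaly, icer = inc$icer,
           inmb = inc$inmb, inhb = inc$inhb, dominance = inc$dominance)
  })
}
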