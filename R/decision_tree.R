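#' Run the 30-day acute-event decision tree for one arm
#'
#' Converts the 30-day adverse-event probabilities of a treatment arm into
#' the initial state distribution of the Markov model, the expected
#' acute-phase cost, and the fraction of the surviving cohort carrying a
#' pacemaker. Branching is sequential and mutually exclusive — death first,
#' then disabling stroke among survivors, then new treated atrial
#' fibrillation among stroke-free survivors — which conserves probability by
#' construction.
#'
#' The base-case acute cost is the index-hospitalization cost: procedure
#' (including rehabilitation) plus a calibrated acute add-on. With
#' `include_ae_costs = TRUE` (scenario), itemised post-discharge 30-day
#' event costs (myocardial infarction, rehospitalization) are added on top.
#'
#' @param params A `cea_parameters` object.
#' @param arm `"tavi"` or `"savr"`.
#' @param include_ae_costs Add itemised 30-day adverse-event costs
#'   (scenario flag; default `FALSE`).
#' @return An object of class `cea_acute`: a list with
#'   `initial_state` (named probability vector over aw/af/ds/dead summing
#'   to 1), `expected_cost` (Euros), `pacemaker_fraction`, and
#'   `ae_extra_cost` (Euros; 0 unless the scenario flag is set).
#' @export
run_decision_tree <- function(params, arm = c("tavi", "savr"),
                              include_ae_costs = FALSE) {
  arm <- match.arg(arm)
  ac <- params$acute[[arm]]
  for (f in ACUTE_FIELDS) {
    p <- ac[[f]]
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
      abort(paste0("acute$", arm, "$", f, " is not a probability in [0, 1]"))
    }
  }
  dead <- ac$death
  ds <- (1 - dead) * ac$disabling_stroke
  af <- (1 - dead) * (1 - ac$disabling_stroke) * ac$new_treated_af
  aw <- 1 - dead - ds - af
  init <- c(aw = aw, af = af, ds = ds, dead = dead)
  if (any(init < -1e-12)) abort("30-day branch masses exceed 1")
  init <- pmax(init, 0)

  co <- params$costs
  cost <- co$procedure[[arm]] + co$acute_addon[[arm]]
  ae_extra <- 0
  if (include_ae_costs) {
    ae_extra <- ac$myocardial_infarction * co$mi_event +
      ac$rehospitalization * co$rehospitalization_event
    cost <- cost + ae_extra
  }
  # survivors who receive a new implant, on top of the baseline carrier rate
  pm <- params$pacemaker$baseline_fraction[[arm]] +
    (1 - params$pacemaker$baseline_fraction[[arm]]) * ac$pacemaker_implant
  structure(
    list(arm = arm, initial_state = init, expected_cost = cost,
         pacemaker_fraction = pm, ae_extra_cost = ae_extra),
    class = "cea_acute"
  )
}

#' @export
print.cea_acute <- function(x, ...) {
  cat(sprintf("<cea_acute> %s: acute cost %.0f EUR, pacemaker %.1f%%\n",
              toupper(x$arm), x$expected_cost, 100 * x$pacemaker_fraction))
  print(round(x$initial_state, 5))
  invisible(x)
}
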