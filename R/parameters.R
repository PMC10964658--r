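#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows left_join desc
#' @importFrom stats setNames
NULL

ARMS <- c("tavi", "savr")
STATES <- c("aw", "af", "ds", "dead")

ACUTE_FIELDS <- c(
  "death", "disabling_stroke", "new_treated_af", "pacemaker_implant",
  "myocardial_infarction", "rehospitalization"
)

COST_FIELDS <- c(
  "reintervention", "af_month1", "af_monthly", "ds_month1", "ds_monthly",
  "ds_caregiver_month1", "ds_caregiver_monthly", "aw_year1", "aw_annual",
  "pacemaker_monthly", "rehospitalization_event", "mi_event", "death"
)

#' Construct a cost-utility parameter set
#'
#' Bundles every model input for both treatment arms into a single validated
#' object: discounting, cohort definition, the synthetic life-table
#' specification, 30-day acute event probabilities, monthly transition
#' schedules with state mortality relative risks, unit costs (2020 Euros),
#' and utility inputs (age/sex population norms minus state decrements).
#'
#' @param x A named list with components `meta`, `discount`, `cohort`,
#'   `life_table`, `acute`, `transitions`, `costs`, `utilities`,
#'   `pacemaker` (see [base_case_parameters()] for the reference layout).
#' @param check If `TRUE` (default), [validate_parameters()] is run and any
#'   violation raises an error listing every offending field.
#' @return An object of class `cea_parameters`.
#' @export
new_cea_parameters <- function(x, check = TRUE) {
  required <- c("meta", "discount", "cohort", "life_table", "acute",
                "transitions", "costs", "utilities", "pacemaker")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("parameter set is missing component(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (arm in ARMS) {
    if (is.null(x$acute[[arm]])) abort(paste0("acute probabilities missing for arm '", arm, "'"))
    if (is.null(x$transitions[[arm]])) abort(paste0("transition schedule missing for arm '", arm, "'"))
  }
  structure(x, class = "cea_parameters")
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters>\n")
  cat(sprintf("  cohort: start age %.1f y, %.0f%% female, horizon %d y, cycle %g mo\n",
              x$cohort$start_age, 100 * x$cohort$fraction_female,
              x$cohort$horizon_years, x$cohort$cycle_length_months))
  cat(sprintf("  discounting: costs %.1f%%/y, effects %.2f%%/y\n",
              100 * x$discount$cost_rate, 100 * x$discount$effect_rate))
  cat(sprintf("  procedure cost: TAVI %s, SAVR %s (%d Euros)\n",
              format(x$costs$procedure$tavi, big.mark = ","),
              format(x$costs$procedure$savr, big.mark = ","),
              x$meta$currency_year))
  viol <- validate_parameters(x)
  cat(sprintf("  validation: %s\n",
              if (nrow(viol) == 0) "clean" else paste(nrow(viol), "violation(s)")))
  invisible(x)
}

check_prob <- function(value, field) {
  if (is.null(value) || !is.numeric(value) || is.na(value)) {
    return(tibble(field = field, rule = "must be a number"))
  }
  if (value < 0 || value > 1) {
    return(tibble(field = field,
                  rule = sprintf("probability %g outside [0, 1]", value)))
  }
  tibble(field = character(), rule = character())
}

check_schedule <- function(sched, field) {
  out <- list()
  for (nm in c("year1", "year2", "thereafter")) {
    out[[nm]] <- check_prob(sched[[nm]], paste0(field, "$", nm))
  }
  bind_rows(out)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs: probabilities in
#' \[0, 1\], non-negative costs, discount rates in \[0, 1), a whole number of
#' cycles in the horizon, utility norms not exceeding 1, non-negative
#' disutility decrements with `disutility_ds >= disutility_af`, and a
#' feasible 30-day branch split per arm. Violations are returned as data,
#' never raised: the function is total on structurally complete input.
#'
#' @param params A `cea_parameters` object (or plain list with the same
#'   layout).
#' @return A tibble with columns `field` and `rule`; zero rows means the
#'   parameter set is valid.
#' @export
validate_parameters <- function(params) {
  v <- list()
  d <- params$discount
  for (nm in c("cost_rate", "effect_rate")) {
    r <- d[[nm]]
    if (!is.numeric(r) || is.na(r) || r < 0 || r >= 1) {
      v[[length(v) + 1]] <- tibble(field = paste0("discount$", nm),
                                   rule = "rate must lie in [0, 1)")
    }
  }
  ch <- params$cohort
  if (!is.numeric(ch$start_age) || ch$start_age <= 0) {
    v[[length(v) + 1]] <- tibble(field = "cohort$start_age", rule = "must be > 0")
  }
  v[[length(v) + 1]] <- check_prob(ch$fraction_female, "cohort$fraction_female")
  n_cycles <- ch$horizon_years * 12 / ch$cycle_length_months
  if (!isTRUE(abs(n_cycles - round(n_cycles)) < 1e-9)) {
    v[[length(v) + 1]] <- tibble(
      field = "cohort$horizon_years",
      rule = sprintf("horizon (%g y) not a whole number of %g-month cycles",
                     ch$horizon_years, ch$cycle_length_months))
  }
  lt <- params$life_table
  if (!is.numeric(lt$gompertz_b) || lt$gompertz_b <= 0) {
    v[[length(v) + 1]] <- tibble(field = "life_table$gompertz_b", rule = "must be > 0")
  }
  if (!is.numeric(lt$gompertz_c) || lt$gompertz_c <= 1) {
    v[[length(v) + 1]] <- tibble(field = "life_table$gompertz_c", rule = "must be > 1")
  }
  for (arm in ARMS) {
    ac <- params$acute[[arm]]
    for (f in ACUTE_FIELDS) {
      v[[length(v) + 1]] <- check_prob(ac[[f]], paste0("acute$", arm, "$", f))
    }
    # sequential 30-day branching: conditional probabilities each in [0,1]
    # keeps the split valid automatically, but flag a nonsensical joint sum
    joint <- ac$death + (1 - ac$death) * ac$disabling_stroke +
      (1 - ac$death) * (1 - ac$disabling_stroke) * ac$new_treated_af
    if (is.finite(joint) && joint > 1 + 1e-12) {
      v[[length(v) + 1]] <- tibble(field = paste0("acute$", arm),
                                   rule = "30-day branch masses exceed 1")
    }
    tr <- params$transitions[[arm]]
    for (s in c("aw_to_af", "aw_to_ds", "af_to_ds", "rehospitalization")) {
      v[[length(v) + 1]] <- check_schedule(tr[[s]], paste0("transitions$", arm, "$", s))
    }
    ri <- tr$reintervention
    v[[length(v) + 1]] <- check_prob(ri$early, paste0("transitions$", arm, "$reintervention$early"))
    v[[length(v) + 1]] <- check_prob(ri$year22, paste0("transitions$", arm, "$reintervention$year22"))
    if (!is.numeric(ri$ramp_start_year) || ri$ramp_start_year < 1 || ri$ramp_start_year > 22) {
      v[[length(v) + 1]] <- tibble(field = paste0("transitions$", arm, "$reintervention$ramp_start_year"),
                                   rule = "must lie in [1, 22]")
    }
    for (rr in c("rr_aw", "rr_af", "rr_ds")) {
      val <- tr[[rr]]
      if (!is.numeric(val) || is.na(val) || val < 0) {
        v[[length(v) + 1]] <- tibble(field = paste0("transitions$", arm, "$", rr),
                                     rule = "relative risk must be >= 0")
      }
    }
    v[[length(v) + 1]] <- check_prob(params$pacemaker$baseline_fraction[[arm]],
                                     paste0("pacemaker$baseline_fraction$", arm))
  }
  co <- params$costs
  for (arm in ARMS) {
    for (f in c("procedure", "acute_addon")) {
      val <- co[[f]][[arm]]
      if (!is.numeric(val) || is.na(val) || val < 0) {
        v[[length(v) + 1]] <- tibble(field = paste0("costs$", f, "$", arm),
                                     rule = "cost must be >= 0")
      }
    }
  }
  for (f in COST_FIELDS) {
    val <- co[[f]]
    if (!is.numeric(val) || is.na(val) || val < 0) {
      v[[length(v) + 1]] <- tibble(field = paste0("costs$", f), rule = "cost must be >= 0")
    }
  }
  ut <- params$utilities
  for (nm in c("male_u0", "female_u0")) {
    val <- ut$norms[[nm]]
    if (!is.numeric(val) || is.na(val) || val > 1 || val < -0.5) {
      v[[length(v) + 1]] <- tibble(field = paste0("utilities$norms$", nm),
                                   rule = "population norm must lie in [-0.5, 1]")
    }
  }
  for (nm in c("disutility_af", "disutility_ds")) {
    val <- ut[[nm]]
    if (!is.numeric(val) || is.na(val) || val < 0) {
      v[[length(v) + 1]] <- tibble(field = paste0("utilities$", nm),
                                   rule = "disutility must be >= 0")
    }
  }
  if (is.numeric(ut$disutility_af) && is.numeric(ut$disutility_ds) &&
      !is.na(ut$disutility_af) && !is.na(ut$disutility_ds) &&
      ut$disutility_ds < ut$disutility_af) {
    v[[length(v) + 1]] <- tibble(field = "utilities$disutility_ds",
                                 rule = "disabling-stroke decrement must be >= AF decrement")
  }
  out <- bind_rows(v)
  if (nrow(out) == 0) {
    out <- tibble(field = character(), rule = character())
  }
  out
}

#' Read a parameter set from a YAML file
#'
#' @param path Path to a YAML parameter file (see
#'   `system.file("extdata", "base_case.yaml", package = "tavicea")` for the
#'   reference dialect).
#' @return A validated `cea_parameters` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) abort(paste0("parameter file not found: ", path))
  raw <- yaml::read_yaml(path)
  params <- new_cea_parameters(raw, check = FALSE)
  viol <- validate_parameters(params)
  if (nrow(viol) > 0) {
    abort(paste0(
      "invalid parameter file '", path, "':\n",
      paste(sprintf("  - %s: %s", viol$field, viol$rule), collapse = "\n")))
  }
  params
}

#' Write a parameter set to a YAML file
#'
#' `write_parameters()` followed by [load_parameters()] is the identity on
#' valid parameter sets (up to floating-point text representation).
#'
#' @param params A `cea_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  writeLines(yaml::as.yaml(unclass(params), precision = 15), path)
  invisible(path)
}

# schedule value for a 0-based cycle index (monthly cycles)
schedule_value <- function(sched, cycle) {
  year <- cycle %/% 12 + 1
  ifelse(year <= 1, sched$year1, ifelse(year <= 2, sched$year2, sched$thereafter))
}

# reintervention monthly rate: flat early plateau, linear ramp to year 22,
# constant thereafter (no longer-term data beyond year 22)
reintervention_rate <- function(ri, cycle) {
  year <- cycle / 12 + 1 / 24  # mid-cycle, in years since procedure, 1-based
  frac <- (year - ri$ramp_start_year) / (22 - ri$ramp_start_year)
  frac <- pmin(pmax(frac, 0), 1)
  ri$early + frac * (ri$year22 - ri$early)
}

#' Age/sex population utility norm
#'
#' Linear-in-age EQ-5D population norm used as the "alive and well" utility;
#' state utilities subtract the AF/DS decrements. The packaged norms are a
#' synthetic stand-in for published Dutch EQ-5D-5L age norms: anchored near
#' 0.84 at age 73 and declining with age.
#'
#' @param utilities The `utilities` component of a parameter set.
#' @param age Age in years (vectorised).
#' @param fraction_female Cohort fraction female used for sex-mix weighting.
#' @return Utility values, clamped to \[-0.5, 1\].
#' @export
population_norm <- function(utilities, age, fraction_female) {
  no <- utilities$norms
  um <- no$male_u0 - no$slope_per_year * (age - no$anchor_age)
  uf <- no$female_u0 - no$slope_per_year * (age - no$anchor_age)
  u <- fraction_female * uf + (1 - fraction_female) * um
  pmin(pmax(u, -0.5), 1)
}
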