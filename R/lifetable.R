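#' Synthetic Gompertz-Makeham life table
#'
#' Builds an abridged general-population life table (age, sex, annual death
#' probability) from a Gompertz-Makeham hazard, standing in for a national
#' statistics life table. The annual hazard at age \eqn{x} is
#' \eqn{a + b c^{x - x_0}} for males and \eqn{a + f b c^{x - x_0}} for
#' females (`female_hazard_factor` \eqn{f < 1} gives women the usual
#' survival advantage), so \eqn{q(x) = 1 - \exp\{-(a + b c^{x - x_0})\}};
#' `anchor_age` \eqn{x_0} (default 0) only re-scales `b` for numerical
#' convenience. The packaged base case calibrates \eqn{(a, b, c)} so the
#' modelled cohort reproduces the published mean and median survival.
#'
#' @param makeham_a Age-independent hazard component (per year), `>= 0`.
#' @param gompertz_b Hazard scale at `anchor_age`, `> 0`.
#' @param gompertz_c Annual hazard growth factor, `> 1`.
#' @param min_age,terminal_age Age range covered; `q` is forced to 1 at
#'   `terminal_age`.
#' @param female_hazard_factor Multiplier on the Gompertz term for women.
#' @param anchor_age Age at which the Gompertz term equals `gompertz_b`.
#' @return A tibble with columns `age`, `sex` (`"male"`/`"female"`) and
#'   `annual_death_probability`, sorted by sex then age.
#' @export
synthetic_life_table <- function(makeham_a, gompertz_b, gompertz_c,
                                 min_age = 55, terminal_age = 110,
                                 female_hazard_factor = 0.55,
                                 anchor_age = 0) {
  stopifnot(makeham_a >= 0, gompertz_b > 0, gompertz_c > 1,
            terminal_age > min_age, female_hazard_factor > 0)
  ages <- seq(min_age, terminal_age)
  q_sex <- function(f) {
    q <- 1 - exp(-(makeham_a + f * gompertz_b * gompertz_c^(ages - anchor_age)))
    q <- pmin(pmax(q, 0), 1)
    q[ages >= terminal_age] <- 1
    q
  }
  bind_rows(
    tibble(age = ages, sex = "male", annual_death_probability = q_sex(1)),
    tibble(age = ages, sex = "female",
           annual_death_probability = q_sex(female_hazard_factor))
  )
}

#' Read a life table from delimited text
#'
#' Expects columns `age`, `sex` and `annual_death_probability` (tab- or
#' comma-separated; autodetected from the header line).
#'
#' @param path Path to the file.
#' @return A life-table tibble as produced by [synthetic_life_table()].
#' @export
read_life_table <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  needed <- c("age", "sex", "annual_death_probability")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("life table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  lt <- as_tibble(df[needed])
  bad <- lt$annual_death_probability < 0 | lt$annual_death_probability > 1
  if (any(bad, na.rm = TRUE)) abort("life table probabilities outside [0, 1]")
  arrange(lt, .data$sex, .data$age)
}

# life table implied by the parameter set's Gompertz-Makeham spec
life_table_from_spec <- function(params) {
  lt <- params$life_table
  synthetic_life_table(
    makeham_a = lt$makeham_a, gompertz_b = lt$gompertz_b,
    gompertz_c = lt$gompertz_c, min_age = lt$min_age,
    terminal_age = lt$terminal_age,
    female_hazard_factor = lt$female_hazard_factor,
    anchor_age = lt$anchor_age %||% 0
  )
}

# sex-mix-weighted annual death probability at (floored) ages; beyond the
# terminal age the probability is 1
annual_death_probability <- function(table, age, fraction_female) {
  age <- floor(age)
  males <- table[table$sex == "male", ]
  females <- table[table$sex == "female", ]
  idx <- match(age, males$age)
  qm <- males$annual_death_probability[idx]
  qf <- females$annual_death_probability[match(age, females$age)]
  qm[age > max(males$age)] <- 1
  qf[age > max(females$age)] <- 1
  if (any(is.na(qm) | is.na(qf))) {
    abort("age below the life table's minimum age")
  }
  fraction_female * qf + (1 - fraction_female) * qm
}

#' Per-cycle death probability with a relative risk
#'
#' Converts the sex-mix-weighted annual death probability at a given age to
#' the model's cycle length, then applies a state relative risk on the
#' complement-power (hazard) scale:
#' \eqn{q_{cyc} = 1 - (1-q)^{\ell/12}} and
#' \eqn{q_{rr} = 1 - (1-q_{cyc})^{rr}}, which stays in \[0, 1\] for any
#' `rr >= 0`.
#'
#' @param age Age in years (vectorised).
#' @param cohort The `cohort` component of a parameter set (supplies
#'   `cycle_length_months` and `fraction_female`).
#' @param table A life-table tibble.
#' @param rr Relative risk multiplier, `>= 0`.
#' @return Per-cycle death probabilities.
#' @export
cycle_death_probability <- function(age, cohort, table, rr = 1) {
  stopifnot(rr >= 0)
  q <- annual_death_probability(table, age, cohort$fraction_female)
  q_cycle <- 1 - (1 - q)^(cohort$cycle_length_months / 12)
  1 - (1 - q_cycle)^rr
}

#' Parametric survival model for scenario extrapolation
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"lognormal"`, `"loglogistic"`.
#' @param pars Named parameter vector: `rate` (exponential); `shape`,
#'   `scale` (Weibull, log-logistic); `shape`, `rate` (Gompertz);
#'   `meanlog`, `sdlog` (log-normal). Time is measured in years.
#' @param hr Proportional-hazards multiplier applied to the parametric
#'   hazard (e.g. 0.75 for a treatment-benefit scenario).
#' @return An object of class `survival_model`.
#' @export
survival_model <- function(family = c("exponential", "weibull", "gompertz",
                                      "lognormal", "loglogistic"),
                           pars, hr = 1) {
  family <- match.arg(family)
  stopifnot(hr >= 0)
  structure(list(family = family, pars = as.list(pars), hr = hr),
            class = "survival_model")
}

# cumulative hazard of the parametric family at time t (years), before hr
cumulative_hazard <- function(model, t) {
  p <- model$pars
  H <- switch(model$family,
    exponential = p$rate * t,
    weibull = (t / p$scale)^p$shape,
    gompertz = if (abs(p$shape) < 1e-12) p$rate * t else
      p$rate / p$shape * (exp(p$shape * t) - 1),
    lognormal = -stats::plnorm(t, p$meanlog, p$sdlog,
                               lower.tail = FALSE, log.p = TRUE),
    loglogistic = log1p((t / p$scale)^p$shape)
  )
  if (any(!is.finite(H[t > 0]))) abort("non-finite parametric hazard")
  H
}

#' Population-capped parametric death-probability sequence
#'
#' Per-cycle death probabilities from a parametric survival model whose
#' hazard is floored at the general-population hazard: patients cannot
#' outlive the general population, so the per-cycle hazard is
#' `max(parametric, population)` and the resulting survivor curve lies at
#' or below the population survivor curve at every cycle.
#'
#' @param model A [survival_model()].
#' @param table A life-table tibble.
#' @param cohort The `cohort` component of a parameter set.
#' @return A tibble with columns `cycle`, `time_years`, `q_population`,
#'   `q_parametric`, `q` (capped) and `survivor` (capped survivor curve at
#'   the end of each cycle).
#' @export
capped_survivor <- function(model, table, cohort) {
  n <- round(cohort$horizon_years * 12 / cohort$cycle_length_months)
  k <- seq_len(n) - 1
  t0 <- k * cohort$cycle_length_months / 12
  t1 <- (k + 1) * cohort$cycle_length_months / 12
  q_pop <- cycle_death_probability(cohort$start_age + t0, cohort, table, rr = 1)
  h_pop <- -log1p(-pmin(q_pop, 1 - 1e-15))
  h_par <- model$hr * (cumulative_hazard(model, t1) - cumulative_hazard(model, t0))
  h <- pmax(h_par, h_pop)
  q <- 1 - exp(-h)
  q[q_pop >= 1] <- 1
  tibble(
    cycle = k, time_years = t0,
    q_population = q_pop, q_parametric = 1 - exp(-h_par),
    q = q, survivor = cumprod(1 - q)
  )
}
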