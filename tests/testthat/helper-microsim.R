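# Independent individual-level simulation of the four-state process, used
# as an oracle for the cohort engine. Schedules, mortality and the
# near-certain-death truncation are re-derived here from the parameter set
# rather than taken from the engine's transition machinery.
microsimulate <- function(params, arm, n_paths = 20000, seed = 1) {
  set.seed(seed)
  cohort <- params$cohort
  n <- round(cohort$horizon_years * 12 / cohort$cycle_length_months)
  lt <- life_table_from_spec(params)
  qm_tab <- lt[lt$sex == "male", ]
  qf_tab <- lt[lt$sex == "female", ]
  tr <- params$transitions[[arm]]
  init <- run_decision_tree(params, arm)$initial_state

  state <- sample.int(4, n_paths, replace = TRUE, prob = init)
  occ <- matrix(0, n + 1, 4)
  occ[1, ] <- tabulate(state, 4) / n_paths
  sv <- function(s, year) if (year <= 1) s$year1 else if (year <= 2) s$year2 else s$thereafter
  for (k in seq_len(n) - 1) {
    age <- floor(cohort$start_age + k * cohort$cycle_length_months / 12)
    qm <- if (age > max(qm_tab$age)) 1 else qm_tab$annual_death_probability[qm_tab$age == age]
    qf <- if (age > max(qf_tab$age)) 1 else qf_tab$annual_death_probability[qf_tab$age == age]
    q <- cohort$fraction_female * qf + (1 - cohort$fraction_female) * qm
    qc <- 1 - (1 - q)^(cohort$cycle_length_months / 12)
    d_aw <- 1 - (1 - qc)^tr$rr_aw
    d_af <- 1 - (1 - qc)^tr$rr_af
    d_ds <- 1 - (1 - qc)^tr$rr_ds
    year <- k %/% 12 + 1
    p_af <- sv(tr$aw_to_af, year); p_ds <- sv(tr$aw_to_ds, year)
    p_afds <- sv(tr$af_to_ds, year)
    if (d_aw >= 0.999 && p_af + p_ds > 0) {
      sc <- min(1, max(0, 1 - d_aw) / (p_af + p_ds))
      p_af <- p_af * sc; p_ds <- p_ds * sc
    }
    if (d_af >= 0.999) p_afds <- min(p_afds, max(0, 1 - d_af))
    u <- stats::runif(n_paths)
    new <- state
    i <- state == 1L
    new[i & u < d_aw] <- 4L
    new[i & u >= d_aw & u < d_aw + p_af] <- 2L
    new[i & u >= d_aw + p_af & u < d_aw + p_af + p_ds] <- 3L
    j <- state == 2L
    new[j & u < d_af] <- 4L
    new[j & u >= d_af & u < d_af + p_afds] <- 3L
    l <- state == 3L
    new[l & u < d_ds] <- 4L
    state <- new
    occ[k + 2, ] <- tabulate(state, 4) / n_paths
  }
  colnames(occ) <- c("aw", "af", "ds", "dead")
  occ
}
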