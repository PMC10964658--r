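# Minimal valid parameter set for targeted unit tests: flat background
# mortality (constant annual q), no transitions, no event rates, simple
# costs and perfect-health utilities. Override pieces per test.
make_test_params <- function(q_annual = 0, start_age = 60, horizon = 10,
                             cost_rate = 0, effect_rate = 0) {
  sched0 <- list(year1 = 0, year2 = 0, thereafter = 0)
  arm_acute <- list(death = 0, disabling_stroke = 0, new_treated_af = 0,
                    pacemaker_implant = 0, myocardial_infarction = 0,
                    rehospitalization = 0)
  arm_trans <- list(
    aw_to_af = sched0, aw_to_ds = sched0, af_to_ds = sched0,
    rehospitalization = sched0,
    reintervention = list(early = 0, ramp_start_year = 5, year22 = 0),
    rr_aw = 1, rr_af = 1, rr_ds = 1)
  new_cea_parameters(list(
    meta = list(currency_year = 2020, inflation_factor = 1),
    discount = list(cost_rate = cost_rate, effect_rate = effect_rate),
    cohort = list(start_age = start_age, fraction_female = 0.5,
                  horizon_years = horizon, cycle_length_months = 1),
    life_table = list(makeham_a = -log(1 - q_annual), gompertz_b = 1e-15,
                      gompertz_c = 1.0001, female_hazard_factor = 1,
                      min_age = 50, terminal_age = 120, anchor_age = 0),
    acute = list(tavi = arm_acute, savr = arm_acute),
    transitions = list(tavi = arm_trans, savr = arm_trans),
    costs = list(procedure = list(tavi = 1000, savr = 800),
                 acute_addon = list(tavi = 0, savr = 0),
                 reintervention = 500,
                 af_month1 = 108, af_monthly = 85,
                 ds_month1 = 15784, ds_monthly = 699,
                 ds_caregiver_month1 = 244, ds_caregiver_monthly = 376,
                 aw_year1 = 0, aw_annual = 0,
                 pacemaker_monthly = 0, rehospitalization_event = 2600,
                 mi_event = 5000, death = 0),
    utilities = list(norms = list(anchor_age = 73, male_u0 = 1, female_u0 = 1,
                                  slope_per_year = 0),
                     disutility_af = 0, disutility_ds = 0),
    pacemaker = list(baseline_fraction = list(tavi = 0, savr = 0))
  ))
}
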