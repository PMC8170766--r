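# shared builders and frozen constants for the test suite

base_params <- function(...) bph_parameters(...)

# no mortality, no between-pathway transitions: cohorts settle into the
# "later" phase of their entry pathway and stay there
zero_dynamics_params <- function(settings = list()) {
  bph_parameters(
    settings = settings,
    transitions = list(
      p_noncompliance_y1 = 0, p_drug_to_surgery_later = 0,
      p_drug_to_pc = 0, p_surgery_to_pc = 0,
      surgery_death_addon_turp = 0, surgery_death_addon_op = 0,
      pc_excess_death = 0
    ),
    life_table = make_life_table("zero")
  )
}

# single flat band covering every age the model can reach
flat_life_table <- function(qx) {
  as_life_table(data.frame(age_low = 40, age_high = 120, qx = qx))
}

# frozen published constants of the default parameter set; the defaults must
# reproduce each of these exactly
frozen_constants <- list(
  p_noncompliance_y1       = 0.3,
  p_drug_to_surgery_later  = 0.005,
  p_drug_to_pc             = 0.000836,
  p_surgery_to_pc          = 0.0011,
  pc_excess_death          = 0.18,
  surgery_death_addon_blended = 0.0012,
  cost_drug_y1   = 146.36,
  cost_drug_later = 146.36,
  cost_surg_y1   = 840.96,
  cost_surg_later = 9,
  cost_pc_y1     = 6141,
  cost_pc_later  = 2303,
  cost_death     = 0,
  cost_infection = 0.71,
  cohort_size    = 1000,
  horizon        = 10L,
  start_age      = 70,
  discount_cost  = 0.07,
  discount_utility = 0.03,
  wtp            = 3701,
  share_turp     = 0.8,
  share_op       = 0.2,
  pc_utility     = 0.62,
  baseline_ipss  = 16.7,
  surgical_improvement = 8.5,
  chemoprevention_rr = 0.25
)
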