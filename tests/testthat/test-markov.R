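test_that("rate-to-probability conversion follows the exponential formula", {
  expect_identical(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(0.18, 1), 1 - exp(-0.18), tolerance = 1e-15)
  expect_equal(round(rate_to_probability(0.18, 1), 6), 0.164730)
  expect_equal(rate_to_probability(1e9, 1), 1)
  expect_equal(rate_to_probability(0.1, 2), 1 - exp(-0.2), tolerance = 1e-15)
  expect_error(rate_to_probability(-0.1, 1), "range error")
  expect_error(rate_to_probability(0.1, 0), "range error")
})

test_that("death probability adds state-specific excess risk to band mortality", {
  p <- bph_parameters(life_table = flat_life_table(0.04))
  lt <- p$life_table
  expect_identical(death_probability(72, lt, "drug_later", p), 0.04)
  # blended perioperative add-on at the 80/20 mix: 0.8*0.001 + 0.2*0.002
  expect_equal(death_probability(70, lt, "surg_y1", p), 0.0412,
               tolerance = 1e-12)
  # add-on confined to the first surgical year by default
  expect_identical(death_probability(70, lt, "surg_later", p), 0.04)
  p2 <- p; p2$transitions$addon_first_year_only <- FALSE
  expect_equal(death_probability(70, lt, "surg_later", p2), 0.0412,
               tolerance = 1e-12)
  # cancer states add the excess cancer mortality
  p3 <- bph_parameters(life_table = flat_life_table(0.05))
  expect_equal(death_probability(75, p3$life_table, "pc_y1", p3), 0.23,
               tolerance = 1e-12)
  expect_equal(death_probability(75, p3$life_table, "pc_later", p3), 0.23,
               tolerance = 1e-12)
  expect_error(death_probability(130, lt, "drug_later", p), "coverage error")
})

test_that("cancer inflow reflects chemoprevention during the first two drug years", {
  p <- base_params()
  expect_equal(cancer_probability("drug_y1", 1, p), 0.000836 * 0.75,
               tolerance = 1e-15)
  expect_equal(cancer_probability("drug_later", 2, p), 0.000836 * 0.75,
               tolerance = 1e-15)
  expect_identical(cancer_probability("drug_later", 3, p), 0.000836)
  expect_identical(cancer_probability("drug_later", 5, p), 0.000836)
  expect_identical(cancer_probability("surg_later", 1, p), 0.0011)
  expect_identical(cancer_probability("surg_y1", 7, p), 0.0011)
  off <- p; off$transitions$chemoprevention_enabled <- FALSE
  expect_identical(cancer_probability("drug_y1", 1, off), 0.000836)
  expect_error(cancer_probability("pc_y1", 1, p), "no cancer transition")
})

test_that("transition matrices are row-stochastic with the documented topology", {
  p <- base_params()
  for (cyc in c(1, 2, 5, 10)) {
    m <- build_transition_matrix(p, cyc)
    expect_equal(unname(rowSums(m)), rep(1, 7), tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 1))
    expect_identical(unname(m["death", ]), c(0, 0, 0, 0, 0, 0, 1))
    # forbidden transitions are structurally zero
    expect_identical(m["surg_y1", "drug_y1"], 0)
    expect_identical(m["surg_later", "drug_later"], 0)
    expect_identical(m["pc_y1", "surg_y1"], 0)
    expect_identical(m["pc_later", "drug_later"], 0)
  }
  # drug_y1 residual: 1 - noncompliance - chemoprevented cancer - mortality
  m1 <- build_transition_matrix(p, 1)
  qx70 <- p$life_table$qx[p$life_table$age_low == 70]
  expect_equal(m1["drug_y1", "drug_later"],
               1 - 0.3 - 0.000836 * 0.75 - qx70, tolerance = 1e-12)
  expect_equal(m1["drug_y1", "surg_y1"], 0.3)
  expect_error(build_transition_matrix(p, 11), "range error")
})

test_that("infeasible outgoing probabilities fail with the row named", {
  p <- bph_parameters(transitions = list(p_noncompliance_y1 = 0.9),
                      life_table = flat_life_table(0.15))
  expect_error(build_transition_matrix(p, 1), "drug_y1")
})

test_that("cohort propagation conserves mass and initialises in the entry state", {
  p <- base_params()
  for (arm in c("pharmacotherapy", "surgery")) {
    tr <- run_cohort(p, arm)
    expect_equal(dim(tr), c(11, 7))
    expect_identical(unname(tr[1, bph_arms()[[arm]]]), 1000)
    expect_identical(sum(tr[1, ]), 1000)
    expect_equal(unname(rowSums(tr)), rep(1000, 11), tolerance = 1e-9)
    expect_true(all(tr >= 0))
    # death occupancy is monotone, strictly so under positive mortality
    expect_true(all(diff(tr[, "death"]) > 0))
  }
})

test_that("with no mortality and no crossovers the cohort stays in its pathway", {
  p <- zero_dynamics_params()
  tr <- run_cohort(p, "pharmacotherapy")
  drug_mass <- tr[, "drug_y1"] + tr[, "drug_later"]
  expect_equal(unname(drug_mass), rep(1000, 11), tolerance = 1e-9)
  # first-year state is transient: emptied after one cycle, never refilled
  expect_identical(unname(tr[-1, "drug_y1"]), rep(0, 10))
})

test_that("accrual uses start-of-cycle occupancy with end-of-cycle discounting", {
  # one person, one cycle on the drug: cost = 146.36 / 1.07
  p1 <- bph_parameters(settings = list(cohort_size = 1, horizon = 1L))
  out <- run_arm(p1, "pharmacotherapy")$outcomes
  expect_equal(out$total_cost, 146.36 / 1.07, tolerance = 1e-12)
  # discounting from year 0 leaves the first cycle undiscounted
  p0 <- bph_parameters(settings = list(cohort_size = 1, horizon = 1L,
                                       discount_from = "year_0"))
  expect_equal(run_arm(p0, "pharmacotherapy")$outcomes$total_cost, 146.36,
               tolerance = 1e-12)

  # 1000 persons held 10 cycles at constant utility: closed-form annuity
  pz <- zero_dynamics_params()
  outq <- run_arm(pz, "surgery")$outcomes
  u_y1 <- state_utility(pz, "surg_y1", 1)
  u_later <- state_utility(pz, "surg_later", 2)
  expect_equal(u_y1, u_later) # same composition either phase
  expect_equal(outq$total_qaly,
               1000 * u_y1 * sum(1.03^-(1:10)), tolerance = 1e-9)

  # totals equal the sum of the per-cycle breakdown
  out2 <- run_arm(base_params(), "pharmacotherapy")$outcomes
  expect_equal(out2$total_cost, sum(out2$per_cycle$disc_cost))
  expect_equal(out2$total_qaly, sum(out2$per_cycle$disc_qaly))
})

test_that("noncompliant patients accrue surgical values one cycle later by default", {
  p_end <- base_params()
  p_imm <- bph_parameters(settings = list(crossover_timing = "immediate"))
  c_end <- run_arm(p_end, "pharmacotherapy")$outcomes
  c_imm <- run_arm(p_imm, "pharmacotherapy")$outcomes
  # immediate booking moves 300 crossover patients from drug to surgical
  # first-year values within cycle 1
  flow <- 1000 * 0.3
  expected_extra <- flow * (840.96 - 146.36) / 1.07
  expect_equal(c_imm$total_cost - c_end$total_cost, expected_extra,
               tolerance = 1e-9)
  # surgery arm is unaffected by the flag
  expect_equal(run_arm(p_imm, "surgery")$outcomes$total_cost,
               run_arm(p_end, "surgery")$outcomes$total_cost)
})

test_that("discounted totals are non-increasing in each discount rate", {
  rates <- c(0, 0.03, 0.07, 0.12)
  costs <- vapply(rates, function(r) {
    run_arm(bph_parameters(settings = list(discount_cost = r)),
            "pharmacotherapy")$outcomes$total_cost
  }, numeric(1))
  qalys <- vapply(rates, function(r) {
    run_arm(bph_parameters(settings = list(discount_utility = r)),
            "surgery")$outcomes$total_qaly
  }, numeric(1))
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})

test_that("the chemoprevention toggle rescales only early drug-arm cancer inflow", {
  on <- base_params()
  off <- bph_parameters(transitions = list(chemoprevention_enabled = FALSE))
  for (cyc in 1:10) {
    m_on <- build_transition_matrix(on, cyc)
    m_off <- build_transition_matrix(off, cyc)
    if (cyc <= 2) {
      for (row in c("drug_y1", "drug_later")) {
        expect_equal(m_on[row, "pc_y1"] / m_off[row, "pc_y1"], 0.75,
                     tolerance = 1e-12)
        # the difference is absorbed by the residual stay probability
        expect_equal(m_on[row, "drug_later"] - m_off[row, "drug_later"],
                     m_off[row, "pc_y1"] - m_on[row, "pc_y1"],
                     tolerance = 1e-12)
        # everything else in the row is untouched
        other <- setdiff(colnames(m_on), c("pc_y1", "drug_later"))
        expect_equal(m_on[row, other], m_off[row, other])
      }
      surg_rows <- c("surg_y1", "surg_later", "pc_y1", "pc_later", "death")
      expect_equal(m_on[surg_rows, ], m_off[surg_rows, ])
    } else {
      expect_equal(m_on, m_off)
    }
  }
  # surgery arm outcomes are identical under either setting
  expect_equal(run_arm(on, "surgery")$outcomes$total_cost,
               run_arm(off, "surgery")$outcomes$total_cost)
  expect_equal(run_arm(on, "surgery")$outcomes$total_qaly,
               run_arm(off, "surgery")$outcomes$total_qaly)
})

test_that("half-cycle correction averages start- and end-of-cycle occupancy", {
  p <- base_params()
  ph <- bph_parameters(settings = list(half_cycle_correction = TRUE))
  tr <- run_cohort(p, "surgery")
  out <- accumulate(tr, p)
  outh <- accumulate(run_cohort(ph, "surgery"), ph)
  # with positive mortality the averaged occupancy is smaller every cycle
  expect_lt(outh$total_qaly, out$total_qaly)
  # manual check on cycle 1 cost
  costs <- state_costs(p)
  occ_avg <- (tr[1, ] + tr[2, ]) / 2
  expect_equal(outh$per_cycle$cost[1], sum(occ_avg * costs), tolerance = 1e-9)
})
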