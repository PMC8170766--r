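test_that("defaults reproduce every frozen published constant exactly", {
  p <- base_params()
  fc <- frozen_constants
  expect_identical(p$transitions$p_noncompliance_y1, fc$p_noncompliance_y1)
  expect_identical(p$transitions$p_drug_to_surgery_later, fc$p_drug_to_surgery_later)
  expect_identical(p$transitions$p_drug_to_pc, fc$p_drug_to_pc)
  expect_identical(p$transitions$p_surgery_to_pc, fc$p_surgery_to_pc)
  expect_identical(p$transitions$pc_excess_death, fc$pc_excess_death)
  expect_equal(surgery_death_addon(p), fc$surgery_death_addon_blended)
  expect_identical(p$costs$drug_y1, fc$cost_drug_y1)
  expect_identical(p$costs$drug_later, fc$cost_drug_later)
  expect_identical(p$costs$surg_y1, fc$cost_surg_y1)
  expect_identical(p$costs$surg_later, fc$cost_surg_later)
  expect_identical(p$costs$pc_y1, fc$cost_pc_y1)
  expect_identical(p$costs$pc_later, fc$cost_pc_later)
  expect_identical(p$costs$death, fc$cost_death)
  expect_identical(p$costs$infection_management, fc$cost_infection)
  expect_identical(p$settings$cohort_size, fc$cohort_size)
  expect_identical(p$settings$horizon, fc$horizon)
  expect_identical(p$settings$start_age, fc$start_age)
  expect_identical(p$settings$discount_cost, fc$discount_cost)
  expect_identical(p$settings$discount_utility, fc$discount_utility)
  expect_identical(p$settings$wtp, fc$wtp)
  expect_identical(p$surgery_mix$share_turp, fc$share_turp)
  expect_identical(p$surgery_mix$share_op, fc$share_op)
  expect_identical(p$utility$pc_utility, fc$pc_utility)
  expect_identical(p$utility$baseline_ipss, fc$baseline_ipss)
  expect_identical(p$utility$surgical_improvement, fc$surgical_improvement)
  expect_identical(p$transitions$chemoprevention_rr, fc$chemoprevention_rr)
})

test_that("state space has seven states with death absorbing and y1 states transient", {
  st <- bph_states()
  expect_length(st, 7)
  expect_identical(st[7], "death")
  expect_setequal(bph_arms(), c("drug_y1", "surg_y1"))
  p <- base_params()
  m <- build_transition_matrix(p, 1)
  expect_identical(unname(m["death", ]), c(0, 0, 0, 0, 0, 0, 1))
  # y1 states cannot be re-entered from themselves: no self-loop
  for (s in c("drug_y1", "surg_y1", "pc_y1")) expect_identical(m[s, s], 0)
})

test_that("empty config yields the base case and invalid configs are rejected", {
  p <- load_model()
  expect_identical(p$settings$cohort_size, 1000)
  expect_identical(p$settings$horizon, 10L)
  expect_identical(p$settings$wtp, 3701)
  expect_error(load_model(list(surgery_mix = list(share_turp = 1.1))),
               "range error")
  expect_error(load_model(list(nonsense = 1)), "unknown key")
  expect_error(load_model(list(settings = list(discout_cost = 0))),
               "unknown key")
  expect_error(load_model(list(schema_version = 99)), "schema_version")
  expect_error(load_model(list(transitions = list(p_drug_to_pc = -0.1))),
               "range error")
})

test_that("zero cost discounting makes discounted totals equal raw sums", {
  p <- load_model(list(settings = list(discount_cost = 0)))
  out <- run_arm(p, "surgery")$outcomes
  expect_equal(out$total_cost, sum(out$per_cycle$cost))
  # utility still discounted at 3%
  expect_lt(out$total_qaly, sum(out$per_cycle$qaly))
})

test_that("parameter sets round-trip through config serialization", {
  p <- bph_parameters(
    settings = list(start_age = 60, discount_cost = 0.05),
    transitions = list(chemoprevention_enabled = FALSE),
    costs = list(tariff_sector = "public")
  )
  # in-memory round trip
  p2 <- load_model(as_model_config(p))
  expect_equal(p2, p)
  # file round trips, both formats
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_model_config(p, path)
    p3 <- load_model(path)
    unlink(path)
    expect_equal(p3, p, tolerance = 1e-12)
  }
})

test_that("scenario catalogue holds the base case plus the eight analysed variants", {
  cat9 <- scenario_catalog()
  expect_length(cat9, 9)
  expect_identical(names(cat9)[1], "base")
  base <- cat9$base
  expect_null(base$chemoprevention_enabled)
  expect_null(base$surgery_mix_override)
  expect_null(base$tariff_sector_override)
  expect_null(base$age_band)
  expect_identical(cat9$age_40_50$age_band$baseline_utility, 1)
  expect_identical(cat9$age_50_60$age_band$baseline_utility, 0.94)
  expect_identical(cat9$age_60_70$age_band$baseline_utility, 0.88)
  expect_false(cat9$no_chemoprevention$chemoprevention_enabled)
  expect_identical(cat9$op_only$surgery_mix_override$share_op, 1)
  expect_identical(cat9$turp_only$surgery_mix_override$share_turp, 1)
  expect_identical(cat9$public_tariff$tariff_sector_override, "public")
  expect_identical(cat9$private_tariff$tariff_sector_override, "private")

  p40 <- apply_scenario(base_params(), cat9$age_40_50)
  expect_identical(p40$settings$start_age, 40)
  expect_identical(age_baseline_utility(p40, 40), 1)
})

test_that("parameter paths read and write every DSA-addressable input", {
  p <- base_params()
  for (path in dsa_parameter_paths()) {
    v <- get_param(p, path)
    expect_true(is.numeric(v) && length(v) == 1)
    # halving any parameter must round-trip through set/get
    p2 <- set_param(p, path, v / 2)
    expect_equal(get_param(p2, path), v / 2)
  }
  # cost.drug addresses both drug-phase costs jointly
  p3 <- set_param(p, "cost.drug", 100)
  expect_identical(p3$costs$drug_y1, 100)
  expect_identical(p3$costs$drug_later, 100)
  expect_error(get_param(p, "cost.unknown"), "unknown parameter path")
})

test_that("structural validation names the offending field", {
  expect_error(bph_parameters(settings = list(cohort_size = 0)), "cohort_size")
  expect_error(bph_parameters(settings = list(discount_cost = 1)), "discount_cost")
  expect_error(bph_parameters(transitions = list(pc_excess_death = 1.2)),
               "pc_excess_death")
  expect_error(bph_parameters(costs = list(pc_y1 = -5)), "costs.pc_y1")
  expect_error(bph_parameters(surgery_mix = list(share_turp = 0.5, share_op = 0.2)),
               "sum to 1")
  expect_error(bph_parameters(costs = list(tariff_sector = "mixed")),
               "tariff_sector")
  # life table must cover the ages the cohort reaches
  lt <- as_life_table(data.frame(age_low = 40, age_high = 75, qx = 0.05))
  expect_error(bph_parameters(life_table = lt), "coverage error")
})
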