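#' Convert a constant event rate to a per-period probability
#'
#' Uses the exponential relation `p = 1 - exp(-r t)` for an instantaneous
#' rate `r` assumed constant over the period `t`.
#'
#' @param rate Events per year, `>= 0`.
#' @param t Period length in years, `> 0`.
#' @return Probability in \[0, 1).
#' @export
#' @examples
#' rate_to_probability(0.18, 1)  # 0.16473
rate_to_probability <- function(rate, t = 1) {
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("range error: `t` must be > 0", call. = FALSE)
  }
  if (any(rate < 0)) stop("range error: `rate` must be >= 0", call. = FALSE)
  1 - exp(-rate * t)
}

lookup_life_table <- function(life_table, age) {
  hit <- which(age >= life_table$age_low & age < life_table$age_high)
  if (length(hit) != 1) {
    stop("coverage error: age ", age, " not covered by the life table",
         call. = FALSE)
  }
  life_table$qx[hit]
}

#' Annual death probability for a state at a given age
#'
#' All-cause background mortality is read from the life-table band covering
#' the current age. State-specific excess risk is added on top: the first
#' surgical year adds the mix-blended perioperative risk (0.0012 at the
#' 80/20 TURP/OP mix; later surgical years add it only when
#' `addon_first_year_only` is disabled), and prostate-cancer states add the
#' cancer excess death probability (0.18). The result is capped at 1.
#'
#' @param age Current age in years.
#' @param life_table Life table (see [make_life_table()]).
#' @param state One of [bph_states()].
#' @param params A `bph_parameters` object (transition spec and surgical mix).
#' @return Probability of dying within the cycle.
#' @export
death_probability <- function(age, life_table, state, params) {
  base <- lookup_life_table(life_table, age)
  tr <- params$transitions
  addon <- 0
  if (state == "surg_y1") {
    addon <- surgery_death_addon(params)
  } else if (state == "surg_later" && !isTRUE(tr$addon_first_year_only)) {
    addon <- surgery_death_addon(params)
  } else if (state %in% c("pc_y1", "pc_later")) {
    addon <- tr$pc_excess_death
  }
  min(base + addon, 1)
}

#' Annual probability of progressing to prostate cancer
#'
#' Drug states carry the background incidence (0.000836/yr), reduced by the
#' chemoprevention relative reduction (25%) during the first two treatment
#' years when the effect is enabled. Post-surgical states carry 0.0011/yr.
#'
#' @param state A living non-cancer state.
#' @param cycle Model cycle, 1-based.
#' @param params A `bph_parameters` object.
#' @return Transition probability into the first cancer year.
#' @export
cancer_probability <- function(state, cycle, params) {
  tr <- params$transitions
  switch(state,
    drug_y1 = , drug_later = {
      p <- tr$p_drug_to_pc
      if (isTRUE(tr$chemoprevention_enabled) &&
          cycle %in% tr$chemoprevention_cycles) {
        p <- p * (1 - tr$chemoprevention_rr)
      }
      p
    },
    surg_y1 = , surg_later = tr$p_surgery_to_pc,
    stop("validation error: no cancer transition from state: ", state,
         call. = FALSE)
  )
}

#' Build the transition matrix for one cycle
#'
#' Encodes the model topology: first-year drug patients either cross over to
#' surgery through noncompliance, progress to cancer, die, or settle into
#' the later-drug state; later drug years feed surgery at the maintained
#' crossover probability; surgical states feed cancer and death and
#' otherwise persist; cancer states feed death and otherwise persist; death
#' is absorbing. Each remaining ("stay") probability is the residual after
#' subtracting the row's outgoing probabilities from one. The matrix is
#' identical for the two arms — they differ only in their entry state.
#'
#' @param params A `bph_parameters` object.
#' @param cycle Model cycle in `1..horizon`; sets the cohort age for the
#'   mortality lookup (`start_age + cycle - 1` unless `freeze_age`).
#' @return 7x7 row-stochastic matrix with dimnames [bph_states()].
#' @export
build_transition_matrix <- function(params, cycle) {
  s <- params$settings
  if (cycle < 1 || cycle > s$horizon) {
    stop("range error: cycle must be in 1..", s$horizon, call. = FALSE)
  }
  age <- if (isTRUE(s$freeze_age)) s$start_age else s$start_age + cycle - 1
  states <- bph_states()
  m <- matrix(0, 7, 7, dimnames = list(states, states))
  tr <- params$transitions

  residual <- function(row, stay) {
    res <- 1 - sum(m[row, ])
    if (res < -1e-12) {
      stop("infeasible parameters: outgoing probabilities of state `", row,
           "` at cycle ", cycle, " sum to ", format(sum(m[row, ])),
           " > 1", call. = FALSE)
    }
    m[row, stay] <<- max(res, 0)
  }

  for (row in c("drug_y1", "drug_later")) {
    m[row, "surg_y1"] <- if (row == "drug_y1") tr$p_noncompliance_y1
                         else tr$p_drug_to_surgery_later
    m[row, "pc_y1"] <- cancer_probability(row, cycle, params)
    m[row, "death"] <- death_probability(age, params$life_table, row, params)
    residual(row, "drug_later")
  }
  for (row in c("surg_y1", "surg_later")) {
    m[row, "pc_y1"] <- cancer_probability(row, cycle, params)
    m[row, "death"] <- death_probability(age, params$life_table, row, params)
    residual(row, "surg_later")
  }
  for (row in c("pc_y1", "pc_later")) {
    m[row, "death"] <- death_probability(age, params$life_table, row, params)
    residual(row, "pc_later")
  }
  m["death", "death"] <- 1
  m
}

#' Propagate the cohort through the model horizon
#'
#' Deterministic cohort simulation: the whole cohort starts in the arm's
#' entry state, and each cycle's occupancy vector is the previous one
#' multiplied by that cycle's transition matrix. Ageing advances the
#' life-table lookup by one year per cycle.
#'
#' @param params A `bph_parameters` object.
#' @param arm `"pharmacotherapy"` or `"surgery"`.
#' @return A `bph_trace`: `(horizon + 1) x 7` occupancy matrix in persons,
#'   row `t + 1` holding the state mix after `t` cycles.
#' @export
#' @examples
#' tr <- run_cohort(bph_parameters(), "pharmacotherapy")
#' rowSums(tr)  # conserved cohort
run_cohort <- function(params, arm = c("pharmacotherapy", "surgery")) {
  arm <- match.arg(arm)
  s <- params$settings
  states <- bph_states()
  trace <- matrix(0, nrow = s$horizon + 1, ncol = length(states),
                  dimnames = list(0:s$horizon, states))
  trace[1, bph_arms()[[arm]]] <- s$cohort_size
  for (t in seq_len(s$horizon)) {
    trace[t + 1, ] <- trace[t, ] %*% build_transition_matrix(params, t)
  }
  structure(trace, class = c("bph_trace", class(trace)), arm = arm)
}

discount_factors <- function(rate, horizon, from = "year_1") {
  t <- seq_len(horizon)
  if (identical(from, "year_0")) t <- t - 1
  (1 + rate)^(-t)
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Occupancy during cycle `t` is the state mix at the start of the cycle
#' (trace row `t - 1`): transitions take effect at cycle end, so a patient
#' crossing over from drug to surgery in cycle 1 accrues drug cost and
#' utility in cycle 1 and surgical values from cycle 2 (the
#' `crossover_timing = "immediate"` setting instead books the noncompliant
#' flow at surgical values already in its crossover cycle). Cycle `t`
#' contributions are discounted by `(1 + d)^-t` with `d` the respective
#' annual rate (`discount_from = "year_0"` shifts the exponent to `t - 1`).
#' An optional half-cycle correction averages start- and end-of-cycle
#' occupancy.
#'
#' @param trace A `bph_trace` from [run_cohort()].
#' @param params The same `bph_parameters` used to produce the trace.
#' @return A `bph_outcomes` list: `total_cost`, `total_qaly`, and a
#'   `per_cycle` data frame with raw and discounted per-cycle contributions.
#' @export
accumulate <- function(trace, params) {
  s <- params$settings
  horizon <- s$horizon
  stopifnot(nrow(trace) == horizon + 1)
  costs <- state_costs(params)
  u <- utility_surface(params)
  dfc <- discount_factors(s$discount_cost, horizon, s$discount_from)
  dfu <- discount_factors(s$discount_utility, horizon, s$discount_from)

  cyc_cost <- cyc_qaly <- numeric(horizon)
  for (t in seq_len(horizon)) {
    occ <- trace[t, ]
    if (isTRUE(s$half_cycle_correction)) occ <- (occ + trace[t + 1, ]) / 2
    if (identical(s$crossover_timing, "immediate") && occ[["drug_y1"]] > 0) {
      flow <- occ[["drug_y1"]] * params$transitions$p_noncompliance_y1
      occ[["drug_y1"]] <- occ[["drug_y1"]] - flow
      occ[["surg_y1"]] <- occ[["surg_y1"]] + flow
    }
    cyc_cost[t] <- sum(occ * costs)
    cyc_qaly[t] <- sum(occ * u[t, ])
  }
  per_cycle <- data.frame(
    cycle = seq_len(horizon),
    cost = cyc_cost, qaly = cyc_qaly,
    disc_cost = cyc_cost * dfc, disc_qaly = cyc_qaly * dfu
  )
  structure(
    list(total_cost = sum(per_cycle$disc_cost),
         total_qaly = sum(per_cycle$disc_qaly),
         per_cycle = per_cycle,
         arm = attr(trace, "arm"),
         settings = s),
    class = "bph_outcomes"
  )
}

#' @export
print.bph_outcomes <- function(x, ...) {
  cat(sprintf("<bph_outcomes> arm: %s\n", x$arm %||% "?"))
  cat(sprintf("  discounted total cost: %.2f USD\n", x$total_cost))
  cat(sprintf("  discounted total QALY: %.2f\n", x$total_qaly))
  invisible(x)
}

#' Run one arm end to end
#'
#' @param params A `bph_parameters` object.
#' @param arm `"pharmacotherapy"` or `"surgery"`.
#' @return List with the occupancy `trace` and the accumulated `outcomes`.
#' @export
run_arm <- function(params, arm) {
  trace <- run_cohort(params, arm)
  list(arm = arm, trace = trace, outcomes = accumulate(trace, params))
}

#' Export a cohort trace as a data frame
#'
#' @param trace A `bph_trace`.
#' @return Data frame with a `cycle` column (0-based state mix snapshots)
#'   and one column per state; suitable for `write.csv()`.
#' @export
trace_as_df <- function(trace) {
  data.frame(cycle = as.integer(rownames(trace)),
             as.data.frame(unclass(trace), row.names = NULL))
}
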