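# Stand-in inputs (life tables, complication profiles) and the
# individual-level microsimulation used to validate the cohort engine.

#' Construct or look up a life table
#'
#' The default preset is the synthetic male life table shipped with the
#' package (see `inst/extdata/life_table_synthetic.csv`): assumed, plausible
#' annual death probabilities by ten-year band, monotone in age — not
#' national statistics. A `"zero"` preset (no background mortality) is
#' provided for identity checks.
#'
#' @param preset `"synthetic_default"` (default), `"zero"`, or a data frame
#'   of bands (`age_low`, `age_high`, `qx`) to validate and use directly.
#' @return A `bph_life_table` data frame.
#' @export
#' @examples
#' lt <- make_life_table()
#' lt$qx[lt$age_low == 70]
make_life_table <- function(preset = "synthetic_default") {
  if (is.data.frame(preset)) return(as_life_table(preset))
  bands <- switch(preset,
    synthetic_default = read_fixture("life_table_synthetic.csv"),
    zero = {
      b <- read_fixture("life_table_synthetic.csv")
      b$qx <- 0
      b
    },
    stop("lookup error: unknown life-table preset: ", preset, call. = FALSE)
  )
  as_life_table(bands)
}

#' @rdname make_life_table
#' @param bands Data frame with columns `age_low`, `age_high`, `qx`.
#' @export
as_life_table <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("age_low", "age_high", "qx") %in% names(bands)))
  bands <- bands[order(bands$age_low), c("age_low", "age_high", "qx")]
  rownames(bands) <- NULL
  validate_life_table(structure(bands, class = c("bph_life_table",
                                                 class(bands))))
}

validate_life_table <- function(lt) {
  if (any(lt$qx < 0) || any(lt$qx >= 1)) {
    stop("range error: life-table qx must be in [0, 1)", call. = FALSE)
  }
  if (any(lt$age_high <= lt$age_low)) {
    stop("validation error: life-table bands must have age_high > age_low",
         call. = FALSE)
  }
  if (nrow(lt) > 1) {
    if (any(lt$age_low[-1] < lt$age_high[-nrow(lt)])) {
      stop("validation error: life-table bands must not overlap", call. = FALSE)
    }
    if (any(diff(lt$qx) < 0)) {
      stop("validation error: life-table qx must be non-decreasing with age",
           call. = FALSE)
    }
  }
  invisible(lt)
}

#' Grid of life tables over the 70-80 band
#'
#' Generates life tables whose 70-80 band takes each value of a grid, the
#' other bands scaled proportionally so monotonicity is preserved. Useful
#' for exploring how background mortality moves the results.
#'
#' @param min,max,step Grid over the 70-80 annual death probability.
#' @return Named list of `bph_life_table` objects.
#' @export
life_table_grid <- function(min = 0.02, max = 0.08, step = 0.01) {
  stopifnot(min > 0, max < 1, step > 0, min <= max)
  base <- make_life_table()
  anchor <- base$qx[base$age_low == 70]
  vals <- seq(min, max, by = step)
  out <- lapply(vals, function(v) {
    b <- base
    b$qx <- pmin(b$qx * (v / anchor), 1 - 1e-9)
    as_life_table(as.data.frame(unclass(b)))
  })
  names(out) <- formatC(vals, format = "g")
  out
}

#' Complication profile for a surgery type
#'
#' Returns the (synthetic) complication fixture rows for one surgery type:
#' complication label, annual probability, utility decrement, and management
#' cost.
#'
#' @param params A `bph_parameters` object.
#' @param type `"TURP"` or `"OP"`.
#' @return Data frame of complications.
#' @export
complication_profile <- function(params, type = c("TURP", "OP")) {
  type <- match.arg(type)
  comp <- params$utility$complications
  out <- comp[comp$surgery_type == type, ]
  rownames(out) <- NULL
  out
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Individual-level microsimulation of one strategy arm
#'
#' Brute-force validation oracle for the cohort recursion: simulates `n`
#' independent patients, each cycle sampling the next state from the same
#' transition matrices the cohort engine builds
#' ([build_transition_matrix()]) and accruing the same per-state discounted
#' costs and utilities ([state_costs()], [utility_surface()]). State
#' propagation and accrual are implemented independently of the cohort
#' engine, so agreement of the means with [accumulate()] exercises the
#' expectation calculation end to end. Results are bit-reproducible for a
#' given `(n, seed, params)`.
#'
#' Only the default accrual conventions are supported
#' (`crossover_timing = "end_of_cycle"`, no half-cycle correction).
#'
#' @param params A `bph_parameters` object.
#' @param arm `"pharmacotherapy"` or `"surgery"`.
#' @param n Number of simulated patients.
#' @param seed RNG seed (the global RNG state is restored afterwards).
#' @return A `bph_microsim` list: per-person `mean_cost`/`mean_qaly` with
#'   standard errors, and `counts`, a `(horizon + 1) x 7` matrix of state
#'   occupancy snapshots comparable to `run_cohort()`'s trace scaled by
#'   `n / cohort_size`.
#' @export
microsim_oracle <- function(params, arm = c("pharmacotherapy", "surgery"),
                            n, seed) {
  arm <- match.arg(arm)
  stopifnot(n >= 1)
  s <- params$settings
  if (!identical(s$crossover_timing, "end_of_cycle") ||
      isTRUE(s$half_cycle_correction)) {
    stop("microsim_oracle supports only the default accrual conventions",
         call. = FALSE)
  }
  horizon <- s$horizon
  states <- bph_states()
  costs <- state_costs(params)
  u <- utility_surface(params)
  dfc <- discount_factors(s$discount_cost, horizon, s$discount_from)
  dfu <- discount_factors(s$discount_utility, horizon, s$discount_from)
  mats <- lapply(seq_len(horizon), build_transition_matrix, params = params)

  with_seed(seed, {
    state <- rep(match(bph_arms()[[arm]], states), n)
    cost_i <- qaly_i <- numeric(n)
    counts <- matrix(0L, horizon + 1, length(states),
                     dimnames = list(0:horizon, states))
    counts[1, ] <- tabulate(state, nbins = 7)
    for (t in seq_len(horizon)) {
      cost_i <- cost_i + costs[state] * dfc[t]
      qaly_i <- qaly_i + u[t, state] * dfu[t]
      m <- mats[[t]]
      new_state <- state
      for (si in unique(state)) {
        idx <- which(state == si)
        new_state[idx] <- sample.int(7, length(idx), replace = TRUE,
                                     prob = m[si, ])
      }
      state <- new_state
      counts[t + 1, ] <- tabulate(state, nbins = 7)
    }
    structure(
      list(n = n, seed = seed, arm = arm,
           mean_cost = mean(cost_i),
           se_cost = stats::sd(cost_i) / sqrt(n),
           mean_qaly = mean(qaly_i),
           se_qaly = stats::sd(qaly_i) / sqrt(n),
           counts = counts),
      class = "bph_microsim"
    )
  })
}

#' @export
print.bph_microsim <- function(x, ...) {
  cat(sprintf("<bph_microsim> arm: %s, n = %d, seed = %d\n",
              x$arm, x$n, x$seed))
  cat(sprintf("  mean cost %.2f (SE %.3f), mean QALY %.4f (SE %.5f) per person\n",
              x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}

#' Randomly perturbed but valid parameter set
#'
#' Jitters every scalar model input uniformly within a relative magnitude,
#' clamping probabilities, utilities and discount rates to their valid
#' ranges, and revalidates. Used as a property-test input generator: the
#' cohort engine and the microsimulation oracle must agree on any set this
#' produces.
#'
#' @param params Base `bph_parameters`.
#' @param magnitude Relative jitter half-width, in \[0, 0.5\].
#' @param seed RNG seed (global RNG state restored afterwards).
#' @return A validated `bph_parameters`.
#' @export
perturb_parameters <- function(params, magnitude, seed) {
  stopifnot(magnitude >= 0, magnitude <= 0.5)
  with_seed(seed, {
    jit <- function(x, lo = 0, hi = Inf) {
      pmin(pmax(x * (1 + stats::runif(length(x), -magnitude, magnitude)), lo), hi)
    }
    tr <- params$transitions
    for (f in c("p_noncompliance_y1", "p_drug_to_surgery_later",
                "p_drug_to_pc", "p_surgery_to_pc", "pc_excess_death",
                "surgery_death_addon_turp", "surgery_death_addon_op")) {
      tr[[f]] <- jit(tr[[f]], 0, 0.95)
    }
    params$transitions <- tr
    for (f in c("drug_y1", "drug_later", "surg_y1", "surg_later",
                "pc_y1", "pc_later")) {
      params$costs[[f]] <- jit(params$costs[[f]])
    }
    params$utility$pc_utility <- jit(params$utility$pc_utility, 0, 1)
    params$utility$surgical_improvement <-
      jit(params$utility$surgical_improvement, 0,
          params$utility$baseline_ipss - params$utility$trajectory$floor)
    params$utility$complication_scale <-
      jit(params$utility$complication_scale, 0, 2)
    params$settings$discount_cost <- jit(params$settings$discount_cost, 0, 0.5)
    params$settings$discount_utility <-
      jit(params$settings$discount_utility, 0, 0.5)
    validate_parameters(params)
  })
}
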