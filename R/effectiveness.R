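#' IPSS trajectory under pharmacotherapy
#'
#' Holds the observed trial IPSS values under dutasteride (years 1-4:
#' 16.7, 12.3, 11.3, 10.6) together with the exclusion set and clamping
#' bounds used when extrapolating the response over the model horizon. The
#' first-year value reflects the pre-response baseline and is excluded from
#' the regression fit.
#'
#' @param observed Data frame with columns `year` and `ipss`.
#' @param exclude_years Integer years excluded from the regression fit.
#' @param floor,ceiling Clamping bounds for extrapolated scores (IPSS is
#'   defined on 1-35 in the utility table).
#' @return An object of class `bph_ipss_trajectory` (unfitted).
#' @export
#' @examples
#' traj <- fit_ipss_regression(bph_ipss_trajectory())
#' c(traj$slope, traj$intercept)
bph_ipss_trajectory <- function(observed = data.frame(
                                  year = 1:4,
                                  ipss = c(16.7, 12.3, 11.3, 10.6)),
                                exclude_years = 1L,
                                floor = 1, ceiling = 35) {
  stopifnot(is.data.frame(observed),
            all(c("year", "ipss") %in% names(observed)),
            floor < ceiling)
  structure(
    list(observed = observed, exclude_years = exclude_years,
         floor = floor, ceiling = ceiling,
         slope = NULL, intercept = NULL),
    class = "bph_ipss_trajectory"
  )
}

#' Fit the linear IPSS extrapolation
#'
#' Ordinary least squares of IPSS on year over the non-excluded observation
#' years. With the default trajectory (years 2-4: 12.3, 11.3, 10.6) the fit
#' is slope -0.85 IPSS/yr, intercept 13.95.
#'
#' @param trajectory A `bph_ipss_trajectory`.
#' @return The trajectory with `slope` and `intercept` filled in.
#' @export
fit_ipss_regression <- function(trajectory) {
  stopifnot(inherits(trajectory, "bph_ipss_trajectory"))
  keep <- !(trajectory$observed$year %in% trajectory$exclude_years)
  pts <- trajectory$observed[keep, ]
  if (nrow(pts) < 2) {
    stop("insufficient data: need at least 2 non-excluded (year, IPSS) points",
         call. = FALSE)
  }
  fit <- stats::lm(ipss ~ year, data = pts)
  trajectory$intercept <- unname(stats::coef(fit)[1])
  trajectory$slope <- unname(stats::coef(fit)[2])
  trajectory
}

#' Extrapolated IPSS in a given model year
#'
#' Year 1 returns the observed baseline score. Later years return the fitted
#' line clamped to the trajectory's bounds, or (optionally) the observed
#' trial values where available.
#'
#' @param trajectory A fitted `bph_ipss_trajectory`.
#' @param year Model year, 1-based.
#' @param use_observed If `TRUE`, years with an observed value return it
#'   instead of the fitted line. Default `FALSE`: one consistent model line
#'   for all years past the first.
#' @return IPSS score.
#' @export
ipss_at <- function(trajectory, year, use_observed = FALSE) {
  stopifnot(inherits(trajectory, "bph_ipss_trajectory"), year >= 1)
  if (is.null(trajectory$slope)) {
    stop("state error: trajectory is unfitted; call fit_ipss_regression() first",
         call. = FALSE)
  }
  obs <- trajectory$observed
  if (year %in% trajectory$exclude_years && year %in% obs$year) {
    return(obs$ipss[match(year, obs$year)])
  }
  if (use_observed && year %in% obs$year) {
    return(obs$ipss[match(year, obs$year)])
  }
  val <- trajectory$intercept + trajectory$slope * year
  min(max(val, trajectory$floor), trajectory$ceiling)
}

#' Map an IPSS score to a utility weight
#'
#' Integer scores return the tabulated utility exactly; non-integer scores
#' are linearly interpolated between the adjacent integer rows (default), or
#' rounded to the nearest integer row when `method = "round"`.
#'
#' @param params A `bph_parameters` object (its `utility$ipss_utility` table
#'   is used).
#' @param ipss Score(s) in \[1, 35\].
#' @param method `"interpolate"` (default) or `"round"`; falls back to the
#'   parameter set's `utility$ipss_lookup` setting when missing.
#' @return Utility weight(s) in \[0, 1\].
#' @export
#' @examples
#' p <- bph_parameters()
#' ipss_to_utility(p, 8)    # 0.944
#' ipss_to_utility(p, 8.2)  # 0.9424
ipss_to_utility <- function(params, ipss, method = NULL) {
  tab <- params$utility$ipss_utility
  method <- method %||% params$utility$ipss_lookup
  if (any(ipss < min(tab$ipss)) || any(ipss > max(tab$ipss))) {
    stop("range error: IPSS must be in [", min(tab$ipss), ", ",
         max(tab$ipss), "]", call. = FALSE)
  }
  if (identical(method, "round")) {
    return(tab$utility[match(round(ipss), tab$ipss)])
  }
  stats::approx(tab$ipss, tab$utility, xout = ipss, method = "linear")$y
}

#' Post-surgical IPSS
#'
#' The surgical response is a fixed symptomatic improvement applied to the
#' shared baseline score (default 16.7 - 8.5 = 8.2), identical for both
#' surgery types. Results below the trajectory floor are clamped with a
#' warning.
#'
#' @param params A `bph_parameters` object.
#' @return IPSS score after surgery.
#' @export
post_surgery_ipss <- function(params) {
  u <- params$utility
  out <- u$baseline_ipss - u$surgical_improvement
  floor <- u$trajectory$floor
  if (out < floor) {
    warning("post-surgical IPSS ", out, " below floor; clamped to ", floor,
            call. = FALSE)
    out <- floor
  }
  out
}

#' Expected annual utility decrement from surgical complications
#'
#' For each surgery type, the expected decrement is the incidence-weighted
#' sum of the per-complication utility losses; the blended value weights the
#' two types by the surgical mix. The global `utility$complication_scale`
#' multiplier (a sensitivity-analysis handle) is applied.
#'
#' @param params A `bph_parameters` object.
#' @param type `"blended"` (default), `"TURP"` or `"OP"`.
#' @return Expected utility decrement per post-surgical year.
#' @export
complication_disutility <- function(params, type = "blended") {
  comp <- params$utility$complications
  per_type <- function(tp) {
    rows <- comp[comp$surgery_type == tp, ]
    sum(rows$annual_probability * rows$utility_decrement)
  }
  raw <- switch(type,
    blended = params$surgery_mix$share_turp * per_type("TURP") +
      params$surgery_mix$share_op * per_type("OP"),
    TURP = per_type("TURP"),
    OP = per_type("OP"),
    stop("validation error: unknown surgery type: ", type, call. = FALSE)
  )
  raw * params$utility$complication_scale
}

#' Annual utility of a health state in a given cycle
#'
#' Composes the utility model: drug states multiply the age-band baseline
#' utility by the IPSS-derived utility for that model year; surgical states
#' multiply the baseline by the post-surgical IPSS utility and subtract the
#' expected complication decrement; prostate-cancer states use the cancer
#' utility (0.62) directly, overriding the IPSS pathway; death is 0. The
#' result is clamped to \[0, 1\].
#'
#' @param params A `bph_parameters` object.
#' @param state One of [bph_states()].
#' @param cycle Model cycle (year), 1-based; determines both the IPSS year
#'   and the cohort's current age (`start_age + cycle - 1`, unless
#'   `settings$freeze_age` is set).
#' @param disutility Complication decrement override; `NULL` (default)
#'   computes the mix-blended value from the complication profiles. Applies
#'   to surgical states only.
#' @return Utility in \[0, 1\] for one year in the state.
#' @export
#' @examples
#' p <- bph_parameters()
#' state_utility(p, "surg_later", 1, disutility = 0)  # 0.8 * 0.9424
state_utility <- function(params, state, cycle, disutility = NULL) {
  stopifnot(state %in% bph_states(), cycle >= 1)
  if (state == "death") return(0)
  age <- if (isTRUE(params$settings$freeze_age)) params$settings$start_age
         else params$settings$start_age + cycle - 1
  ab <- age_baseline_utility(params, age)
  u <- switch(state,
    drug_y1 = , drug_later = {
      traj <- params$utility$trajectory
      if (is.null(traj$slope)) traj <- fit_ipss_regression(traj)
      ab * ipss_to_utility(params,
                           ipss_at(traj, cycle,
                                   use_observed = params$utility$use_observed_years))
    },
    surg_y1 = , surg_later = {
      if (is.null(disutility)) disutility <- complication_disutility(params)
      if (disutility < 0) {
        stop("range error: complication disutility must be >= 0", call. = FALSE)
      }
      ab * ipss_to_utility(params, post_surgery_ipss(params)) - disutility
    },
    pc_y1 = , pc_later = params$utility$pc_utility
  )
  min(max(u, 0), 1)
}

#' Per-cycle utility matrix for the model horizon
#'
#' Convenience wrapper evaluating [state_utility()] for every state and
#' cycle; used by both the cohort accumulator and the microsimulation so the
#' two share a single utility surface.
#'
#' @param params A `bph_parameters` object.
#' @return `horizon x 7` matrix of annual utilities, columns in
#'   [bph_states()] order.
#' @export
utility_surface <- function(params) {
  # fit the trajectory once rather than per (state, cycle) call
  if (is.null(params$utility$trajectory$slope)) {
    params$utility$trajectory <- fit_ipss_regression(params$utility$trajectory)
  }
  horizon <- params$settings$horizon
  states <- bph_states()
  m <- matrix(0, nrow = horizon, ncol = length(states),
              dimnames = list(NULL, states))
  for (t in seq_len(horizon)) {
    for (s in states) m[t, s] <- state_utility(params, s, t)
  }
  m
}
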