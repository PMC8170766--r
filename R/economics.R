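#' Incremental cost and effectiveness between two arms
#'
#' Differences are signed "alternative minus reference". The full pipeline
#' ([compare_arms()]) uses surgery as reference and pharmacotherapy as the
#' alternative under evaluation, so the base case lands in the south-west
#' quadrant (cheaper, less effective). Refuses to compare outcomes computed
#' under different run settings.
#'
#' @param ref_totals,alt_totals `bph_outcomes` objects (or lists with
#'   `total_cost` and `total_qaly`).
#' @return Named numeric: `inc_cost`, `inc_qaly`.
#' @export
incremental <- function(ref_totals, alt_totals) {
  if (!is.null(ref_totals$settings) && !is.null(alt_totals$settings) &&
      !identical(ref_totals$settings, alt_totals$settings)) {
    stop("comparison error: arm totals were computed under different settings",
         call. = FALSE)
  }
  c(inc_cost = alt_totals$total_cost - ref_totals$total_cost,
    inc_qaly = alt_totals$total_qaly - ref_totals$total_qaly)
}

#' Incremental cost-effectiveness ratio and CE-plane quadrant
#'
#' The quadrant is read off the signs of the incrementals (alternative minus
#' reference), with zero treated as non-negative: NE costlier/more
#' effective, SE cheaper/more effective (dominant), SW cheaper/less
#' effective, NW costlier/less effective (dominated). When the QALY
#' difference is zero the ratio is undefined and a dominance marker is
#' returned instead (`"cheaper_equal"`, `"costlier_equal"`, or
#' `"equivalent"` when both increments vanish).
#'
#' @param inc_cost Incremental cost (USD).
#' @param inc_qaly Incremental effectiveness (QALY).
#' @return List with `value` (USD/QALY, `NA` when undefined), `quadrant`,
#'   and `marker` (`NULL` for an ordinary ratio).
#' @export
#' @examples
#' icer(-136301.1, -18)$value  # 7572.28...
icer <- function(inc_cost, inc_qaly) {
  quadrant <- paste0(if (inc_cost >= 0) "N" else "S",
                     if (inc_qaly >= 0) "E" else "W")
  if (inc_qaly == 0) {
    marker <- if (inc_cost == 0) "equivalent"
              else if (inc_cost < 0) "cheaper_equal" else "costlier_equal"
    return(list(value = NA_real_, quadrant = quadrant, marker = marker))
  }
  list(value = inc_cost / inc_qaly, quadrant = quadrant, marker = NULL)
}

#' Willingness-to-pay verdict for an ICER
#'
#' Applies the cost-effectiveness decision rule per quadrant. NE (the
#' alternative is costlier and more effective): the alternative is preferred
#' when its ICER does not exceed the threshold. SW (cheaper and less
#' effective): the alternative is preferred when the savings per QALY
#' forgone — the (positive) ICER — are at least the threshold; otherwise
#' the extra effectiveness of the reference is worth buying. SE: the
#' alternative dominates; NW: it is dominated. Dominance markers resolve to
#' the cheaper arm (`"cheaper_equal"`) or the other arm
#' (`"costlier_equal"`); `"equivalent"` returns `"equivalent"`.
#'
#' @param icer_result List from [icer()].
#' @param wtp Willingness-to-pay threshold, USD/QALY, `> 0`.
#' @return `"alternative"`, `"reference"`, or `"equivalent"`.
#' @export
decide <- function(icer_result, wtp) {
  stopifnot(wtp > 0)
  if (!is.null(icer_result$marker)) {
    return(switch(icer_result$marker,
      equivalent = "equivalent",
      cheaper_equal = "alternative",
      costlier_equal = "reference"
    ))
  }
  switch(icer_result$quadrant,
    SE = "alternative",                                     # dominant
    NW = "reference",                                       # dominated
    NE = if (icer_result$value <= wtp) "alternative" else "reference",
    SW = if (icer_result$value >= wtp) "alternative" else "reference"
  )
}

#' Full two-arm cost-utility comparison
#'
#' Runs both strategy arms through the cohort engine, accumulates discounted
#' totals, and derives incrementals, ICER, CE-plane quadrant and the
#' willingness-to-pay verdict. The convention — reference = surgery,
#' alternative = pharmacotherapy — is recorded in the result.
#'
#' @param params A `bph_parameters` object.
#' @param keep_traces Keep the occupancy traces in the result (default
#'   `FALSE` to keep scenario batches light).
#' @return A `bph_comparison` object.
#' @export
#' @examples
#' cmp <- compare_arms(bph_parameters())
#' cmp$icer$value
compare_arms <- function(params, keep_traces = FALSE) {
  pharma <- run_arm(params, "pharmacotherapy")
  surg <- run_arm(params, "surgery")
  inc <- incremental(surg$outcomes, pharma$outcomes)
  ic <- icer(inc[["inc_cost"]], inc[["inc_qaly"]])
  verdict_side <- decide(ic, params$settings$wtp)
  verdict <- switch(verdict_side,
    alternative = "pharmacotherapy",
    reference = "surgery",
    "equivalent"
  )
  structure(
    list(
      arm_totals = data.frame(
        arm = c("pharmacotherapy", "surgery"),
        total_cost = c(pharma$outcomes$total_cost, surg$outcomes$total_cost),
        total_qaly = c(pharma$outcomes$total_qaly, surg$outcomes$total_qaly)
      ),
      reference = "surgery",
      alternative = "pharmacotherapy",
      inc_cost = unname(inc[["inc_cost"]]),
      inc_qaly = unname(inc[["inc_qaly"]]),
      icer = ic,
      quadrant = ic$quadrant,
      wtp = params$settings$wtp,
      verdict = verdict,
      traces = if (keep_traces) list(pharmacotherapy = pharma$trace,
                                     surgery = surg$trace)
    ),
    class = "bph_comparison"
  )
}

#' @export
print.bph_comparison <- function(x, ...) {
  cat("<bph_comparison> (alternative:", x$alternative, "vs reference:",
      paste0(x$reference, ")\n"))
  at <- x$arm_totals
  for (i in seq_len(nrow(at))) {
    cat(sprintf("  %-16s cost %12.2f USD   QALY %9.2f\n",
                at$arm[i], at$total_cost[i], at$total_qaly[i]))
  }
  cat(sprintf("  incremental: %.2f USD, %.2f QALY  [quadrant %s]\n",
              x$inc_cost, x$inc_qaly, x$quadrant))
  if (is.na(x$icer$value)) {
    cat("  ICER: undefined (", x$icer$marker, ")\n", sep = "")
  } else {
    cat(sprintf("  ICER: %.1f USD/QALY (WTP %.0f) -> %s preferred\n",
                x$icer$value, x$wtp, x$verdict))
  }
  invisible(x)
}

fmt_num <- function(x, paren_negatives = FALSE, digits = 2) {
  if (!paren_negatives) return(round(x, digits))
  out <- formatC(abs(x), format = "f", digits = digits, big.mark = ",")
  ifelse(x < 0, paste0("(", out, ")"), out)
}

#' Render arm and scenario report tables
#'
#' Produces a two-row per-arm summary (total cost, total QALY, incrementals
#' and ICER on the alternative's row) from the first result, and a
#' scenario table (one row per comparison, in input order) with incremental
#' cost, incremental QALY, ICER, quadrant and verdict. When `out_dir` is
#' given, writes `arms.csv`, `scenarios.csv` and `comparison.json`.
#'
#' @param results A single `bph_comparison` or a named list of them (the
#'   first is taken as the base case for the arm table).
#' @param out_dir Optional output directory (created if missing).
#' @param paren_negatives Format negative numbers in the CSVs as
#'   parenthesized magnitudes, e.g. `(136,301.06)`.
#' @return List with `arms` and `scenarios` data frames, invisibly when
#'   writing to disk.
#' @export
render_report <- function(results, out_dir = NULL, paren_negatives = FALSE) {
  if (inherits(results, "bph_comparison")) results <- list(base = results)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "bph_comparison")))
  if (is.null(names(results))) names(results) <- seq_along(results)

  base <- results[[1]]
  arms <- base$arm_totals
  arms$inc_cost <- c(base$inc_cost, NA)
  arms$inc_qaly <- c(base$inc_qaly, NA)
  arms$icer <- c(round(base$icer$value, 1), NA)

  scenarios <- data.frame(
    scenario = names(results),
    inc_cost = vapply(results, `[[`, numeric(1), "inc_cost"),
    inc_qaly = vapply(results, `[[`, numeric(1), "inc_qaly"),
    icer = vapply(results, function(r) round(r$icer$value, 1), numeric(1)),
    quadrant = vapply(results, `[[`, character(1), "quadrant"),
    verdict = vapply(results, `[[`, character(1), "verdict"),
    row.names = NULL
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    arms_out <- arms
    scen_out <- scenarios
    if (paren_negatives) {
      for (col in c("inc_cost", "inc_qaly", "icer")) {
        arms_out[[col]] <- fmt_num(arms_out[[col]], TRUE)
        scen_out[[col]] <- fmt_num(scen_out[[col]], TRUE)
      }
    }
    utils::write.csv(arms_out, file.path(out_dir, "arms.csv"),
                     row.names = FALSE)
    utils::write.csv(scen_out, file.path(out_dir, "scenarios.csv"),
                     row.names = FALSE)
    json <- lapply(results, function(r) {
      list(arm_totals = r$arm_totals, reference = r$reference,
           alternative = r$alternative, inc_cost = r$inc_cost,
           inc_qaly = r$inc_qaly, icer = r$icer$value,
           quadrant = r$quadrant, wtp = r$wtp, verdict = r$verdict)
    })
    jsonlite::write_json(json, file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(list(arms = arms, scenarios = scenarios)))
  }
  list(arms = arms, scenarios = scenarios)
}
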