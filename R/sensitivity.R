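#' Default one-way sensitivity ranges
#'
#' Builds a `low`/`high` range for every addressable parameter path, as base
#' value ± a relative fraction (default 20%), with probabilities, utilities
#' and discount rates capped to stay inside their valid intervals.
#'
#' @param params A `bph_parameters` object.
#' @param rel Relative half-width of the range (fraction of the base value).
#' @return Data frame with columns `parameter`, `base`, `low`, `high`.
#' @export
default_dsa_ranges <- function(params, rel = 0.2) {
  paths <- dsa_parameter_paths()
  base <- vapply(paths, get_param, numeric(1), params = params)
  low <- base * (1 - rel)
  high <- base * (1 + rel)
  bounded01 <- grepl("^prob\\.", paths) | paths == "util.pc_utility"
  high[bounded01] <- pmin(high[bounded01], 1)
  is_disc <- grepl("^settings\\.discount", paths)
  high[is_disc] <- pmin(high[is_disc], 1 - 1e-9)
  data.frame(parameter = paths, base = unname(base),
             low = unname(low), high = unname(high), row.names = NULL)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For each range, reruns the full two-arm comparison twice — once with the
#' parameter at its low bound and once at its high bound, everything else at
#' base — and records the resulting outcome. Entries are sorted by swing
#' (absolute difference between the two outcomes), descending, which is the
#' tornado-diagram ordering. Ranges that produce an invalid parameter set
#' are skipped with a warning.
#'
#' @param params Base `bph_parameters`.
#' @param ranges Data frame as from [default_dsa_ranges()]; `low <= base <=
#'   high` is required per row.
#' @param outcome `"icer"` (default) or `"nmb"` — incremental net monetary
#'   benefit of the alternative at the model's WTP, which keeps the ordering
#'   sign-stable if a range flips the CE-plane quadrant.
#' @return A `bph_tornado` data frame: `parameter`, `low`, `high`,
#'   `outcome_low`, `outcome_high`, `swing`, sorted by `swing` descending,
#'   with the base-case outcome in `attr(, "base_outcome")`.
#' @export
one_way_dsa <- function(params, ranges = default_dsa_ranges(params),
                        outcome = c("icer", "nmb")) {
  outcome <- match.arg(outcome)
  measure <- function(cmp) {
    if (outcome == "nmb") {
      cmp$wtp * cmp$inc_qaly - cmp$inc_cost
    } else {
      cmp$icer$value
    }
  }
  bad <- ranges$low > ranges$base | ranges$base > ranges$high
  if (any(bad)) {
    stop("validation error: need low <= base <= high for: ",
         paste(ranges$parameter[bad], collapse = ", "), call. = FALSE)
  }
  base_cmp <- compare_arms(params)
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    vals <- vapply(c(ranges$low[i], ranges$high[i]), function(v) {
      cmp <- tryCatch(
        compare_arms(set_param(params, ranges$parameter[i], v)),
        error = function(e) {
          warning("skipping ", ranges$parameter[i], " at ", format(v), ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        }
      )
      if (is.null(cmp)) NA_real_ else measure(cmp)
    }, numeric(1))
    if (anyNA(vals)) return(NULL)
    data.frame(parameter = ranges$parameter[i],
               low = ranges$low[i], high = ranges$high[i],
               outcome_low = vals[1], outcome_high = vals[2],
               swing = abs(vals[2] - vals[1]))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(-out$swing), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, base_outcome = measure(base_cmp), outcome = outcome,
            class = c("bph_tornado", class(out)))
}

#' @export
print.bph_tornado <- function(x, ...) {
  cat("<bph_tornado> outcome:", attr(x, "outcome"),
      " base:", format(attr(x, "base_outcome")), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Run the scenario catalogue
#'
#' Applies each scenario's overrides to the base parameter set and reruns
#' the full two-arm comparison. The base case is part of the catalogue.
#'
#' @param params Base `bph_parameters`.
#' @param catalog List of `bph_scenario` objects, default
#'   [scenario_catalog()].
#' @return List with `results` (named `bph_comparison` list in catalogue
#'   order) and `summary` (the scenario table from [render_report()]).
#' @export
#' @examples
#' \donttest{
#' sc <- run_scenarios(bph_parameters())
#' sc$summary
#' }
run_scenarios <- function(params, catalog = scenario_catalog()) {
  results <- lapply(catalog, function(sc) compare_arms(apply_scenario(params, sc)))
  names(results) <- vapply(catalog, `[[`, character(1), "name")
  list(results = results, summary = render_report(results)$scenarios)
}
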