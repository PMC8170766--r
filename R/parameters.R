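#' Health states of the cohort model
#'
#' The model distinguishes the first year in each treatment pathway from all
#' later years, because costs, utilities and transition probabilities differ
#' between the two phases. The seven states, in canonical order, are:
#' first year of drug therapy, later drug years, first year after surgery,
#' later post-surgical years, first year of prostate cancer, later cancer
#' years, and death (absorbing).
#'
#' @return Character vector of the seven state labels in canonical order.
#' @export
#' @examples
#' bph_states()
bph_states <- function() {
  c("drug_y1", "drug_later", "surg_y1", "surg_later",
    "pc_y1", "pc_later", "death")
}

#' Strategy arms and their entry states
#'
#' The decision tree splits the cohort into two strategies before the Markov
#' phase: pharmacotherapy (dutasteride), entering the first drug year, and
#' surgery (a TURP/OP mix), entering the first surgical year.
#'
#' @return Named character vector mapping arm name to entry state.
#' @export
bph_arms <- function() {
  c(pharmacotherapy = "drug_y1", surgery = "surg_y1")
}

states_y1 <- function() c("drug_y1", "surg_y1", "pc_y1")

# ---- defaults -------------------------------------------------------------

default_settings <- function() {
  list(
    cohort_size      = 1000,
    horizon          = 10L,
    cycle_length     = 1,
    start_age        = 70,
    discount_cost    = 0.07,
    discount_utility = 0.03,
    wtp              = 3701,
    # end-of-cycle convention: the first cycle is discounted at t = 1
    discount_from    = "year_1",
    half_cycle_correction = FALSE,
    # noncompliant patients cross over at the end of cycle 1 (accrue drug
    # cost/utility in cycle 1, surgical values from cycle 2 on)
    crossover_timing = "end_of_cycle",
    freeze_age       = FALSE
  )
}

default_transitions <- function() {
  list(
    p_noncompliance_y1      = 0.3,
    p_drug_to_surgery_later = 0.005,
    p_drug_to_pc            = 0.000836,
    p_surgery_to_pc         = 0.0011,
    pc_excess_death         = 0.18,
    surgery_death_addon_turp = 0.001,
    surgery_death_addon_op   = 0.002,
    chemoprevention_rr      = 0.25,
    chemoprevention_cycles  = c(1L, 2L),
    chemoprevention_enabled = TRUE,
    # the perioperative death add-on applies to the first surgical year only
    addon_first_year_only   = TRUE
  )
}

default_surgery_mix <- function() {
  list(share_turp = 0.8, share_op = 0.2)
}

default_costs <- function() {
  list(
    drug_y1    = 146.36,
    drug_later = 146.36,
    surg_y1    = 840.96,
    surg_later = 9,
    pc_y1      = 6141,
    pc_later   = 2303,
    death      = 0,
    infection_management = 0.71,
    tariff_sector = "blended"
  )
}

default_age_baseline <- function() {
  data.frame(
    age_low  = c(40, 50, 60, 70),
    age_high = c(50, 60, 70, 80),
    utility  = c(1, 0.94, 0.88, 0.8)
  )
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "bphcea")
  if (identical(path, "")) {
    # during development the package may not be installed yet
    path <- file.path("inst", "extdata", file)
  }
  path
}

read_fixture <- function(file) {
  utils::read.csv(extdata_path(file), comment.char = "#",
                  stringsAsFactors = FALSE)
}

default_utility_model <- function() {
  list(
    ipss_utility         = read_fixture("ipss_utility.csv"),
    age_baseline         = default_age_baseline(),
    pc_utility           = 0.62,
    baseline_ipss        = 16.7,
    surgical_improvement = 8.5,
    complication_scale   = 1,
    complications        = read_fixture("complications_synthetic.csv"),
    # non-integer IPSS scores are interpolated in the utility table by
    # default; "round" reproduces a nearest-integer lookup
    ipss_lookup          = "interpolate",
    # years 2-4 use the fitted regression line, not the observed trial values
    use_observed_years   = FALSE,
    trajectory           = bph_ipss_trajectory()
  )
}

default_sector_costs <- function() {
  read_fixture("tariff_synthetic.csv")
}

# ---- constructor ----------------------------------------------------------

#' Assemble a full model parameter set
#'
#' Bundles settings, transition probabilities, the surgical mix, per-state
#' costs, the life table, and the utility model into a validated parameter
#' object. All arguments default to the base-case parameterization: a cohort
#' of 1000 seventy-year-old men followed for ten annual cycles, costs
#' discounted at 7%/yr and utilities at 3%/yr, a willingness-to-pay threshold
#' of 3,701 USD/QALY, and an 80/20 TURP/OP surgical mix.
#'
#' @param settings List of run settings (cohort size, horizon, start age,
#'   discount rates, willingness-to-pay, accrual conventions).
#' @param transitions List of transition-probability parameters.
#' @param surgery_mix List with `share_turp` and `share_op` (must sum to 1).
#' @param costs List of per-state annual costs in USD.
#' @param life_table Life table as returned by [make_life_table()].
#' @param utility Utility model: IPSS-utility table, age-band baseline
#'   utilities, cancer-state utility, surgical IPSS improvement, and the
#'   complication profiles.
#' @param sector_costs Data frame of sector-specific surgical tariffs
#'   (columns `sector`, `surg_y1`, `surg_later`).
#' @return An object of class `bph_parameters`.
#' @export
#' @examples
#' p <- bph_parameters()
#' p$settings$wtp
bph_parameters <- function(settings = list(), transitions = list(),
                           surgery_mix = list(), costs = list(),
                           life_table = make_life_table(),
                           utility = list(),
                           sector_costs = default_sector_costs()) {
  params <- structure(
    list(
      settings     = utils::modifyList(default_settings(), settings),
      transitions  = utils::modifyList(default_transitions(), transitions),
      surgery_mix  = utils::modifyList(default_surgery_mix(), surgery_mix),
      costs        = utils::modifyList(default_costs(), costs),
      life_table   = life_table,
      utility      = utils::modifyList(default_utility_model(), utility),
      sector_costs = sector_costs
    ),
    class = "bph_parameters"
  )
  validate_parameters(params)
}

#' @export
print.bph_parameters <- function(x, ...) {
  s <- x$settings
  cat("<bph_parameters>\n")
  cat(sprintf("  cohort %d, start age %g, horizon %d yr cycles\n",
              s$cohort_size, s$start_age, s$horizon))
  cat(sprintf("  discounting: cost %.0f%%/yr, utility %.0f%%/yr; WTP %g USD/QALY\n",
              100 * s$discount_cost, 100 * s$discount_utility, s$wtp))
  cat(sprintf("  surgery mix: TURP %.0f%% / OP %.0f%%; tariff sector: %s\n",
              100 * x$surgery_mix$share_turp, 100 * x$surgery_mix$share_op,
              x$costs$tariff_sector))
  cat(sprintf("  chemoprevention: %s\n",
              if (x$transitions$chemoprevention_enabled) "on (cycles 1-2)" else "off"))
  invisible(x)
}

# ---- validation -----------------------------------------------------------

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("range error: `", name, "` must be a probability in [0, 1], got ",
         paste(format(x), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop("range error: `", name, "` must be non-negative", call. = FALSE)
  }
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter object: probabilities
#' in \[0, 1\], non-negative costs, discount rates in \[0, 1), surgical mix
#' shares summing to one, a strictly decreasing IPSS-utility table, life
#' table coverage of the ages the cohort will reach, and recognised values
#' for the categorical settings. Row-level feasibility (outgoing
#' probabilities of a state exceeding one) is checked at matrix construction,
#' where the offending row can be named.
#'
#' @param params A `bph_parameters` object (or a list with the same shape).
#' @return The validated object, invisibly classed as `bph_parameters`.
#' @export
validate_parameters <- function(params) {
  s <- params$settings
  if (!is.numeric(s$cohort_size) || s$cohort_size <= 0) {
    stop("range error: `settings.cohort_size` must be > 0", call. = FALSE)
  }
  if (!is.numeric(s$horizon) || s$horizon < 1 || s$horizon != round(s$horizon)) {
    stop("range error: `settings.horizon` must be an integer >= 1", call. = FALSE)
  }
  for (f in c("discount_cost", "discount_utility")) {
    if (!is.numeric(s[[f]]) || s[[f]] < 0 || s[[f]] >= 1) {
      stop("range error: `settings.", f, "` must be in [0, 1)", call. = FALSE)
    }
  }
  check_nonneg(s$wtp, "settings.wtp")
  if (!s$discount_from %in% c("year_0", "year_1")) {
    stop("validation error: `settings.discount_from` must be \"year_0\" or \"year_1\"",
         call. = FALSE)
  }
  if (!s$crossover_timing %in% c("end_of_cycle", "immediate")) {
    stop("validation error: `settings.crossover_timing` must be \"end_of_cycle\" or \"immediate\"",
         call. = FALSE)
  }

  tr <- params$transitions
  for (f in c("p_noncompliance_y1", "p_drug_to_surgery_later", "p_drug_to_pc",
              "p_surgery_to_pc", "pc_excess_death", "surgery_death_addon_turp",
              "surgery_death_addon_op", "chemoprevention_rr")) {
    check_prob(tr[[f]], paste0("transitions.", f))
  }

  mix <- params$surgery_mix
  check_prob(mix$share_turp, "surgery_mix.share_turp")
  check_prob(mix$share_op, "surgery_mix.share_op")
  if (abs(mix$share_turp + mix$share_op - 1) > 1e-9) {
    stop("validation error: surgery mix shares must sum to 1", call. = FALSE)
  }

  for (f in c("drug_y1", "drug_later", "surg_y1", "surg_later", "pc_y1",
              "pc_later", "death", "infection_management")) {
    check_nonneg(params$costs[[f]], paste0("costs.", f))
  }
  if (!params$costs$tariff_sector %in% params$sector_costs$sector) {
    stop("validation error: `costs.tariff_sector` must be one of: ",
         paste(params$sector_costs$sector, collapse = ", "), call. = FALSE)
  }

  validate_life_table(params$life_table)
  lt <- params$life_table
  ages <- s$start_age + seq_len(s$horizon) - 1
  if (any(ages < min(lt$age_low)) || any(ages >= max(lt$age_high))) {
    stop("coverage error: life table must cover ages ", min(ages), "-",
         max(ages), call. = FALSE)
  }

  u <- params$utility
  tab <- u$ipss_utility
  if (!identical(tab$ipss, 1:35) && !identical(as.numeric(tab$ipss), as.numeric(1:35))) {
    stop("validation error: IPSS-utility table must cover integer scores 1..35",
         call. = FALSE)
  }
  if (any(diff(tab$utility) >= 0)) {
    stop("validation error: IPSS-utility table must be strictly decreasing",
         call. = FALSE)
  }
  check_prob(tab$utility, "utility.ipss_utility$utility")
  check_prob(u$pc_utility, "utility.pc_utility")
  check_prob(u$age_baseline$utility, "utility.age_baseline$utility")
  check_nonneg(u$surgical_improvement, "utility.surgical_improvement")
  check_nonneg(u$complication_scale, "utility.complication_scale")
  check_prob(u$complications$annual_probability,
             "utility.complications$annual_probability")
  check_nonneg(u$complications$utility_decrement,
               "utility.complications$utility_decrement")

  invisible(structure(params, class = "bph_parameters"))
}

# ---- config document I/O --------------------------------------------------

config_schema_version <- 1L

allowed_config_keys <- function() {
  list(
    top         = c("schema_version", "settings", "transitions", "surgery_mix",
                    "costs", "life_table", "utility"),
    settings    = names(default_settings()),
    transitions = names(default_transitions()),
    surgery_mix = names(default_surgery_mix()),
    costs       = names(default_costs()),
    life_table  = c("preset", "bands"),
    utility     = c("pc_utility", "baseline_ipss", "surgical_improvement",
                    "complication_scale", "ipss_lookup", "use_observed_years")
  )
}

reject_unknown <- function(keys, allowed, where) {
  extra <- setdiff(keys, allowed)
  if (length(extra)) {
    stop("validation error: unknown key", if (length(extra) > 1) "s",
         " in ", where, ": ", paste(extra, collapse = ", "), call. = FALSE)
  }
}

#' Load a model parameter set from a configuration document
#'
#' Reads a YAML or JSON configuration (or an equivalent R list) describing
#' overrides to the base-case parameterization, applies it over the defaults,
#' and validates the result. Unknown keys are rejected so typos cannot pass
#' silently; an empty configuration yields the base case unchanged. The
#' accepted structure is documented by the JSON schema shipped in
#' `inst/schema/model-config.schema.json`.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, a list of overrides,
#'   or `NULL` for the base case.
#' @return A validated `bph_parameters` object.
#' @export
#' @examples
#' load_model()              # base case
#' load_model(list(settings = list(discount_cost = 0)))
load_model <- function(config = NULL) {
  if (is.null(config)) config <- list()
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("validation error: config file not found: ", config, call. = FALSE)
    }
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::fromJSON(config, simplifyVector = TRUE),
      stop("validation error: unsupported config format: .", ext, call. = FALSE)
    )
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) {
    stop("validation error: config must be a list or a file path", call. = FALSE)
  }

  allowed <- allowed_config_keys()
  reject_unknown(names(config), allowed$top, "config")
  if (!is.null(config$schema_version) &&
      config$schema_version != config_schema_version) {
    stop("validation error: unsupported schema_version ",
         config$schema_version, " (expected ", config_schema_version, ")",
         call. = FALSE)
  }
  for (group in c("settings", "transitions", "surgery_mix", "costs", "utility")) {
    if (!is.null(config[[group]])) {
      reject_unknown(names(config[[group]]), allowed[[group]], group)
    }
  }

  life_table <- make_life_table()
  if (!is.null(config$life_table)) {
    lt_cfg <- config$life_table
    reject_unknown(names(lt_cfg), allowed$life_table, "life_table")
    if (!is.null(lt_cfg$bands)) {
      bands <- as.data.frame(lt_cfg$bands)
      life_table <- as_life_table(bands)
    } else if (!is.null(lt_cfg$preset)) {
      life_table <- make_life_table(lt_cfg$preset)
    }
  }

  bph_parameters(
    settings    = config$settings %||% list(),
    transitions = config$transitions %||% list(),
    surgery_mix = config$surgery_mix %||% list(),
    costs       = config$costs %||% list(),
    utility     = config$utility %||% list(),
    life_table  = life_table
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a parameter set to a configuration list
#'
#' Inverse of [load_model()] for the configurable fields: the returned list,
#' fed back through `load_model()`, reproduces the parameter set exactly.
#'
#' @param params A `bph_parameters` object.
#' @return A plain list with a `schema_version` field.
#' @export
as_model_config <- function(params) {
  u <- params$utility
  list(
    schema_version = config_schema_version,
    settings       = params$settings,
    transitions    = params$transitions,
    surgery_mix    = params$surgery_mix,
    costs          = params$costs,
    life_table     = list(bands = as.data.frame(unclass(params$life_table))),
    utility        = list(
      pc_utility           = u$pc_utility,
      baseline_ipss        = u$baseline_ipss,
      surgical_improvement = u$surgical_improvement,
      complication_scale   = u$complication_scale,
      ipss_lookup          = u$ipss_lookup,
      use_observed_years   = u$use_observed_years
    )
  )
}

#' Write a parameter set to a YAML or JSON configuration file
#'
#' @param params A `bph_parameters` object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, path) {
  cfg <- as_model_config(params)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(cfg, path),
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"),
    stop("validation error: unsupported config format: .", ext, call. = FALSE)
  )
  invisible(path)
}

# ---- scenario catalogue ---------------------------------------------------

#' The named scenario catalogue
#'
#' Returns the nine configurations analysed by the model: the base case plus
#' eight scenarios — surgical costs at the public-only or private-only
#' tariff, the drug's chemoprevention effect switched off, an OP-only or
#' TURP-only surgical mix, and three younger age bands (40–50, 50–60, 60–70)
#' with their band baseline utilities (1, 0.94, 0.88).
#'
#' @return A list of `bph_scenario` objects of length 9, base case first.
#' @export
#' @examples
#' names(scenario_catalog())
scenario_catalog <- function() {
  sc <- function(name, chemoprevention_enabled = NULL,
                 surgery_mix_override = NULL, tariff_sector_override = NULL,
                 age_band = NULL) {
    structure(
      list(name = name,
           chemoprevention_enabled = chemoprevention_enabled,
           surgery_mix_override = surgery_mix_override,
           tariff_sector_override = tariff_sector_override,
           age_band = age_band),
      class = "bph_scenario"
    )
  }
  out <- list(
    sc("base"),
    sc("public_tariff",  tariff_sector_override = "public"),
    sc("private_tariff", tariff_sector_override = "private"),
    sc("no_chemoprevention", chemoprevention_enabled = FALSE),
    sc("op_only",   surgery_mix_override = list(share_turp = 0, share_op = 1)),
    sc("turp_only", surgery_mix_override = list(share_turp = 1, share_op = 0)),
    sc("age_40_50", age_band = list(start_age = 40, baseline_utility = 1)),
    sc("age_50_60", age_band = list(start_age = 50, baseline_utility = 0.94)),
    sc("age_60_70", age_band = list(start_age = 60, baseline_utility = 0.88))
  )
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Apply a scenario's overrides to a parameter set
#'
#' @param params Base `bph_parameters`.
#' @param scenario A `bph_scenario` from [scenario_catalog()].
#' @return A new validated `bph_parameters` with the overrides applied.
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(inherits(scenario, "bph_scenario"))
  if (!is.null(scenario$chemoprevention_enabled)) {
    params$transitions$chemoprevention_enabled <- scenario$chemoprevention_enabled
  }
  if (!is.null(scenario$surgery_mix_override)) {
    params$surgery_mix <- utils::modifyList(params$surgery_mix,
                                            scenario$surgery_mix_override)
  }
  if (!is.null(scenario$tariff_sector_override)) {
    params$costs$tariff_sector <- scenario$tariff_sector_override
  }
  if (!is.null(scenario$age_band)) {
    params$settings$start_age <- scenario$age_band$start_age
    # the band baseline utility is read from the age-baseline map at run
    # time; check the map agrees with the scenario's stated value
    got <- age_baseline_utility(params, scenario$age_band$start_age)
    if (abs(got - scenario$age_band$baseline_utility) > 1e-9) {
      stop("validation error: age-baseline map gives ", got,
           " for start age ", scenario$age_band$start_age,
           " but scenario `", scenario$name, "` states ",
           scenario$age_band$baseline_utility, call. = FALSE)
    }
  }
  validate_parameters(params)
}

# ---- parameter paths (for the DSA and programmatic overrides) -------------

#' Parameter paths addressable by the sensitivity analysis
#'
#' @return Character vector of dotted parameter paths usable with
#'   [get_param()] and [set_param()]. `cost.drug` addresses the annual drug
#'   acquisition cost (first and later years jointly);
#'   `util.complication_scale` scales every complication utility decrement.
#' @export
dsa_parameter_paths <- function() {
  c("cost.drug", "cost.surg_y1", "cost.surg_later", "cost.pc_y1",
    "cost.pc_later",
    "prob.noncompliance_y1", "prob.drug_to_surgery_later", "prob.drug_to_pc",
    "prob.surgery_to_pc", "prob.pc_excess_death",
    "util.pc_utility", "util.surgical_improvement", "util.complication_scale",
    "settings.discount_cost", "settings.discount_utility")
}

#' @rdname dsa_parameter_paths
#' @param params A `bph_parameters` object.
#' @param path One of the paths from `dsa_parameter_paths()`.
#' @export
get_param <- function(params, path) {
  switch(path,
    "cost.drug"        = params$costs$drug_y1,
    "cost.surg_y1"     = params$costs$surg_y1,
    "cost.surg_later"  = params$costs$surg_later,
    "cost.pc_y1"       = params$costs$pc_y1,
    "cost.pc_later"    = params$costs$pc_later,
    "prob.noncompliance_y1"      = params$transitions$p_noncompliance_y1,
    "prob.drug_to_surgery_later" = params$transitions$p_drug_to_surgery_later,
    "prob.drug_to_pc"            = params$transitions$p_drug_to_pc,
    "prob.surgery_to_pc"         = params$transitions$p_surgery_to_pc,
    "prob.pc_excess_death"       = params$transitions$pc_excess_death,
    "util.pc_utility"            = params$utility$pc_utility,
    "util.surgical_improvement"  = params$utility$surgical_improvement,
    "util.complication_scale"    = params$utility$complication_scale,
    "settings.discount_cost"     = params$settings$discount_cost,
    "settings.discount_utility"  = params$settings$discount_utility,
    stop("validation error: unknown parameter path: ", path, call. = FALSE)
  )
}

#' @rdname dsa_parameter_paths
#' @param value New value for the parameter.
#' @export
set_param <- function(params, path, value) {
  switch(path,
    "cost.drug" = {
      params$costs$drug_y1 <- value
      params$costs$drug_later <- value
    },
    "cost.surg_y1"    = params$costs$surg_y1 <- value,
    "cost.surg_later" = params$costs$surg_later <- value,
    "cost.pc_y1"      = params$costs$pc_y1 <- value,
    "cost.pc_later"   = params$costs$pc_later <- value,
    "prob.noncompliance_y1"      = params$transitions$p_noncompliance_y1 <- value,
    "prob.drug_to_surgery_later" = params$transitions$p_drug_to_surgery_later <- value,
    "prob.drug_to_pc"            = params$transitions$p_drug_to_pc <- value,
    "prob.surgery_to_pc"         = params$transitions$p_surgery_to_pc <- value,
    "prob.pc_excess_death"       = params$transitions$pc_excess_death <- value,
    "util.pc_utility"            = params$utility$pc_utility <- value,
    "util.surgical_improvement"  = params$utility$surgical_improvement <- value,
    "util.complication_scale"    = params$utility$complication_scale <- value,
    "settings.discount_cost"     = params$settings$discount_cost <- value,
    "settings.discount_utility"  = params$settings$discount_utility <- value,
    stop("validation error: unknown parameter path: ", path, call. = FALSE)
  )
  validate_parameters(params)
}

# ---- derived helpers shared across modules --------------------------------

#' Age-band baseline utility
#'
#' Looks up the baseline (age-related) utility for a given age from the
#' utility model's age-band map (40–50: 1, 50–60: 0.94, 60–70: 0.88,
#' 70–80: 0.8 by default). Bands are half-open `[low, high)`.
#'
#' @param params A `bph_parameters` object.
#' @param age Age in years.
#' @return Baseline utility in \[0, 1\].
#' @export
age_baseline_utility <- function(params, age) {
  ab <- params$utility$age_baseline
  hit <- which(age >= ab$age_low & age < ab$age_high)
  if (length(hit) != 1) {
    stop("coverage error: age ", age, " not covered by the age-baseline map",
         call. = FALSE)
  }
  ab$utility[hit]
}

#' Per-state annual costs under the active tariff sector
#'
#' Returns the cost vector actually used by the accumulator: the per-state
#' costs from the cost set, with the surgical-pathway entries replaced by the
#' active sector's tariff when a non-blended sector is selected.
#'
#' @param params A `bph_parameters` object.
#' @return Named numeric vector over [bph_states()], USD per cycle.
#' @export
state_costs <- function(params) {
  costs <- params$costs
  surg_y1 <- costs$surg_y1
  surg_later <- costs$surg_later
  if (!identical(costs$tariff_sector, "blended")) {
    row <- params$sector_costs[params$sector_costs$sector == costs$tariff_sector, ]
    surg_y1 <- row$surg_y1
    surg_later <- row$surg_later
  }
  c(drug_y1 = costs$drug_y1, drug_later = costs$drug_later,
    surg_y1 = surg_y1, surg_later = surg_later,
    pc_y1 = costs$pc_y1, pc_later = costs$pc_later, death = costs$death)
}

#' Blended perioperative death add-on for the surgical mix
#'
#' The excess first-year death probability after surgery is the mix-weighted
#' mean of the per-type risks (TURP 0.001, OP 0.002 by default); at the
#' default 80/20 mix this is 0.0012.
#'
#' @param params A `bph_parameters` object.
#' @return Additive probability.
#' @export
surgery_death_addon <- function(params) {
  params$surgery_mix$share_turp * params$transitions$surgery_death_addon_turp +
    params$surgery_mix$share_op * params$transitions$surgery_death_addon_op
}
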