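---
title: "A Markov cohort cost-utility model for moderate BPH: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for moderate BPH: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bphcea)
```

## The decision problem

Moderate benign prostatic hyperplasia (BPH, International Prostate Symptom
Score 7–19) can be managed either with long-term 5-alpha-reductase-inhibitor
pharmacotherapy (dutasteride, 0.5 mg once daily) or with immediate surgery —
in the setting modelled here a mix of transurethral resection of the
prostate (TURP, 80%) and open prostatectomy (OP, 20%). `bphcea` implements a
cost-utility comparison of these two strategies from a health-provider
perspective: a decision tree splits a cohort of 1000 men (70 years old in
the base case) into the two arms, and each arm is then propagated through a
seven-state Markov model with annual cycles over a ten-year horizon.

The seven states separate the first year in each pathway from all later
years, because first-year costs, utilities and risks differ from maintenance
years: `drug_y1`, `drug_later`, `surg_y1`, `surg_later`, `pc_y1`,
`pc_later` (prostate cancer), and absorbing `death`. First-year states are
transient: they are occupied for exactly one cycle by any entering cohort
fraction.

Transitions (per year) are: noncompliance with medication moves 30% of
first-year drug patients into surgery, and 0.5% of later-year drug patients;
drug patients progress to prostate cancer at 0.000836/yr (reduced by 25%
during treatment years 1–2, the chemoprevention effect seen in long-term
dutasteride trials) and post-surgical patients at 0.0011/yr; everyone faces
age-specific background mortality, with a perioperative add-on in the first
surgical year (TURP +0.001, OP +0.002, blended +0.0012 at the 80/20 mix)
and an excess +0.18/yr in the cancer states. The probability of remaining
in a state is the residual after subtracting the row's outgoing
probabilities from one; a parameter set whose outgoing probabilities exceed
one is rejected with the offending row named. Constant event rates are
converted to cycle probabilities with `p = 1 - exp(-rt)`
(`rate_to_probability()`).

## Effectiveness

Symptom relief is measured on the IPSS and converted to utility weights.

* **Drug arm.** Observed mean IPSS under dutasteride is 16.7, 12.3, 11.3,
  10.6 at years 1–4. The first-year value reflects the pre-response
  baseline and is excluded; an ordinary least-squares line through the
  remaining three points (slope −0.85 IPSS/yr, intercept 13.95) extrapolates
  the response over the horizon, clamped to the score range [1, 35]. Year 1
  uses the observed 16.7. A flag (`use_observed_years`) substitutes the
  observed trial values in years 2–4; the default uses the fitted line
  throughout so the trajectory is one consistent model.
* **Surgical arm.** Surgery improves the baseline score by a fixed 8.5
  units (16.7 → 8.2), identical for TURP and OP.
* **IPSS → utility.** A tabulated map assigns a utility weight to each
  integer score 1–35 (shipped as `inst/extdata/ipss_utility.csv`, strictly
  decreasing). Non-integer scores are linearly interpolated by default —
  the continuous choice, which keeps sensitivity analyses smooth — with a
  nearest-integer lookup available (`ipss_lookup = "round"`).
* **Composition.** A state's annual utility multiplies the age-band
  baseline utility (40–50: 1, 50–60: 0.94, 60–70: 0.88, 70–80: 0.8) by the
  IPSS-derived weight; surgical states additionally subtract the expected
  complication disutility; cancer states use 0.62 directly (overriding, not
  multiplying, the IPSS pathway); death is 0. Results are clamped to
  [0, 1].

Costs per state-year (USD): drug therapy 146.36 (0.4/day acquisition cost),
first surgical year 840.96 (procedure plus complication management), later
surgical years 9 (ongoing complication management, including the
0.71-per-episode moderate-infection protocol), first cancer year 6141,
later cancer years 2303, death 0. Costs are discounted at 7%/yr and
utilities at 3%/yr.

## Accrual and discounting conventions

Transitions are booked at cycle end: occupancy *during* cycle `t` is the
state mix at its start, so a patient crossing over to surgery in cycle 1
accrues drug cost and utility in cycle 1 and first-year surgical values in
cycle 2. The alternative — booking the noncompliant flow at surgical values
already within the crossover cycle — is available
(`crossover_timing = "immediate"`). Cycle `t` is discounted by
`(1+d)^-t` (end-of-cycle convention, first cycle at `t = 1`);
`discount_from = "year_0"` leaves the first cycle undiscounted. No
half-cycle correction is applied by default; `half_cycle_correction = TRUE`
averages start- and end-of-cycle occupancy. Ageing advances the life-table
band lookup one year per cycle (`freeze_age = TRUE` reproduces the simpler
frozen-age reading). The surgical transition matrix is identical for the
two arms — they differ only in entry state — so
`build_transition_matrix()` takes no arm argument.

## Decision rules

With surgery as reference and pharmacotherapy as the alternative, the
incremental cost-effectiveness ratio is `ICER = ΔC/ΔE`. The
cost-effectiveness-plane quadrant is read from the signs of `(ΔC, ΔE)`
with zero treated as non-negative: SE (cheaper, more effective) dominates,
NW is dominated, NE prefers the alternative when `ICER ≤ WTP`, and in SW —
the base-case quadrant, where pharmacotherapy is cheaper but less effective
— the alternative is preferred when the savings per QALY forgone (the
positive ICER) are at least the willingness-to-pay threshold, 3,701
USD/QALY here. When `ΔE = 0` the ratio is undefined and a dominance marker
is returned instead.

## Sensitivity and scenario analysis

`one_way_dsa()` varies one parameter at a time between bounds (default
±20% of base, capped so probabilities, utilities and discount rates stay in
range), reruns the full comparison at each bound, and sorts parameters by
the absolute swing of the ICER — the tornado ordering. Because ICER ratios
can be unstable when a bound flips the quadrant, incremental net monetary
benefit (`outcome = "nmb"`) is available as a sign-stable alternative. The
undisplayed ranges are declared in the output.

`scenario_catalog()` holds the nine analysed configurations: base case,
public-only and private-only surgical tariffs, chemoprevention off, OP-only
and TURP-only surgical mixes, and start ages 40/50/60 with their band
baseline utilities. Age scenarios set the start age to the band's lower
bound (the within-band start age is otherwise arbitrary) and draw both the
baseline utility and mortality from the band maps.

## Synthetic stand-in inputs

Two required inputs are not distributed with the published analysis this
package re-implements, and are shipped as clearly labelled synthetic
fixtures:

* **Life table** (`life_table_synthetic.csv`). Assumed annual male death
  probabilities by ten-year band (40–50: 0.0035 … 70–80: 0.07, 80–90:
  0.13), monotone in age and plausible for an adult male population with
  life expectancy near 72. Each band value represents average mortality
  over a whole decade of occupancy, hence is weighted toward the band's
  later ages.
* **Complication profiles** (`complications_synthetic.csv`). Per-type
  annual complication probabilities and utility decrements. The expected
  annual decrement is ≈0.0130 for TURP and ≈0.0011 for OP. The levels were
  calibrated once so that the implied complication QALY burden reproduces
  the order of magnitude of the published incremental-QALY results at the
  80/20 mix (base ≈ −17 QALY per 1000 patients, OP-only ≈ −58, TURP-only ≈
  −7); the individual entries are assumed stand-ins. The asymmetry encodes
  that OP complications are mostly acute and perioperative (their burden
  sits in the first-year cost and the higher perioperative mortality)
  while TURP carries a recurring annual burden.
* **Sector tariffs** (`tariff_synthetic.csv`). Public/private surgical
  tariffs consistent with a bed-share blend `0.84·public + 0.16·private =
  840.96`; the split direction is assumed. Sector scenarios exercise the
  machinery; their absolute results are placeholders.

Because of these stand-ins, absolute totals and verdicts are
fixture-dependent. Under the defaults the base case lands in the SW
quadrant with an ICER of ≈1,581 USD/QALY — below the 3,701 threshold, so
the model prefers surgery at base, whereas the published analysis reported
savings large enough (ICER ≈ 7.5k) to prefer pharmacotherapy. The published
arm totals imply substantially heavier cohort attrition (and hence a far
smaller drug-cost tail) than any mortality schedule inside this fixture's
documented 0.02–0.08 band for ages 70–80 can produce; rather than adopt an
implausible life table, the package keeps the realistic schedule and treats
the verdict as fixture-dependent. The qualitative structure is preserved
and tested: pharmacotherapy saves money at a QALY loss (SW), removing
chemoprevention lowers the ICER, the OP-only scenario has a much larger
incremental-QALY magnitude than TURP-only, and the drug acquisition cost
dominates the tornado.

## Validation

An individual-level microsimulation (`microsim_oracle()`) re-implements
propagation and accrual independently: `n` patients are simulated one
multinomial transition at a time from the same matrices, costs and
utilities the cohort engine uses, and their discounted means are compared
with the cohort expectation. The shipped checks use n = 200,000 patients
per arm (Monte-Carlo standard errors ≈ 0.3% of the means) on the base case
and on five seeded ±20% parameter perturbations, requiring agreement
within three standard errors; degenerate (deterministic) dynamics must
agree exactly. The unit suite uses n = 20,000 for speed. All stochastic
components take explicit seeds and restore the caller's RNG state.

What passing these checks shows — and does not. They establish that the
cohort recursion, discounting, and accrual are internally consistent and
that the arithmetic of the published worked examples is reproduced exactly.
They do not validate the synthetic fixtures against real mortality or
complication data, and they cannot certify the absolute cost totals for any
particular health system.

## Numerical choices and edge cases

* Transition-matrix rows must sum to 1 within 1e-12; tiny negative
  residuals from floating-point cancellation are clamped to 0, real
  infeasibilities raise an error naming the row.
* Post-surgical IPSS below the score floor clamps to the floor with a
  warning; state utilities clamp to [0, 1].
* Quadrant boundaries: zero incremental cost or effectiveness counts as
  non-negative (N/E side); `ΔE = 0` returns a dominance marker rather than
  an infinite ratio.
* ICERs are displayed rounded to one decimal; full precision is kept
  internally and in JSON exports.
* Configuration documents (YAML/JSON, schema version 1, published in
  `inst/schema/`) reject unknown keys, so misspelt overrides fail loudly.

## Known limitations

The model inherits the published design's simplifications: a two-phase
(first year / later years) state structure without tunnel states, a single
IPSS trajectory per arm rather than patient-level heterogeneity, no
probabilistic sensitivity analysis, and no treatment sequencing beyond the
noncompliance crossover. Currency conversion and tariff derivation are out
of scope; costs are taken as given in 2017 USD.
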