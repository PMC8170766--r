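# SYNTHETIC post-surgical complication profiles per surgery type.
# annual_probability: probability a survivor experiences the complication in
#   a given year; utility_decrement: utility loss while it occurs (per year).
# The per-type expected annual utility decrement (sum of probability x
# decrement) is ~0.0130 for TURP and ~0.0011 for OP. The TURP-OP asymmetry
# reflects that open-prostatectomy complications are mostly perioperative
# and acute (their burden sits in the first-year cost and perioperative
# mortality), whereas TURP carries a recurring annual burden (recurrence,
# strictures, stenosis); the two levels were calibrated so the implied
# complication QALY burden matches the order of magnitude of the published
# incremental-QALY results at the 80/20 mix. Individual probabilities and
# decrements are assumed stand-ins, NOT published estimates. Complication
# management costs beyond the moderate-infection protocol (0.71 USD) are
# already folded into the per-state surgical costs, so the cost column here
# is informational.
surgery_type,complication,annual_probability,utility_decrement,management_cost
TURP,urethral_stricture,0.04,0.08,0
TURP,meatal_stenosis,0.02,0.05,0
TURP,bladder_neck_stenosis,0.03,0.07,0
TURP,turp_recurrence,0.05,0.06,0
TURP,postoperative_fever,0.06,0.005,0
TURP,infection,0.05,0.02,0.71
TURP,transfusion,0.03,0.02,0
TURP,revision_surgery,0.01,0.18,0
OP,bladder_neck_contracture,0.005,0.1,0
OP,urethral_stricture,0.004,0.1,0
OP,infection,0.02,0.005,0.71
OP,transfusion,0.01,0.01,0
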