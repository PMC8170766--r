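# SYNTHETIC male period life table: annual probability of death (qx) by
# ten-year age band. These are assumed, plausible values for an adult male
# population in a middle-income setting (life expectancy at birth ~72 yr) --
# NOT estimates from any national census or registry. They stand in for an
# age-specific mortality schedule the model requires but that is not
# distributed with it. Each band value represents average annual mortality
# over the whole decade of occupancy (a cohort entering at the band floor
# ages through it), so it is weighted toward the band's later ages.
# Bands are [age_low, age_high): a 72-year-old uses the 70-80 row.
age_low,age_high,qx
40,50,0.0035
50,60,0.009
60,70,0.025
70,80,0.07
80,90,0.13
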