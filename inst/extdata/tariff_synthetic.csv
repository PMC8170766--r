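# Sector-specific surgical tariffs (USD). The blended row carries the
# published per-state costs of the surgical pathway; the public and private
# rows are SYNTHETIC placeholders consistent with a bed-share weighting of
# 0.84 x public + 0.16 x private = blended (the direction of the 16/84 split
# is assumed). Sector scenarios exercise the scenario machinery; their
# absolute results are fixture-dependent and not reproductions of any
# published figure.
sector,surg_y1,surg_later
blended,840.96,9
public,550,6
private,2368.5,24.75
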