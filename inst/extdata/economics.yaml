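# Default economic configuration: expected values and low/expected/high
# uncertainty ranges (also read as min/mode/max triangular distributions).
# Herd-measured quantities carry trial-scale ranges; market prices a
# symmetric 2020 spread; the trade values marked "reconstructed" are the
# package's calibrated synthetic defaults (see the methods vignette) and
# should be replaced with farm-specific figures for real use.
barren_reduction:
  low: 0.02
  expected: 0.06
  high: 0.10
heifer_cost_gbp:
  low: 1136
  expected: 1495
  high: 1854
daily_yield_l:
  low: 15
  expected: 24
  high: 33
milk_price_gbp_per_l:
  low: 0.20
  expected: 0.28
  high: 0.36
cull_value_gbp:
  low: 534
  expected: 631
  high: 728
treatment_extra_cost_gbp:
  low: 12
  expected: 18
  high: 24
beef_share_shift:
  low: -0.09
  expected: -0.03
  high: 0.03
days_gain:            # reconstructed; right-skewed lactation-length gain
  low: 2
  expected: 4
  high: 7.8
feed_cost_gbp_per_l:  # reconstructed; downside-skewed feed cost
  low: 0.0222
  expected: 0.07
  high: 0.07
ai_cost_gbp: 18       # reconstructed
services_per_conception_pgod: 1.72
services_per_conception_moft: 1.65
conc_first42_pgod: 0.70
conc_first42_moft: 0.77
conc_second42_pgod: 0.10
conc_second42_moft: 0.09
calf_value_dairy_male: 45       # reconstructed
calf_value_dairy_female: 143    # reconstructed
calf_value_beefx_male: 200      # reconstructed
calf_value_beefx_female: 163    # reconstructed
male_fraction: 0.52
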