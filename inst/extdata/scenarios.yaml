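# Default scenario definitions for the prevalence estimator and the
# parity-cancer-risk fertility corrections.
#
# trend scenarios: multiplier applied to reference-year age-specific cancer
# mortality rates when reconstructing historic deaths in year yd:
#   S1  stable rates            -> 1
#   S2  rates rising 1%/year    -> 0.99^(ref - yd)
#   S3  rates falling 1%/year   -> 1.01^(ref - yd)
#   S4  S2 for low/medium HDI countries, S3 for high/very-high HDI countries
trend_scenarios: [S1, S2, S3, S4]

# mortality rate ratio applied to a child's hazards after maternal death
mrr_labels:
  a: 1.25
  b: 1.5
  c: 2.0
  d: 2.6
  e: 1.0

# multiplicative corrections to cohort fertility for parity-associated
# cancer risk; min_age_at_death restricts the correction to deaths above
# that age (exclusive); unlisted sites default to 1.
parity_rr:
  - site: "Cervix uteri"
    rr: 1.1
  - site: "Ovary"
    rr: 0.8
  - site: "Breast"
    rr: 0.93
    min_age_at_death: 50
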