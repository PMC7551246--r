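# Default run configuration: study conditions for the YYB ECEA pipeline.
# effect: mean height gain (cm) with 95% CI bounds.
# costs: per-pack components in RMB cents; PPP factor from 19.4 RMB = $5.50.
# scenarios: the coverage x delivery grid of the main analysis.
effect:
  eff_cm: 2.46
  ci_lower_cm: 0.96
  ci_upper_cm: 3.97
costs:
  m_cents: 35.0
  f_cents: 17.9
  a_cents: 16.7
  tv_cents: 0.9
  tm_max_cents: 13.5
  tm_min_cents: 0.9
  r_min: 31
  r_max: 208
  packs_per_year: 365
  trips_per_year: 12
  hours_per_workyear: 2000
simulate:
  n_provinces: 25
  children_per_province: 640
  poverty_fraction: 0.4
scenarios:
  - coverage: 0.25
    delivery_type: 1
  - coverage: 0.25
    delivery_type: 2
  - coverage: 0.75
    delivery_type: 1
  - coverage: 0.75
    delivery_type: 2
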