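# Example configuration for a single phage-biofilm replicate at desk scale.
# Any key omitted here falls back to the package default (Table-constrained
# E. coli / phage T7 values); unknown keys are rejected.
space:
  x_max_um: 300
  y_max_um: 90
  dl_um: 3
nutrient:
  N_max_mg_per_l: 4
strains:
  susceptible:
    resistance_mode: SUSCEPTIBLE
    cost_c: 0
    interaction_rate_I: 0.09
  resistant:
    resistance_mode: ABORTIVE
    cost_c: 0.05
    interaction_rate_I: 0.09
sim:
  dt_min: 7.5
  seed: 1
  resistant_fraction: 0.5
  endpoint_days_after_infection: 3
  max_days: 10
pulse:
  enabled: true
  mode: POINT
  count: 120
  height_threshold_um: 20
  duration_iterations: 1
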