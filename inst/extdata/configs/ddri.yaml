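# DNA-damage-response inhibitor 210 mg/m^2 weekly: S-phase kill with
# weekly-period oscillation of the S census.
lattice:
  extents: [20, 20, 20]
init:
  n_cancer: 120
rates:
  division: 0.006
treatments:
  - modality: ddri
    amount: 210
    pattern: weekly
    start_day: 7
    n_doses: 3
ddri:
  emax: 0.5
run:
  horizon_days: 28
  seed: 1
  output_interval: 6
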