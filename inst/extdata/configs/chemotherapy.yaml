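# Docetaxel 0.132 g Q3W (1.75 m^2 x 75 mg/m^2): K/PD kill of G2/M cells with
# resistance-driven exponential decline of the kill rate.
lattice:
  extents: [20, 20, 20]
init:
  n_cancer: 120
cycle:
  durations: {G1: 11, S: 8, G2: 4, M: 1}
rates:
  division: 0.003
treatments:
  - modality: docetaxel
    amount: 0.132
    pattern: q3w
    start_day: 0
    n_doses: 2
run:
  horizon_days: 28
  seed: 1
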