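# Untreated baseline: growing tumour, adaptive PDL1 expression, progressive
# effector exhaustion (desk-scale analogue of the no-treatment scenario).
lattice:
  extents: [20, 20, 20]
init:
  n_cancer: 80
run:
  horizon_days: 30
  seed: 1
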