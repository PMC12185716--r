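# Desk-scale three-cohort study configuration for the bundled pipeline
# demonstration. Cohort shapes (ages, doses, mutation rates) follow the
# package defaults; only the sample sizes are reduced.
seed: 20260928
window_bp: 20
cohorts:
  inova:
    n_offspring: 20
  radar:
    n_offspring: 12
  cru:
    n_offspring: 12
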