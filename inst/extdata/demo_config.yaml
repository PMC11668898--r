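# Demo configuration: every stage runs on seeded synthetic data.
seed: 1
stages:
  variants:
    enabled: true
    n_true: 150
  signatures:
    enabled: true
    n_mutations: 2000
    weights:
      SBSsyn1: 0.6
      SBSsyn2: 0.4
  de:
    enabled: true
    n_genes: 2000
  ora:
    enabled: true
  survival:
    enabled: true
    n_patients: 200
  assays:
    enabled: true
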