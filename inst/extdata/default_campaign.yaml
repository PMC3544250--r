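# Default MABC campaign: Saltol introgression scheme.
generations: 3
pop_size: 300
n_advanced: 2
cm_per_mb: 4.0
missing_rate: 0.0
panel: saltol
background: synthetic
foreground: [RM493, RM3412b]
flanks:
  "1": {RM10825: A}
  "2": {RM10694: A}
  "3": {RM10694: A}
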