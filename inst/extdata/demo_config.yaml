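# Demonstration configuration: generate a small synthetic series, anonymize
# it with PPMS++, audit it, and report metrics.  Paths are relative to this
# file; point `output` somewhere writable before running.
schema:
  - {name: Sex, kind: categorical, taxonomy: sex_taxonomy.tsv}
  - {name: Age, kind: numeric, min: 0, max: 100}
  - {name: Weight, kind: numeric, min: 30, max: 150}
k: 3
lifespan_x: 8
seed: 42
variant: ppms++
thresholds: {mode: uniform, theta: 0.6}
synth: {n_quarters: 3, cases_per_quarter: 120, followup_prob: 0.3,
        lifespan_max: 2, n_symptoms: 40}
output: out
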