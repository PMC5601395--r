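# Example scenario: one year of daily 40 mg simvastatin with imperfect
# adherence, simulated for two years.  All omitted keys take the
# typical-patient defaults (see scenario_schema.yaml).
regimen:
  dose_mg: 40
  interval_h: 24
  start_h: 0
  duration_h: 8760
adherence:
  p_t: 0.90
  q_nt: 0.25
  seed: 42
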