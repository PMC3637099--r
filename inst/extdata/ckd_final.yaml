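name: ckd_final
lookback_years: 5
min_occurrences: 1
codes:
  - {code: E102, system: ICD10}
  - {code: E112, system: ICD10}
  - {code: E132, system: ICD10}
  - {code: E142, system: ICD10}
  - {code: I12, system: ICD10}
  - {code: I13, system: ICD10}
  - {code: N08, system: ICD10}
  - {code: N18, system: ICD10}
  - {code: N19, system: ICD10}
  - {code: "403", system: OHIP}
  - {code: "585", system: OHIP}
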