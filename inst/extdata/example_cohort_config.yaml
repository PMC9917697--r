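# Example simulator overrides. Only the keys present here change; all
# others keep the calibrated package defaults (see ?default_cohort_config).
n_patients: 500
seed: 7
# a rheumatic-heavy referral mix
etiology_mix:
  mitral_valve_prolapse: 0.25
  infective_endocarditis: 0.10
  rheumatic_heart_disease: 0.45
  atrial_mitral_regurgitation: 0.12
  barlows_syndrome: 0.03
  other: 0.05
feature_freqs:
  rheumatic_heart_disease:
    # model a population with even more subvalvular calcification
    calc:
      chordae: 0.9
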