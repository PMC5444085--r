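# Example scenario: a zoophilic, endophagic vector population under a
# layered net + veterinary-insecticide programme, with a synthetic survey.
profile:
  q_human: 0.5
  pi_indoor: 0.9
  pi_in_bed: 0.8
  f_livestock: 0.9
  r_indoor_rest: 0.3
  sugar_rate: 0.2
interventions:
  - kind: LLIN
    coverage: 0.8
    block: 0.625
  - kind: IRS
    coverage: 0.7
    post_kill: 0.8
  - kind: LIVESTOCK_INSECTICIDE
    coverage: 0.6
    post_kill: 0.8
synth:
  seed: 1
  person_nights: 500
  blood_meals: 200
context:
  sleeps_indoors: true
  outdoor_night_activity: true
  owns_livestock: true
baseline_survival: 0.7
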