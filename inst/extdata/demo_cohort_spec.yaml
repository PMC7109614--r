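# Demo cohort for `copdflow simulate`: 50 over-40 primary-care attendees.
"n": 50
seed: 7
obstruction_prevalence: 0.25
attempt_sigma_l: 0.05
screening_sensitivity: 0.9
screening_specificity: 0.85
no_show_prob: 0.12
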