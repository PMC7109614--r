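# Default opportunistic-screening questionnaire.
# Non-canonical: the redesigned pathway requires *a* screening instrument but
# does not standardise one; this default is modelled on published COPD
# population screeners (age band, smoking exposure band, exertional dyspnea,
# chronic cough/sputum, prior breathing-problem episodes) and is fully
# replaceable by any instrument file with the same schema.
name: copdflow-default-screener
source: package default (non-canonical)
cutoff: 5
items:
  - key: age_band
    text: "Age band (41-50 = 0, 51-65 = 1, >65 = 2)"
    min: 0
    max: 2
  - key: pack_years_band
    text: "Cumulative smoking (never/<10 pack-years = 0, 10-30 = 1, >30 = 2)"
    min: 0
    max: 2
  - key: dyspnea_exertion
    text: "Breathlessness on exertion (never = 0, on hills/stairs = 1, on level ground = 2)"
    min: 0
    max: 2
  - key: chronic_cough_sputum
    text: "Cough or sputum on most days (no = 0, seasonal = 1, most of the year = 2)"
    min: 0
    max: 2
  - key: breathing_episodes
    text: "Episodes of breathing problems in the past year (none = 0, one = 1, more = 2)"
    min: 0
    max: 2
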