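# Default diagnostic-pathway process model: one state per task in the
# redesigned primary-care COPD pathway, with the responsible actor per task.
# Guards are names of registered pure predicates over the event payload.
name: copd-diagnosis-default
initial: appointment_requested
states:
  - {name: appointment_requested,        actor: patient, terminal: false}
  - {name: screening_invited,            actor: patient, terminal: false}
  - {name: suspicion_recorded,           actor: system,  terminal: false}
  - {name: awaiting_consultation,        actor: patient, terminal: false}
  - {name: consultation_evaluation,      actor: doctor,  terminal: false}
  - {name: clinical_suspicion_check,     actor: doctor,  terminal: false}
  - {name: spirometry_calibration,       actor: nurse,   terminal: false}
  - {name: device_calibration,           actor: nurse,   terminal: false}
  - {name: spirometry_attempts,          actor: nurse,   terminal: false}
  - {name: spirometry_validation,        actor: system,  terminal: false}
  - {name: complementary_tests,          actor: doctor,  terminal: false}
  - {name: differential_diagnosis,       actor: doctor,  terminal: false}
  - {name: severity_staging,             actor: system,  terminal: false}
  - {name: referral_report,              actor: doctor,  terminal: false}
  - {name: treatment_planning,           actor: doctor,  terminal: false}
  - {name: not_copd,                     actor: system,  terminal: true}
  - {name: copd_diagnosed_primary_care,  actor: doctor,  terminal: true}
  - {name: referred_to_specialist,       actor: doctor,  terminal: true}
  - {name: no_show,                      actor: system,  terminal: true}
transitions:
  - {from: appointment_requested,   event: eligibility_checked,    guard: eligible,                to: screening_invited}
  - {from: appointment_requested,   event: eligibility_checked,    guard: not_eligible,            to: awaiting_consultation}
  - {from: screening_invited,       event: screening_done,         guard: screening_positive,      to: suspicion_recorded}
  - {from: screening_invited,       event: screening_done,         guard: screening_negative,      to: awaiting_consultation}
  - {from: screening_invited,       event: screening_skipped,      guard: always,                  to: awaiting_consultation}
  - {from: suspicion_recorded,      event: suspicion_noted,        guard: always,                  to: awaiting_consultation}
  - {from: awaiting_consultation,   event: patient_arrived,        guard: always,                  to: consultation_evaluation}
  - {from: awaiting_consultation,   event: no_show_timeout,        guard: always,                  to: no_show}
  - {from: consultation_evaluation, event: evaluation_done,        guard: always,                  to: clinical_suspicion_check}
  - {from: clinical_suspicion_check, event: suspicion_assessed,    guard: copd_suspected,          to: spirometry_calibration}
  - {from: clinical_suspicion_check, event: suspicion_assessed,    guard: copd_not_suspected,      to: not_copd}
  - {from: spirometry_calibration,  event: calibration_checked,    guard: calibrated,              to: spirometry_attempts}
  - {from: spirometry_calibration,  event: calibration_checked,    guard: uncalibrated,            to: device_calibration}
  - {from: device_calibration,      event: calibration_performed,  guard: always,                  to: spirometry_attempts}
  - {from: spirometry_attempts,     event: attempts_recorded,      guard: always,                  to: spirometry_validation}
  - {from: spirometry_validation,   event: session_validated,      guard: session_valid_obstructed, to: complementary_tests}
  - {from: spirometry_validation,   event: session_validated,      guard: session_valid_clear,     to: not_copd}
  - {from: spirometry_validation,   event: session_validated,      guard: session_invalid,         to: spirometry_attempts}
  - {from: complementary_tests,     event: tests_reviewed,         guard: always,                  to: differential_diagnosis}
  - {from: differential_diagnosis,  event: alternatives_ruled_out, guard: copd_confirmed,          to: severity_staging}
  - {from: differential_diagnosis,  event: alternatives_ruled_out, guard: alternative_dx_found,    to: not_copd}
  - {from: severity_staging,        event: staged,                 guard: refer,                   to: referral_report}
  - {from: severity_staging,        event: staged,                 guard: no_refer,                to: treatment_planning}
  - {from: referral_report,         event: report_completed,       guard: always,                  to: referred_to_specialist}
  - {from: treatment_planning,      event: treatment_defined,      guard: always,                  to: copd_diagnosed_primary_care}
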