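{
  "$comment": "Canonical record schemas for copdflow JSON/CSV dialects. CSV flattens one record per row; list-valued fields are JSON-only.",
  "patient_record": {
    "required": ["patient_id", "age", "sex", "height"],
    "properties": {
      "patient_id": {"type": "string"},
      "age": {"type": "integer", "minimum": 0, "unit": "years"},
      "sex": {"enum": ["male", "female"]},
      "height": {"type": "number", "exclusiveMinimum": 0, "unit": "cm"},
      "weight": {"type": "number", "exclusiveMinimum": 0, "unit": "kg"},
      "group": {"type": "string", "description": "ancestry group label mapped to a reference-equation row"},
      "smoking_status": {"enum": ["never", "ex", "current"]},
      "pack_years": {"type": "number", "minimum": 0},
      "dyspnea": {"type": ["boolean", "null"]},
      "chronic_cough": {"type": ["boolean", "null"]},
      "chronic_sputum": {"type": ["boolean", "null"]},
      "recurrent_infections": {"type": ["boolean", "null"]},
      "risk_exposure": {"type": ["boolean", "null"]},
      "family_history_copd": {"type": ["boolean", "null"]}
    }
  },
  "spirometry_attempt": {
    "required": ["patient_id", "fvc", "fev1"],
    "properties": {
      "patient_id": {"type": "string", "description": "session identifier"},
      "attempt": {"type": "integer", "minimum": 1},
      "fvc": {"type": "number", "unit": "L", "exclusiveMinimum": 0.2, "exclusiveMaximum": 10},
      "fev1": {"type": "number", "unit": "L", "description": "0 < FEV1 <= FVC"},
      "fet": {"type": ["number", "null"], "unit": "s"},
      "slow_start": {"type": "boolean"},
      "early_termination": {"type": "boolean"},
      "glottis_closure": {"type": "boolean"},
      "variable_effort": {"type": "boolean"}
    }
  },
  "clinical_assessment": {
    "required": ["bmi", "fev1_pct", "mmrc", "exacerbations"],
    "properties": {
      "bmi": {"type": "number", "unit": "kg/m2"},
      "fev1_pct": {"type": "number", "exclusiveMinimum": 0, "unit": "% predicted"},
      "mmrc": {"type": "integer", "minimum": 0, "maximum": 4},
      "exacerbations": {"type": "integer", "minimum": 0, "unit": "per year"},
      "hospitalizations": {"type": "integer", "minimum": 0, "unit": "per year"},
      "cat_score": {"type": "integer", "minimum": 0, "maximum": 40},
      "six_mwd": {"type": ["number", "null"], "unit": "m"}
    }
  },
  "task_log_entry": {
    "required": ["instance_id", "state", "event", "actor", "entered"],
    "properties": {
      "instance_id": {"type": "string"},
      "patient_id": {"type": "string"},
      "state": {"type": "string"},
      "event": {"type": "string"},
      "actor": {"enum": ["patient", "doctor", "nurse", "system"]},
      "entered": {"type": "string", "format": "date-time (ISO-8601 UTC)"},
      "exited": {"type": ["string", "null"], "format": "date-time (ISO-8601 UTC)"}
    }
  },
  "notification": {
    "required": ["recipient", "kind", "scheduled_time"],
    "properties": {
      "recipient": {"enum": ["patient", "doctor"]},
      "kind": {"enum": ["screening_invite", "screening_positive_alert", "appointment_reminder"]},
      "scheduled_time": {"type": "string", "format": "date-time (ISO-8601 UTC)"},
      "payload_key": {"type": "string"}
    }
  }
}
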