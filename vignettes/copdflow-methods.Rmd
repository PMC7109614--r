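---
title: "copdflow: methods, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{copdflow: methods, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdflow)
```

## The problem and the model

COPD is chronically underdiagnosed in primary care: patients present for
unrelated reasons while already obstructed, spirometry is frequently skipped
or performed poorly, the fixed FEV1/FVC < 0.7 rule over-calls obstruction in
the elderly, and referral criteria are applied inconsistently. `copdflow`
implements the diagnostic pathway as an explicit, executable process model so
that every rule is a configurable, testable unit and every task is traced.

The pathway is a finite state machine (19 states, 25 guarded transitions)
from `appointment_requested` to one of four terminal outcomes: `not_copd`,
`copd_diagnosed_primary_care`, `referred_to_specialist`, `no_show`. Guards
are pure predicates over an accumulated payload (e.g. `screening_positive`,
`session_valid`), which makes dispatch deterministic, allows guard inversion
when simulating random walks, and keeps the engine free of hidden state. The
clock is always an explicit argument: nothing reads the wall clock, so every
execution is reproducible. Each `advance()` closes the current task-log entry
and opens the next; the log is by construction a walk through the model, and
`replay_task_log()` re-walks it independently as a soundness oracle.

## Spirometry

A session is *valid* when the device is calibrated (last calibration at most
`calibration_max_age_hours = 24` h old, boundary inclusive) and the
*reproducibility criterion* holds: among the acceptable attempts (at least
three), the difference between the two best FVC values and between the two
best FEV1 values must each be at most `repro_threshold_l = 0.15` L,
*inclusive*. With more than three acceptable attempts the two-best rule is
applied over all of them — more attempts can only help, so the generalisation
is monotone. We apply the rule to the *acceptable* subset only; applying it
to all attempts is the stricter alternative and can be emulated by clearing
the quality flags.

Attempt acceptability follows the classic failure patterns (slow start,
early termination, glottis closure, variable effort). These are
operator-entered flags — curve-morphology detection from raw flow–volume
samples is out of scope — except early termination, which is computed when a
forced expiratory time is present (`min_fet_s = 6` s).

Best FVC and best FEV1 are independent per-parameter maxima and may come
from different attempts; the ratio is `best FEV1 / best FVC` carried at full
precision. Obstruction is a strict inequality, ratio < threshold, with no
rounding before the comparison (rounding first creates artifacts exactly at
0.70). One numerical guard exists: the reproducibility deltas are compared
with a 10⁻⁹ L tolerance so that values recorded on the usual 0.01 L lattice
(where 3.45 − 3.30 exceeds 0.15 by one part in 10¹⁶ in binary arithmetic)
honour the inclusive boundary.

### The lower limit of normal

The default obstruction threshold is the patient's demographic LLN of the
FEV1/FVC ratio, the age/sex/height/ancestry-specific 5th percentile:
LLN = predicted − 1.645 × SEE under the usual normal-residual assumption.
Equations are a CSV of per-(sex, group) coefficient rows with validity
ranges; evaluation outside the ranges is an error, never an extrapolation,
and an unmapped ancestry group is an error listing the available groups
(separate coefficient rows per group, rather than multiplicative correction
factors, keep the mapping auditable).

**The bundled set is synthetic.** No published all-age equation set could be
transcribed with its provenance intact into this package, so the default
(`reference_equations_synthetic.csv`) is package-constructed with realistic
magnitudes — for a 60-year-old man of 175 cm it gives predicted ratio 0.76,
LLN 0.6695, predicted FEV1 3.5 L — and a negative age coefficient, so LLN
declines with age and drops below 0.7 around age 65–75. It is clearly
labelled, and `equations_path` swaps in any published set with the same
schema. All fixed-vs-LLN discordance results in this package are therefore
*structural* demonstrations (the two modes disagree exactly in the band
between the thresholds; the fixed cut never calls fewer obstructions when
LLN < 0.7), not population estimates.

## Screening

Eligibility is strict: age **over** 40 (the 35-year cut used by some
guidelines is available via `age_cut = 35`) and no completed screening within
the revalidation window (`revalidation_years = 2`). The nightly sweep
deduplicates within and across runs, skips and reports records without an
age, and schedules an appointment reminder at exactly T − 24 h
(`reminder_lead_hours`).

The pathway requires *a* screening questionnaire but does not standardise
one. The bundled instrument (5 items — age band, smoking exposure band,
exertional dyspnea, chronic cough/sputum, prior breathing episodes — each
0–2 points, positive at total ≥ 5 of 10) is modelled on published COPD
population screeners and is explicitly **non-canonical**: it is a YAML file,
replaceable item for item, and scoring is driven entirely by the file
(per-item ranges, cutoff at ≥). Clinical suspicion outside screening uses the
key-indicator rule: age over the cut plus at least one of dyspnea, chronic
cough, chronic sputum, recurrent lower-respiratory infections, risk-factor
exposure, or family history; unknown flags count as absent but are reported
separately so "not asked" is never conflated with "absent".

## Severity staging and referral

BODE and BODEx cut-points are shipped as CSV tables transcribed from the
published index definitions (FEV1% bands ≥65 / 50–64 / 36–49 / ≤35; walk
bands ≥350 / 250–349 / 150–249 / ≤149 m; mMRC 0–1 / 2 / 3 / 4; BMI >21 / ≤21;
exacerbations 0 / 1–2 / ≥3), interpreted as contiguous half-open intervals so
non-integer inputs stage consistently. BODEx uses the recorded past-year
exacerbation count. When both indices are computable BODE drives severity
(the walk test is the richer measurement; `index_precedence` flips this);
without a 6-minute-walk distance the engine falls back to BODEx.

The four severity levels are not tied to specific index bands anywhere in
the pathway definition, so the defaults — BODE 0–2 / 3–4 / 5–6 / 7–10 and
BODEx 0–2 / 3–4 / 5–6 / ≥7, quartile-style — are **non-canonical defaults**
in a validated band table (gap-free, non-overlapping, full-range coverage is
enforced at config load). An FEV1-percent-predicted driver
(`severity_driver = "fev1_pct"`, bands ≥80 / 50–79 / 30–49 / <30) is
implemented as the alternative used by guidelines that stage on airflow
limitation alone; the package asserts neither as canonical. CAT impact uses
<10 / 10–20 / 21–30 / >30.

Referral fires when severity is severe or very severe, or exacerbations are
frequent — defaults ≥2 moderate exacerbations/yr or ≥1 hospitalization, the
common convention, both configurable. A flagged referral must carry a
complete structured report (scores, spirometry summary, exacerbation
history); incompleteness is an error naming the field, mirroring the audit
finding that referral reports from primary care often omit recommended
information.

## Differential diagnosis

The knowledge base decomposes each free-text feature of the seven-disease
differential table into atomic canonical keys (the asthma row becomes six
keys), keeping the verbatim source text alongside each key. Matching is the
Jaccard coefficient over key sets — the simplest fully explainable choice —
with ties broken by the fixed table order and matched features returned per
diagnosis. This is decision support, not a classifier: no probabilistic
disease model is implied, and all features (symptoms, imaging, demographics)
are accepted as optional inputs.

## The synthetic cohort generator

The generator emulates the population the redesign targets: over-40
primary-care attendees (ages truncated-normal 62 ± 11 on [41, 90] — the
screening rule itself excludes younger patients, so modelling them would only
dilute the end-to-end signal), half male, 45% ever-smokers, 25% truly
obstructed. True ratios are placed *relative to each patient's own LLN*
(obstructed: 0.02–0.12 below; clear: 0.02–0.15 above), which makes the
fixed-vs-LLN discordance exercisable by construction. Attempt values are
true values plus Gaussian noise (`attempt_sigma_l = 0.05` L within-session
variability; ~3% of attempts carry a quality failure), screening answers are
constructed to hit the target sensitivity/specificity (defaults 0.90/0.85)
in expectation, and no-shows default to 12% — inside the 10–15% absenteeism
range reported for primary-care consultations. Each patient draws from a
stream derived from (seed, patient id), so cohorts are deterministic and
extensible without reshuffling existing patients.

What the generator does *not* emulate: real epidemiological joint
distributions (parameters are spec-driven, not fitted), measurement bias,
device drift, missing data beyond the walk test, or patients who refuse
screening. Passing end-to-end tests therefore demonstrates the *internal
consistency* of the engine — with zero noise and perfect screening the
pipeline recovers ground truth exactly, and degradation appears only where
noise crosses a patient's threshold — not diagnostic performance on real
patients.

An invalid session in a replay is regenerated (the "repeat the test" path) up
to `max_session_retries = 3` times; if still invalid the patient is
classified from the best attempts anyway and flagged `forced`, so every
process instance reaches a terminal state and the confusion matrix stays
complete. Degenerate inputs are handled explicitly throughout: empty
appointment lists, empty feature sets (all scores 0, stable order), fewer
than three attempts (`insufficient_attempts`), missing ages (skipped and
logged), terminal instances (rejected events leave the instance unchanged).

## Configuration and formats

All tunables live in one validated config (`engine_config()`); durations are
numeric fields with the unit in the name (`reminder_lead_hours`,
`revalidation_years`, `no_show_window_days`) — unambiguous, and they
round-trip through YAML without a duration-string parser. Clinical data
files must carry a provenance label (`source` column); band tables are
checked for coverage. JSON is the canonical record dialect (CSV is the flat
convenience form; `inst/schemas/records.json` documents both), timestamps
are ISO-8601 UTC, and task logs export as append-only JSON Lines that replay
to identical final states. The exit-code contract of the CLI treats a
negative verdict ("not reproducible") as a result (exit 0); only failure to
compute is nonzero.

## Verification approach and problem sizes

The suite pits each rule against an independent oracle: the reproducibility
rule against brute-force pairwise enumeration on an exhaustive 0.01 L lattice
(125,000 attempt triples including the exact-0.15 boundary), index scoring
against directly-coded band oracles on the full cut-point boundary lattice
(±0.01 at every cut), the differential ranking against an exhaustive Jaccard
recomputation on all 1,024 subsets of a 10-feature vocabulary, and process
execution against log replay on 10,000 random valid walks. End-to-end
properties use seeded cohorts of 120–5,000 patients (1,000 for the
noise-free recovery run, 5,000 for the discordance analysis); prevalence
recovery is checked at n = 2,000 within three standard errors. These sizes
were chosen to make the property checks exhaustive where the input space is
finite and statistically comfortable where it is not.

## Known limitations

- The bundled reference equations are synthetic; obstruction calls in LLN
  mode are only as good as the equation set configured.
- The screening instrument and the severity band mapping are explicit
  non-canonical defaults, as discussed above.
- Quality flags other than early termination require operator input; the
  engine validates sessions but cannot detect a mis-performed curve itself.
- Complementary tests (X-ray, oximetry, blood work) are recorded as
  pass-through facts; their interpretation is out of scope.
- The process engine is a single-instance executor with explicit clocks; it
  is not a BPMN 2.0 runtime and has no messaging, persistence or EHR
  connectivity.
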